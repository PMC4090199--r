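#' Count phenotype genes per pathway
#'
#' The association score for phenotype i and pathway j is the number of
#' phenotype-i genes that are members of pathway j. Every pathway of the
#' database appears in the output, zeros included.
#'
#' @param genes Character vector of the phenotype's pathway-universe
#'   genes, or a one-row `phenotype_gene_sets` table.
#' @param db A [pathway_db()].
#' @return Named integer vector, one count per pathway id.
#' @examples
#' db <- pathway_db(list(P1 = c("g1", "g2", "g3", "g4"), P2 = "g5"))
#' compute_dp(c("g1", "g2"), db)
#' @export
compute_dp <- function(genes, db) {
  stopifnot(inherits(db, "pathway_db"))
  if (inherits(genes, "phenotype_gene_sets")) {
    stopifnot(nrow(genes) == 1L)
    genes <- genes$universe_genes[[1L]]
  }
  genes <- unique(as.character(genes))
  if (!all(genes %in% db$universe)) {
    stop("gene outside pathway universe: ",
         setdiff(genes, db$universe)[1L])
  }
  vapply(db$pathways, function(p) sum(genes %in% p), integer(1))
}

# internal: sparse pathway-by-gene incidence matrix (P x N), gene order
# following db$universe
.pl_incidence <- function(db) {
  gi <- lapply(db$pathways, function(p) match(p, db$universe))
  Matrix::sparseMatrix(
    i = rep(seq_along(gi), lengths(gi)),
    j = unlist(gi, use.names = FALSE),
    x = 1,
    dims = c(db$P, db$N)
  )
}

# internal: P x reps matrix of pathway counts for `reps` random draws of
# G distinct genes from the universe (uniform, without replacement)
.pl_draw_counts <- function(G, db, reps, M = NULL) {
  if (is.null(M)) M <- .pl_incidence(db)
  idx <- unlist(lapply(seq_len(reps), function(r) sample.int(db$N, G)),
                use.names = FALSE)
  Z <- Matrix::sparseMatrix(i = idx, j = rep(seq_len(reps), each = G),
                            x = 1, dims = c(db$N, reps))
  out <- as.matrix(M %*% Z)
  storage.mode(out) <- "integer"
  out
}

#' Sample the pooled resampling null for a gene-set size
#'
#' Draws `reps` random gene sets of `G` distinct genes uniformly from the
#' pathway universe; each draw contributes one count per pathway (how many
#' of the G genes fall in that pathway). All `reps * P` counts are pooled
#' into a single multiset of expected random scores, the empirical null
#' against which an observed count is judged. The pool depends only on
#' `(G, db, seed)`, so it can be shared by every phenotype with the same
#' `G`.
#'
#' @param G Gene-set size, `0 < G <= db$N`.
#' @param db A [pathway_db()].
#' @param reps Number of resampling replicates (default 1000).
#' @param seed Optional integer seed; fixing it makes the pool
#'   reproducible.
#' @param keep_matrix Keep the full P-by-reps count matrix (needed for
#'   the per-pathway conditional null variant).
#' @return Object of class `null_pool`: list with `G`, `reps`, `scores`
#'   (integer vector of length `reps * P`), `tail_counts`
#'   (`tail_counts[k+1]` = number of pooled scores `>= k`, k = 0..G),
#'   `seed`, and optionally `per_pathway`.
#' @export
sample_null_pool <- function(G, db, reps = 1000, seed = NULL,
                             keep_matrix = FALSE) {
  stopifnot(inherits(db, "pathway_db"))
  if (!is.numeric(G) || G < 1 || G > db$N) {
    stop("G must be in [1, N]; got G=", G, ", N=", db$N)
  }
  if (reps < 1) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  counts <- .pl_draw_counts(as.integer(G), db, as.integer(reps))
  scores <- as.integer(counts)
  tab <- tabulate(scores + 1L, nbins = G + 1L)
  tail_counts <- rev(cumsum(rev(tab)))
  structure(
    list(G = as.integer(G), reps = as.integer(reps), scores = scores,
         tail_counts = tail_counts, seed = seed,
         per_pathway = if (keep_matrix) counts else NULL),
    class = "null_pool"
  )
}

#' Exact tail probability of the pooled null
#'
#' Closed form for the pooled resampling null: a random draw of `G`
#' distinct genes from a universe of `N` gives pathway j a
#' hypergeometric(N, m_j, G) count, and pooling across pathways yields
#' the uniform mixture over pathways. The pooled upper tail at `k` is
#' therefore `(1/P) * sum_j Pr[X_j >= k]`. Serves as the analytic oracle
#' for [sample_null_pool()] and for power calculations.
#'
#' @param k Observed count (non-negative integer). `k <= 0` returns 1;
#'   `k > G` returns 0.
#' @param G Gene-set size, `G <= db$N`.
#' @param db A [pathway_db()].
#' @return Probability in \[0, 1\].
#' @examples
#' db <- pathway_db(list(P1 = paste0("g", 1:4), P2 = paste0("g", 3:8)))
#' exact_pooled_tail(2, 2, db)  # 21/56 = 0.375
#' @export
exact_pooled_tail <- function(k, G, db) {
  stopifnot(inherits(db, "pathway_db"))
  if (G < 0 || G > db$N) stop("G must be in [0, N]")
  if (k > G) return(0)
  if (k <= 0) return(1)
  m <- lengths(db$pathways)
  mean(stats::phyper(k - 1, m, db$N - m, G, lower.tail = FALSE))
}

#' Empirical p-value of an observed count against a null pool
#'
#' The fraction of pooled null scores at least as large as the observed
#' count — the observed association is significant when it is within or
#' above the top `alpha` of the random scores. The raw fraction can be 0
#' when the observation exceeds the pool maximum; the smoothed
#' `(c+1)/(n+1)` estimator never reports 0.
#'
#' @param dp Observed count (non-negative integer).
#' @param pool A [sample_null_pool()] result.
#' @param smooth Use the `(c+1)/(n+1)` estimator (default `FALSE`).
#' @return Probability.
#' @export
empirical_pvalue <- function(dp, pool, smooth = FALSE) {
  stopifnot(inherits(pool, "null_pool"))
  n <- length(pool$scores)
  cnt <- if (dp <= 0) n else if (dp > pool$G) 0L else pool$tail_counts[dp + 1L]
  if (smooth) (cnt + 1) / (n + 1) else cnt / n
}

#' Score phenotype gene sets against all pathways
#'
#' For each testable phenotype, counts its universe genes in every
#' pathway and assigns each count an empirical p-value from the pooled
#' resampling null for that phenotype's gene-set size `G`. A
#' phenotype-pathway association is called significant when the p-value
#' is at or below `alpha` and the count is at least `min_dp` (clustering
#' requires at least two distinct genes in the pathway).
#'
#' Null pools are cached by `G`: the pool distribution depends only on
#' `(G, db, seed)`, so phenotypes with equal `G` share one pool (and
#' hence identical p-values for identical counts). Pool seeds are derived
#' deterministically from `seed` and `G`, so results are reproducible and
#' independent of the order or number of phenotypes. Set `cache = FALSE`
#' to resample per phenotype.
#'
#' @param gene_sets A `phenotype_gene_sets` table
#'   ([build_phenotype_gene_sets()]).
#' @param db A [pathway_db()].
#' @param reps Resampling replicates per pool (default 1000).
#' @param alpha Significance level for the empirical p-value
#'   (default 0.05).
#' @param min_dp Minimum count required to call significance (default 2).
#' @param seed Optional master seed.
#' @param null_mode `"pooled"` (default): p-values from the pool of all
#'   `reps * P` scores, a function of `(G, dp)` only. `"per_pathway"`: a
#'   conditional variant comparing each pathway's count only to that
#'   pathway's own `reps` replicate counts.
#' @param smooth Use the smoothed p-value estimator.
#' @param cache Share one pool per distinct `G` across phenotypes
#'   (default `TRUE`); `FALSE` resamples a fresh pool per phenotype.
#' @param min_G Minimum universe gene-set size scored (default 2).
#' @return Data frame with one row per (phenotype, pathway):
#'   `phenotype`, `pathway_id`, `pathway_name`, `G`, `dp`, `p_emp`,
#'   `significant`, `pool_reps`.
#' @export
run_enrichment <- function(gene_sets, db, reps = 1000, alpha = 0.05,
                           min_dp = 2, seed = NULL,
                           null_mode = c("pooled", "per_pathway"),
                           smooth = FALSE, cache = TRUE, min_G = 2) {
  null_mode <- match.arg(null_mode)
  stopifnot(inherits(db, "pathway_db"))
  keep <- gene_sets$testable & gene_sets$G >= min_G
  gs <- gene_sets[keep, , drop = FALSE]
  if (nrow(gs) == 0L) return(.pl_empty_results())
  pools <- new.env(parent = emptyenv())
  get_pool <- function(G, i) {
    if (!cache) {
      return(sample_null_pool(
        G, db, reps = reps, seed = .pl_child_seed(seed, G * 1000L + i),
        keep_matrix = (null_mode == "per_pathway")))
    }
    key <- as.character(G)
    if (is.null(pools[[key]])) {
      pools[[key]] <- sample_null_pool(
        G, db, reps = reps, seed = .pl_child_seed(seed, G),
        keep_matrix = (null_mode == "per_pathway"))
    }
    pools[[key]]
  }
  res <- vector("list", nrow(gs))
  for (i in seq_len(nrow(gs))) {
    G <- gs$G[i]
    pool <- get_pool(G, i)
    dp <- compute_dp(gs$universe_genes[[i]], db)
    if (null_mode == "pooled") {
      p <- vapply(dp, empirical_pvalue, numeric(1), pool = pool,
                  smooth = smooth)
    } else {
      n <- ncol(pool$per_pathway)
      cnt <- vapply(seq_along(dp), function(j) {
        sum(pool$per_pathway[j, ] >= dp[j])
      }, integer(1))
      p <- if (smooth) (cnt + 1) / (n + 1) else cnt / n
    }
    res[[i]] <- data.frame(
      phenotype = gs$phenotype[i],
      pathway_id = names(db$pathways),
      pathway_name = unname(db$pathway_names),
      G = G,
      dp = unname(dp),
      p_emp = unname(p),
      significant = unname(p <= alpha & dp >= min_dp),
      pool_reps = pool$reps,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# internal: empty results table with the right columns
.pl_empty_results <- function() {
  data.frame(phenotype = character(0), pathway_id = character(0),
             pathway_name = character(0), G = integer(0), dp = integer(0),
             p_emp = numeric(0), significant = logical(0),
             pool_reps = integer(0), stringsAsFactors = FALSE)
}

#' Histogram of a null pool
#'
#' Score-frequency table of the pooled expected random scores, suitable
#' for plotting a per-association null distribution next to the observed
#' count.
#'
#' @param pool A [sample_null_pool()] result.
#' @return Data frame with columns `score`, `count`, `frequency`.
#' @export
pool_histogram <- function(pool) {
  stopifnot(inherits(pool, "null_pool"))
  tab <- tabulate(pool$scores + 1L, nbins = pool$G + 1L)
  data.frame(score = 0:pool$G, count = tab,
             frequency = tab / length(pool$scores))
}
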