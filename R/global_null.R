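#' Simulate the global null of significant-association counts
#'
#' Nested pseudo-phenotype simulation accounting for multiple testing
#' across the whole phenotype-by-pathway grid. In each outer replicate,
#' every phenotype is replaced by a pseudo phenotype: a random draw of
#' the same number of pathway-universe genes (`pG = G`). The pseudo
#' counts per pathway are assessed with exactly the same resampling
#' significance procedure as the real data, and the number of
#' significant pseudo associations is summed over phenotypes. The
#' distribution of these totals is what the full pipeline is expected to
#' report when no phenotype's genes truly cluster.
#'
#' Two inner-null modes are provided. With `fresh_inner = FALSE`
#' (default) the inner pool for each gene-set size is drawn once and
#' shared across outer replicates and phenotypes — the pool distribution
#' depends only on `G`, and sharing reduces the cost from
#' `outer_reps * inner_reps` to `inner_reps` resamples per distinct `G`.
#' With `fresh_inner = TRUE` every (replicate, phenotype) pair draws its
#' own inner pool, the literal nested procedure.
#'
#' @param gene_set_sizes Integer vector of per-phenotype gene-set sizes
#'   `G` (one entry per analyzed phenotype; sizes must lie in
#'   `[1, db$N]`).
#' @param db A [pathway_db()].
#' @param outer_reps Number of outer (pseudo-phenotype) replicates.
#' @param inner_reps Resampling replicates per inner null pool.
#' @param alpha,min_dp Significance rule, as in [run_enrichment()].
#' @param seed Optional master seed.
#' @param fresh_inner Draw a fresh inner pool per replicate and
#'   phenotype (see above).
#' @return Data frame of class `global_null_replicates` with columns
#'   `replicate` and `total_significant`; attribute `"k_star"` records
#'   the per-G critical counts in the cached mode.
#' @export
simulate_global_null <- function(gene_set_sizes, db, outer_reps = 200,
                                 inner_reps = 1000, alpha = 0.05,
                                 min_dp = 2, seed = NULL,
                                 fresh_inner = FALSE) {
  stopifnot(inherits(db, "pathway_db"))
  gene_set_sizes <- as.integer(gene_set_sizes)
  if (length(gene_set_sizes) == 0L) stop("no gene-set sizes supplied")
  if (any(gene_set_sizes < 1L) || any(gene_set_sizes > db$N)) {
    stop("every G must be in [1, N]")
  }
  if (outer_reps < 1 || inner_reps < 1) stop("replicate counts must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  M <- .pl_incidence(db)
  n_ph <- length(gene_set_sizes)

  if (!fresh_inner) {
    # critical count per distinct G from one shared pool:
    # dp significant  <=>  dp >= k_star[G]
    Gs <- sort(unique(gene_set_sizes))
    k_star <- setNames(rep(Inf, length(Gs)), Gs)
    for (G in Gs) {
      pool <- sample_null_pool(G, db, reps = inner_reps,
                               seed = .pl_child_seed(seed, G))
      n <- length(pool$scores)
      ks <- seq.int(max(1L, min_dp), G)
      ok <- ks[pool$tail_counts[ks + 1L] / n <= alpha]
      if (length(ok)) k_star[as.character(G)] <- min(ok)
    }
    # batch the pseudo draws by distinct G: one count matrix per size,
    # columns folded back into outer replicates
    totals <- integer(outer_reps)
    for (G in Gs) {
      n_i <- sum(gene_set_sizes == G)
      counts <- .pl_draw_counts(G, db, outer_reps * n_i, M = M)
      k <- k_star[as.character(G)]
      sig_per_draw <- if (is.finite(k)) colSums(counts >= k) else
        integer(ncol(counts))
      totals <- totals + colSums(matrix(sig_per_draw, nrow = n_i,
                                        ncol = outer_reps))
    }
    out <- data.frame(replicate = seq_len(outer_reps),
                      total_significant = as.integer(totals))
    attr(out, "k_star") <- k_star
  } else {
    totals <- integer(outer_reps)
    for (r in seq_len(outer_reps)) {
      sig <- 0L
      for (i in seq_len(n_ph)) {
        G <- gene_set_sizes[i]
        pdp <- .pl_draw_counts(G, db, 1L, M = M)[, 1L]
        pool <- sample_null_pool(G, db, reps = inner_reps)
        n <- length(pool$scores)
        p <- ifelse(pdp <= 0, 1, pool$tail_counts[pmin(pdp, G) + 1L] / n)
        sig <- sig + sum(p <= alpha & pdp >= min_dp)
      }
      totals[r] <- sig
    }
    out <- data.frame(replicate = seq_len(outer_reps),
                      total_significant = totals)
  }
  class(out) <- c("global_null_replicates", "data.frame")
  attr(out, "params") <- list(outer_reps = outer_reps,
                              inner_reps = inner_reps, alpha = alpha,
                              min_dp = min_dp, fresh_inner = fresh_inner)
  out
}

#' Summarize the global null against the observed total
#'
#' Locates the pipeline's observed number of significant
#' phenotype-pathway associations within the simulated null totals:
#' median, mean, standard deviation, the z-score
#' `(observed - mean) / sd`, and the resampling p-value (fraction of
#' null totals at least as large as the observed). When the observed
#' total exceeds every replicate, the p-value is reported as the upper
#' bound `1 / outer_reps` with `p_is_upper_bound = TRUE`; 0 is never
#' reported.
#'
#' @param observed_total Observed count of significant associations.
#' @param replicates A `global_null_replicates` data frame or a numeric
#'   vector of null totals (at least 2).
#' @return Object of class `global_null_summary`: list with
#'   `observed_total`, `null_totals`, `null_median`, `null_mean`,
#'   `null_sd`, `z`, `p_global`, `p_is_upper_bound`, `degenerate`
#'   (zero-variance null flag).
#' @export
summarize_global_null <- function(observed_total, replicates) {
  totals <- if (is.data.frame(replicates)) replicates$total_significant
            else as.numeric(replicates)
  if (length(totals) < 2L) stop("need at least 2 null replicates")
  m <- mean(totals)
  s <- stats::sd(totals)
  degenerate <- s == 0
  z <- if (degenerate) {
    if (observed_total == m) 0 else {
      warning("zero-variance null with observed != mean; z is infinite")
      sign(observed_total - m) * Inf
    }
  } else (observed_total - m) / s
  cnt <- sum(totals >= observed_total)
  n <- length(totals)
  structure(
    list(observed_total = observed_total, null_totals = totals,
         null_median = stats::median(totals), null_mean = m, null_sd = s,
         z = z,
         p_global = if (cnt == 0L) 1 / n else cnt / n,
         p_is_upper_bound = cnt == 0L,
         degenerate = degenerate),
    class = "global_null_summary"
  )
}

#' @export
print.global_null_summary <- function(x, ...) {
  cat("Global null of significant phenotype-pathway associations\n")
  cat("  observed total: ", x$observed_total, "\n", sep = "")
  cat("  null median / mean / sd: ", x$null_median, " / ",
      signif(x$null_mean, 4), " / ", signif(x$null_sd, 4), "\n", sep = "")
  cat("  z: ", signif(x$z, 4), "\n", sep = "")
  cat("  p_global: ", if (x$p_is_upper_bound) "< " else "",
      signif(x$p_global, 4), " (", length(x$null_totals),
      " replicates)\n", sep = "")
  invisible(x)
}
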