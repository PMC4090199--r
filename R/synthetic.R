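#' Specification for synthetic GWAS-pathway data
#'
#' Bundles the parameters of the synthetic generator: a pathway database
#' of configurable size and overlap, and a catalog of phenotypes whose
#' genes are drawn either uniformly from the pathway universe (null
#' phenotypes) or preferentially from one designated causal pathway
#' (planted signal). Defaults describe the benchmark conditions used
#' throughout the package's tests: a 20-pathway database of 15-gene
#' pathways over a 200-gene universe, 50 null phenotypes, 20 planted
#' phenotypes drawing 80% of their ~10 genes from their causal pathway,
#' and study sizes following a linear link to gene count
#' (`500 + 150 * genes + Normal(0, 300)`).
#'
#' `overlap_fraction` is the expected fraction of one pathway's genes
#' shared with another given pathway; with mean pathway size `s` the
#' generator samples pathways from a gene pool of size `round(s /
#' overlap_fraction)`, making the expected pairwise intersection
#' `s_a * s_b / N`. Zero means disjoint pathways.
#'
#' @param n_pathways Number of pathways.
#' @param pathway_size_range Length-2 integer range of pathway sizes
#'   (inclusive, sampled uniformly).
#' @param overlap_fraction Expected pairwise overlap fraction in
#'   `[0, 1)` (see above).
#' @param n_phenotypes_null,n_phenotypes_planted Phenotype counts.
#' @param genes_per_phenotype_range Length-2 range of genes per
#'   phenotype.
#' @param signal_fraction Probability that a planted phenotype's gene is
#'   drawn from its causal pathway.
#' @param snps_per_gene SNPs emitted per chosen gene.
#' @param sample_size_model List with `intercept`, `slope`, `sigma`:
#'   study size = `intercept + slope * n_genes + Normal(0, sigma)`,
#'   floored at 50.
#' @param ensure_coverage Guarantee the universe equals the full gene
#'   pool by swapping uncovered pool genes into multiply-covered slots
#'   (pathway sizes preserved). Default `TRUE`.
#' @param messy Place a fraction of SNPs just downstream of their gene
#'   (within 2 kb) instead of inside it, exercising the nearest-gene
#'   window logic; mapping remains unambiguous. Default `FALSE`.
#' @param category_planted,category_null Category labels written for
#'   planted and null phenotypes.
#' @param seed Integer seed; all generation is reproducible given the
#'   spec.
#' @return Object of class `synthetic_spec` (validated list).
#' @export
synthetic_spec <- function(n_pathways = 20,
                           pathway_size_range = c(15, 15),
                           overlap_fraction = 0.075,
                           n_phenotypes_null = 50,
                           n_phenotypes_planted = 20,
                           genes_per_phenotype_range = c(8, 12),
                           signal_fraction = 0.8,
                           snps_per_gene = 1,
                           sample_size_model = list(intercept = 500,
                                                    slope = 150,
                                                    sigma = 300),
                           ensure_coverage = TRUE,
                           messy = FALSE,
                           category_planted = "planted",
                           category_null = "null",
                           seed = 1) {
  stopifnot(n_pathways >= 1, length(pathway_size_range) == 2L,
            pathway_size_range[1L] >= 1,
            pathway_size_range[1L] <= pathway_size_range[2L],
            overlap_fraction >= 0, overlap_fraction < 1,
            n_phenotypes_null >= 0, n_phenotypes_planted >= 0,
            length(genes_per_phenotype_range) == 2L,
            genes_per_phenotype_range[1L] >= 1,
            genes_per_phenotype_range[1L] <= genes_per_phenotype_range[2L],
            signal_fraction >= 0, signal_fraction <= 1,
            snps_per_gene >= 1,
            is.list(sample_size_model),
            all(c("intercept", "slope", "sigma") %in%
                  names(sample_size_model)),
            sample_size_model$sigma >= 0)
  if (overlap_fraction > 0) {
    pool <- round(mean(pathway_size_range) / overlap_fraction)
    if (pool < pathway_size_range[2L]) {
      stop("infeasible overlap/size combination: gene pool (", pool,
           ") smaller than the largest pathway")
    }
  }
  structure(
    list(n_pathways = as.integer(n_pathways),
         pathway_size_range = as.integer(pathway_size_range),
         overlap_fraction = overlap_fraction,
         n_phenotypes_null = as.integer(n_phenotypes_null),
         n_phenotypes_planted = as.integer(n_phenotypes_planted),
         genes_per_phenotype_range = as.integer(genes_per_phenotype_range),
         signal_fraction = signal_fraction,
         snps_per_gene = as.integer(snps_per_gene),
         sample_size_model = sample_size_model,
         ensure_coverage = isTRUE(ensure_coverage),
         messy = isTRUE(messy),
         category_planted = category_planted,
         category_null = category_null,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic pathway database and gene annotation
#'
#' Samples pathway gene sets with the overlap structure declared in the
#' spec and lays every universe gene out as a non-overlapping interval
#' (2 kb genes every 10 kb, 100 genes per synthetic chromosome), so
#' coordinate mapping of intragenic SNPs is unambiguous.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `db` (a [pathway_db()]) and `annotation`
#'   (gene-interval data frame, [read_gene_intervals()] layout).
#' @export
generate_pathway_db <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  sizes <- .pl_sample_range(spec$pathway_size_range[1L],
                            spec$pathway_size_range[2L],
                            spec$n_pathways)
  if (spec$overlap_fraction == 0) {
    pool_n <- sum(sizes)
    pool <- sprintf("g%04d", seq_len(pool_n))
    stops <- cumsum(sizes)
    starts <- c(1L, stops[-length(stops)] + 1L)
    sets <- lapply(seq_along(sizes), function(j) pool[starts[j]:stops[j]])
  } else {
    pool_n <- round(mean(spec$pathway_size_range) / spec$overlap_fraction)
    pool <- sprintf("g%04d", seq_len(pool_n))
    sets <- lapply(sizes, function(s) sample(pool, s))
    if (spec$ensure_coverage) {
      sets <- .pl_cover_pool(sets, pool)
    }
  }
  names(sets) <- sprintf("PW%03d", seq_along(sets))
  db <- pathway_db(sets, pathway_names = paste("synthetic pathway",
                                               seq_along(sets)))
  ann <- .pl_gene_layout(db$universe)
  list(db = db, annotation = ann)
}

# internal: sample n integers uniformly from [lo, hi], safe when lo == hi
.pl_sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n) else
    lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# internal: swap uncovered pool genes into multiply-covered slots so the
# union of pathways equals the pool; pathway sizes are preserved
.pl_cover_pool <- function(sets, pool) {
  leftovers <- setdiff(pool, unique(unlist(sets, use.names = FALSE)))
  for (lg in leftovers) {
    mult <- table(unlist(sets, use.names = FALSE))
    dup_genes <- names(mult)[mult >= 2L]
    if (length(dup_genes) == 0L) {
      stop("cannot cover gene pool: no multiply-covered gene left to swap")
    }
    # pick a random (pathway, gene) slot holding a multiply-covered gene
    cand <- which(vapply(sets, function(s) any(s %in% dup_genes),
                         logical(1)))
    j <- if (length(cand) == 1L) cand else sample(cand, 1L)
    g_opts <- intersect(sets[[j]], dup_genes)
    g <- if (length(g_opts) == 1L) g_opts else sample(g_opts, 1L)
    sets[[j]][sets[[j]] == g] <- lg
  }
  sets
}

# internal: deterministic non-overlapping gene layout
.pl_gene_layout <- function(genes, genes_per_chrom = 100L,
                            gene_width = 2000L, gene_step = 10000L) {
  idx <- seq_along(genes)
  slot <- (idx - 1L) %% genes_per_chrom
  data.frame(
    symbol = genes,
    chrom = sprintf("chr%d", 1L + (idx - 1L) %/% genes_per_chrom),
    start = slot * gene_step,
    end = slot * gene_step + gene_width,
    strand = "+",
    stringsAsFactors = FALSE
  )
}

#' Generate a GWAS-catalog-style association table with planted signal
#'
#' Emits one catalog row per SNP. Planted phenotypes draw each of their
#' genes from their causal pathway with probability `signal_fraction`
#' (otherwise uniformly from the universe, all genes distinct); null
#' phenotypes draw uniformly. Every chosen gene contributes
#' `snps_per_gene` SNPs placed inside its interval (or just downstream
#' in messy mode) with association p-values sampled log-uniformly in
#' `[1e-12, 1e-5]` — below the catalog threshold, since filtering is
#' exercised elsewhere. Study sizes follow the spec's linear link to
#' gene count; each phenotype is one study.
#'
#' @param spec A [synthetic_spec()].
#' @param db,annotation Output of [generate_pathway_db()] (the db built
#'   from the same spec).
#' @return List of data frames: `catalog` (columns `trait`, `snp`,
#'   `chrom`, `pos`, `pvalue`, `reported_genes`, `sample_size`,
#'   `study`), `categories` (`phenotype`, `category`) and `truth`
#'   (`phenotype`, `causal_pathway` (`"none"` for null), `n_genes`,
#'   `genes` semicolon-joined).
#' @export
generate_catalog <- function(spec, db, annotation) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(db, "pathway_db"))
  set.seed(spec$seed + 1L)
  n_total <- spec$n_phenotypes_planted + spec$n_phenotypes_null
  planted <- rep(c(TRUE, FALSE),
                 c(spec$n_phenotypes_planted, spec$n_phenotypes_null))
  labels <- ifelse(planted,
                   sprintf("Planted phenotype %03d",
                           cumsum(planted) * planted),
                   sprintf("Null phenotype %03d",
                           cumsum(!planted) * !planted))
  ann_idx <- setNames(seq_len(nrow(annotation)), annotation$symbol)
  cat_rows <- vector("list", n_total)
  truth <- vector("list", n_total)
  snp_counter <- 0L
  for (i in seq_len(n_total)) {
    n_genes <- .pl_sample_range(spec$genes_per_phenotype_range[1L],
                                spec$genes_per_phenotype_range[2L], 1L)
    if (planted[i]) {
      causal <- sample(names(db$pathways), 1L)
      causal_set <- db$pathways[[causal]]
      k <- stats::rbinom(1L, n_genes, spec$signal_fraction)
      k <- min(k, length(causal_set), n_genes)
      from_causal <- causal_set[sample.int(length(causal_set), k)]
      others <- setdiff(db$universe, from_causal)
      rest <- others[sample.int(length(others), n_genes - k)]
      genes <- c(from_causal, rest)
    } else {
      causal <- "none"
      genes <- db$universe[sample.int(db$N, n_genes)]
    }
    genes <- sort(genes)
    m <- spec$sample_size_model
    ss <- max(50L, as.integer(round(m$intercept + m$slope * n_genes +
                                      stats::rnorm(1L, 0, m$sigma))))
    rows <- vector("list", length(genes) * spec$snps_per_gene)
    r <- 0L
    for (g in genes) {
      gi <- ann_idx[[g]]
      for (s in seq_len(spec$snps_per_gene)) {
        snp_counter <- snp_counter + 1L
        if (spec$messy && stats::runif(1L) < 0.2) {
          pos <- annotation$end[gi] + sample.int(2000L, 1L) - 1L
        } else {
          pos <- annotation$start[gi] +
            sample.int(annotation$end[gi] - annotation$start[gi], 1L) - 1L
        }
        r <- r + 1L
        rows[[r]] <- data.frame(
          trait = labels[i],
          snp = sprintf("rs%07d", snp_counter),
          chrom = annotation$chrom[gi],
          pos = pos,
          pvalue = 10^stats::runif(1L, -12, -5),
          reported_genes = g,
          sample_size = ss,
          study = sprintf("study_%03d", i),
          stringsAsFactors = FALSE
        )
      }
    }
    cat_rows[[i]] <- do.call(rbind, rows)
    truth[[i]] <- data.frame(
      phenotype = normalize_phenotype_label(labels[i]),
      causal_pathway = causal,
      n_genes = length(genes),
      genes = paste(genes, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  catalog <- do.call(rbind, cat_rows)
  rownames(catalog) <- NULL
  truth <- do.call(rbind, truth)
  categories <- data.frame(
    phenotype = normalize_phenotype_label(labels),
    category = ifelse(planted, spec$category_planted, spec$category_null),
    stringsAsFactors = FALSE
  )
  list(catalog = catalog, categories = categories, truth = truth)
}

#' Convert a generated catalog to the association-table layout
#'
#' In-memory equivalent of writing a generated catalog to TSV and
#' reading it back with [read_association_table()]: labels normalized,
#' reported genes as a list column. Generated p-values already sit below
#' the catalog threshold, so no rows are dropped.
#'
#' @param catalog The `catalog` data frame from [generate_catalog()].
#' @return Association data frame as returned by
#'   [read_association_table()].
#' @export
catalog_to_associations <- function(catalog) {
  out <- data.frame(
    phenotype = normalize_phenotype_label(catalog$trait),
    phenotype_raw = catalog$trait,
    snp = catalog$snp,
    chrom = catalog$chrom,
    pos = as.integer(catalog$pos),
    pvalue = catalog$pvalue,
    sample_size = as.integer(catalog$sample_size),
    study = catalog$study,
    stringsAsFactors = FALSE
  )
  out$reported_genes <- lapply(catalog$reported_genes, function(g) g)
  out
}
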