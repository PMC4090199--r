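#' Category-level clustering summaries
#'
#' Aggregates enrichment results by phenotype category: how many
#' phenotypes in the category have at least one significant pathway,
#' both overall and within bins of SNP count (phenotypes with more
#' associated SNPs have more chances to cluster). Also reports the total
#' number of significant associations in the category and the number of
#' unique pathways they involve — categories whose members repeatedly
#' hit the same pathways (association count far above the unique-pathway
#' count) share a molecular basis.
#'
#' @param results Enrichment results ([run_enrichment()]).
#' @param gene_sets `phenotype_gene_sets` table (supplies SNP counts;
#'   only testable phenotypes are summarized).
#' @param categories Named category vector ([read_category_map()]);
#'   phenotypes missing from it count under `"other"` with a warning.
#' @param snp_bins Increasing lower bin edges for SNP counts; default
#'   `c(2, 5, 10, 20)` gives bins 2-4, 5-9, 10-19, >=20.
#' @return Data frame with one row per (category, bin) plus an `"all"`
#'   bin per category: `category`, `snp_bin`, `n_phenotypes`,
#'   `n_with_any_significant`, `fraction`, `n_associations`,
#'   `n_unique_pathways`.
#' @export
category_fractions <- function(results, gene_sets, categories,
                               snp_bins = c(2, 5, 10, 20)) {
  stopifnot(length(snp_bins) >= 1L, !is.unsorted(snp_bins, strictly = TRUE))
  gs <- gene_sets[gene_sets$testable, , drop = FALSE]
  if (nrow(gs) == 0L) {
    return(data.frame(category = character(0), snp_bin = character(0),
                      n_phenotypes = integer(0),
                      n_with_any_significant = integer(0),
                      fraction = numeric(0), n_associations = integer(0),
                      n_unique_pathways = integer(0),
                      stringsAsFactors = FALSE))
  }
  cat_vec <- category_of(categories, gs$phenotype)
  sig <- results[results$significant, , drop = FALSE]
  any_sig <- gs$phenotype %in% sig$phenotype
  labels <- c(
    paste0(snp_bins[-length(snp_bins)], "-", snp_bins[-1L] - 1L),
    paste0(">=", snp_bins[length(snp_bins)])
  )
  bin_of <- labels[findInterval(gs$n_snps, snp_bins)]
  bin_of[gs$n_snps < snp_bins[1L]] <- paste0("<", snp_bins[1L])

  summarize <- function(idx, category, bin) {
    ph <- gs$phenotype[idx]
    s <- sig[sig$phenotype %in% ph, , drop = FALSE]
    data.frame(category = category, snp_bin = bin,
               n_phenotypes = length(idx),
               n_with_any_significant = sum(any_sig[idx]),
               fraction = mean(any_sig[idx]),
               n_associations = nrow(s),
               n_unique_pathways = length(unique(s$pathway_id)),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (cc in sort(unique(cat_vec))) {
    in_cat <- which(cat_vec == cc)
    out[[length(out) + 1L]] <- summarize(in_cat, cc, "all")
    for (b in unique(bin_of[in_cat])) {
      out[[length(out) + 1L]] <- summarize(
        in_cat[bin_of[in_cat] == b], cc, b)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlations among subjects, genes and pathways
#'
#' Per-phenotype Pearson correlations (two-sided tests) between the
#' number of study subjects (cases + controls pooled over the
#' phenotype's GWAS), the number of genes its SNPs implicate, and the
#' number of pathways significantly associated with it. Computed on raw
#' counts by default, mirroring how such correlations are usually
#' reported; `log_transform` applies `log1p` to all three variables for
#' exploration.
#'
#' @param gene_sets `phenotype_gene_sets` table (supplies `sample_size`
#'   and gene counts; only testable phenotypes enter).
#' @param results Enrichment results (supplies significant-pathway
#'   counts).
#' @param log_transform Apply `log1p` before correlating.
#' @return Data frame with columns `pair`
#'   (`subjects~pathways`, `subjects~genes`, `genes~pathways`),
#'   `pearson_r`, `p_value`, `n`, `note` (reason when a correlation is
#'   undefined; `NA` otherwise).
#' @export
correlation_table <- function(gene_sets, results, log_transform = FALSE) {
  gs <- gene_sets[gene_sets$testable, , drop = FALSE]
  sig <- results[results$significant, , drop = FALSE]
  n_path <- vapply(gs$phenotype, function(ph) {
    sum(sig$phenotype == ph)
  }, integer(1))
  vars <- list(subjects = as.numeric(gs$sample_size),
               genes = as.numeric(gs$n_genes),
               pathways = as.numeric(n_path))
  if (log_transform) vars <- lapply(vars, log1p)
  pairs <- list(c("subjects", "pathways"), c("subjects", "genes"),
                c("genes", "pathways"))
  rows <- lapply(pairs, function(p) {
    x <- vars[[p[1L]]]
    y <- vars[[p[2L]]]
    ok <- !is.na(x) & !is.na(y)
    nm <- paste(p, collapse = "~")
    if (sum(ok) < 3L) {
      return(data.frame(pair = nm, pearson_r = NA_real_,
                        p_value = NA_real_, n = sum(ok),
                        note = "fewer than 3 complete observations",
                        stringsAsFactors = FALSE))
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(pair = nm, pearson_r = NA_real_,
                        p_value = NA_real_, n = sum(ok),
                        note = "zero variance", stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                          alternative = "two.sided")
    data.frame(pair = nm, pearson_r = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok), note = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
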