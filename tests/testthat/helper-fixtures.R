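# Shared fixtures: all built in code, nothing read from disk.

# Two overlapping pathways over an 8-gene universe; the pooled tail at
# (k = 2, G = 2) has the closed form 21/56 = 0.375.
toy_db <- function() {
  pathway_db(list(P1 = paste0("g", 1:4), P2 = paste0("g", 3:8)))
}

# Random small database for property loops.
random_db <- function(P = 4, N = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- sprintf("g%03d", seq_len(N))
  sets <- lapply(seq_len(P), function(j) {
    sample(pool, sample(3:max(3, N %/% 2), 1))
  })
  names(sets) <- sprintf("P%02d", seq_len(P))
  pathway_db(sets)
}

# Construct a phenotype_gene_sets table directly from gene lists,
# bypassing SNP mapping (for enrichment-level tests).
make_gene_sets <- function(genes_list, db,
                           phenotypes = sprintf("ph%02d",
                                                seq_along(genes_list)),
                           sample_size = NA_integer_) {
  out <- data.frame(
    phenotype = phenotypes,
    n_snps = lengths(genes_list),
    n_genes = lengths(genes_list),
    G = vapply(genes_list,
               function(g) length(intersect(g, db$universe)), integer(1)),
    sample_size = rep_len(sample_size, length(genes_list)),
    testable = lengths(genes_list) >= 2L,
    stringsAsFactors = FALSE
  )
  out$all_genes <- lapply(genes_list, function(g) sort(unique(g)))
  out$universe_genes <- lapply(genes_list, function(g)
    intersect(sort(unique(g)), db$universe))
  class(out) <- c("phenotype_gene_sets", "data.frame")
  out
}

# Minimal enrichment-results table from a named list
# phenotype -> significant pathway ids (non-significant rows omitted;
# build_links only consumes significant rows).
make_sig_results <- function(sig_sets) {
  rows <- lapply(names(sig_sets), function(ph) {
    ids <- sig_sets[[ph]]
    if (length(ids) == 0L) return(NULL)
    data.frame(phenotype = ph, pathway_id = ids, pathway_name = ids,
               G = NA_integer_, dp = 2L, p_emp = 0.01, significant = TRUE,
               pool_reps = 1000L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(phenotype = character(0), pathway_id = character(0),
                      pathway_name = character(0), G = integer(0),
                      dp = integer(0), p_emp = numeric(0),
                      significant = logical(0), pool_reps = integer(0),
                      stringsAsFactors = FALSE)
  }
  out
}

# Tiny gene annotation on one chromosome.
tiny_annotation <- function() {
  data.frame(
    symbol = c("GENE1", "GENE2", "GENE3"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100L, 320L, 0L),
    end = c(200L, 400L, 150L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE
  )
}

# Write an association-table fixture; `rows` is a character vector of
# tab-joined data lines under the default header.
write_catalog_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste(c("trait", "snp", "chrom", "pos", "pvalue",
                    "reported_genes", "sample_size", "study"),
                  collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

catalog_row <- function(trait, snp = "rs1", chrom = "chr1", pos = 150,
                        pvalue = 1e-8, genes = "", n = 1000,
                        study = "s1") {
  paste(trait, snp, chrom, pos, pvalue, genes, n, study, sep = "\t")
}
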