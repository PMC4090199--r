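#' Map a single SNP to gene symbols
#'
#' A phenotype SNP is assigned to the gene in which, or near which, it
#' occurs. In `"coordinate"` mode the SNP is assigned to every gene whose
#' interval contains its position; failing that, to the single nearest
#' gene within `window` base pairs (equidistant flanking genes are broken
#' deterministically toward the lexicographically smaller symbol); failing
#' that, to no gene. In `"reported"` mode the catalog's curated gene
#' column is returned verbatim, with intergenic placeholders such as
#' `"GENE1 - GENE2"` split into both genes (or dropped).
#'
#' Distances use the internal 0-based half-open convention: a SNP at
#' position `p` upstream of a gene starting at `s` is `s - p` away; one
#' downstream of a gene ending at `e` (exclusive) is `p - e` away.
#'
#' @param snp A list or one-row data frame with elements `chrom`, `pos`
#'   and (for reported mode) `reported_genes`.
#' @param annotation Gene-interval data frame from [read_gene_intervals()].
#' @param window Maximum distance in base pairs for nearest-gene
#'   assignment (default 20000). Must be non-negative.
#' @param mode `"coordinate"` or `"reported"`.
#' @param split_intergenic In reported mode, split `"A - B"` placeholders
#'   into both genes (`TRUE`, default) or drop them (`FALSE`).
#' @return Character vector of gene symbols (possibly empty). The
#'   attribute `"distance"` carries the assignment distance in bp
#'   (0 for containment or reported mode).
#' @export
map_snp_to_genes <- function(snp, annotation, window = 20000,
                             mode = c("coordinate", "reported"),
                             split_intergenic = TRUE) {
  mode <- match.arg(mode)
  if (mode == "reported") {
    genes <- snp$reported_genes
    if (is.list(genes)) genes <- genes[[1L]]
    genes <- .pl_clean_reported(genes, split_intergenic)
    return(structure(genes, distance = if (length(genes)) 0 else NA_real_))
  }
  if (!is.numeric(window) || window < 0) stop("window must be non-negative")
  chrom <- as.character(snp$chrom)
  pos <- as.numeric(snp$pos)
  ann <- annotation[annotation$chrom == chrom, , drop = FALSE]
  if (nrow(ann) == 0L) {
    warning("chromosome '", chrom, "' absent from annotation")
    return(structure(character(0), distance = NA_real_))
  }
  contained <- ann$start <= pos & pos < ann$end
  if (any(contained)) {
    return(structure(sort(ann$symbol[contained]), distance = 0))
  }
  d <- ifelse(pos < ann$start, ann$start - pos, pos - ann$end)
  dmin <- min(d)
  if (dmin > window) {
    return(structure(character(0), distance = NA_real_))
  }
  nearest <- sort(ann$symbol[d == dmin])[1L]
  structure(nearest, distance = dmin)
}

# internal: clean a reported-genes vector; handle intergenic placeholders
.pl_clean_reported <- function(genes, split_intergenic = TRUE) {
  if (length(genes) == 0L) return(character(0))
  out <- character(0)
  for (g in genes) {
    g <- trimws(g)
    if (!nzchar(g) || toupper(g) %in% c("NR", "INTERGENIC", "NA")) next
    if (grepl(" - ", g, fixed = TRUE)) {
      if (split_intergenic) {
        out <- c(out, trimws(strsplit(g, " - ", fixed = TRUE)[[1L]]))
      }
    } else {
      out <- c(out, g)
    }
  }
  sort(unique(out[nzchar(out)]))
}

#' Build per-phenotype gene sets from SNP associations
#'
#' Groups threshold-filtered, label-normalized associations by phenotype,
#' maps each distinct SNP to genes, and deduplicates the genes (several
#' SNPs in one gene count that gene once). `G` is the number of a
#' phenotype's genes that appear in at least one pathway of `db` — the
#' draw size used by the resampling null. Phenotypes with fewer than two
#' distinct mapped genes cannot show clustering across genes and are
#' flagged untestable; they are kept in the table but excluded from
#' downstream scoring.
#'
#' Per-phenotype sample size is the sum of `sample_size` over distinct
#' `study` ids when a study column is present (all GWAS of the phenotype
#' pooled), otherwise the maximum row value.
#'
#' @param associations Data frame from [read_association_table()].
#' @param annotation Gene intervals (required for coordinate mode).
#' @param db A [pathway_db()].
#' @param window,mode,split_intergenic Passed to [map_snp_to_genes()].
#' @param audit If `TRUE`, attach a per-SNP audit table (phenotype, SNP,
#'   mapped genes, mode, distance) as attribute `"audit"`.
#' @return A data frame of class `phenotype_gene_sets` with columns
#'   `phenotype`, `n_snps` (distinct SNPs), `n_genes` (=|all_genes|),
#'   `G` (=|universe_genes|), `sample_size`, `testable`, and list columns
#'   `all_genes`, `universe_genes`.
#' @export
build_phenotype_gene_sets <- function(associations, annotation = NULL,
                                      db, window = 20000,
                                      mode = c("reported", "coordinate"),
                                      split_intergenic = TRUE,
                                      audit = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "pathway_db"))
  if (mode == "coordinate" && is.null(annotation)) {
    stop("coordinate mode requires a gene annotation")
  }
  empty <- .pl_empty_gene_sets()
  if (nrow(associations) == 0L) return(empty)

  phenos <- unique(associations$phenotype)
  rows <- vector("list", length(phenos))
  audit_rows <- if (audit) list() else NULL
  for (i in seq_along(phenos)) {
    ph <- phenos[i]
    sub <- associations[associations$phenotype == ph, , drop = FALSE]
    # one mapping per distinct SNP id
    sub_u <- sub[!duplicated(sub$snp), , drop = FALSE]
    genes <- character(0)
    for (k in seq_len(nrow(sub_u))) {
      hit <- map_snp_to_genes(sub_u[k, ], annotation, window = window,
                              mode = mode,
                              split_intergenic = split_intergenic)
      genes <- c(genes, hit)
      if (audit) {
        audit_rows[[length(audit_rows) + 1L]] <- data.frame(
          phenotype = ph, snp = sub_u$snp[k],
          mapped_genes = paste(hit, collapse = ";"),
          mode = mode,
          distance = if (length(hit)) attr(hit, "distance") else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    all_genes <- sort(unique(genes))
    universe_genes <- intersect(all_genes, db$universe)
    rows[[i]] <- list(
      phenotype = ph,
      n_snps = nrow(sub_u),
      n_genes = length(all_genes),
      G = length(universe_genes),
      sample_size = .pl_sample_size(sub_u),
      testable = length(all_genes) >= 2L,
      all_genes = list(all_genes),
      universe_genes = list(universe_genes)
    )
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(phenotype = r$phenotype, n_snps = r$n_snps,
               n_genes = r$n_genes, G = r$G, sample_size = r$sample_size,
               testable = r$testable, stringsAsFactors = FALSE)
  }))
  out$all_genes <- lapply(rows, function(r) r$all_genes[[1L]])
  out$universe_genes <- lapply(rows, function(r) r$universe_genes[[1L]])
  rownames(out) <- NULL
  class(out) <- c("phenotype_gene_sets", "data.frame")
  if (audit) attr(out, "audit") <- do.call(rbind, audit_rows)
  out
}

# internal: empty phenotype_gene_sets table
.pl_empty_gene_sets <- function() {
  out <- data.frame(phenotype = character(0), n_snps = integer(0),
                    n_genes = integer(0), G = integer(0),
                    sample_size = integer(0), testable = logical(0),
                    stringsAsFactors = FALSE)
  out$all_genes <- list()
  out$universe_genes <- list()
  class(out) <- c("phenotype_gene_sets", "data.frame")
  out
}

# internal: aggregate sample size over a phenotype's rows (distinct SNPs).
# Sum over distinct studies when study ids exist; else max (single-study
# fallback).
.pl_sample_size <- function(rows) {
  ss <- rows$sample_size
  if (all(is.na(ss))) return(NA_integer_)
  if (!is.null(rows$study) && any(!is.na(rows$study))) {
    first <- rows[!duplicated(rows$study), , drop = FALSE]
    return(as.integer(sum(first$sample_size, na.rm = TRUE)))
  }
  as.integer(max(ss, na.rm = TRUE))
}

#' Write / read a phenotype gene-set table
#'
#' Serializes the output of [build_phenotype_gene_sets()] as TSV (gene
#' lists semicolon-joined) so pipeline stages can be run independently.
#'
#' @param gene_sets A `phenotype_gene_sets` data frame.
#' @param path File path.
#' @param params Optional named list recorded in the `#` header.
#' @return The path (writer, invisibly) or the table (reader).
#' @export
write_gene_sets <- function(gene_sets, path, params = NULL) {
  .pl_write_tsv(gene_sets, path, params)
}

#' @rdname write_gene_sets
#' @export
read_gene_sets <- function(path) {
  df <- .pl_read_tsv(path, list_cols = c("all_genes", "universe_genes"))
  df$testable <- as.logical(df$testable)
  class(df) <- c("phenotype_gene_sets", "data.frame")
  df
}
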