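#' Normalize a phenotype label
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to
#' a single space, and case-folds to lower case, so that different
#' GWAS-catalog spellings of the same trait merge. Idempotent.
#'
#' @param x Character vector of raw labels.
#' @return Character vector of normalized labels.
#' @examples
#' normalize_phenotype_label(c("Celiac disease", "celiac  Disease "))
#' @export
normalize_phenotype_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

# internal: default column-name mapping for association tables
.pl_default_columns <- function() {
  list(phenotype = "trait", snp = "snp", chrom = "chrom", pos = "pos",
       pvalue = "pvalue", genes = "reported_genes",
       sample_size = "sample_size", study = "study")
}

#' Read a GWAS-catalog-style association table
#'
#' Reads a tab-separated table of phenotype-SNP associations, normalizes
#' phenotype labels (so entries of the same phenotype merge), and drops
#' rows whose association p-value exceeds the catalog significance
#' threshold. Rows are returned in file order.
#'
#' @param path Path to a TSV file with a header. Lines starting with `#`
#'   are ignored.
#' @param pvalue_threshold Retain rows with association p-value at or
#'   below this value (default `1e-5`, the usual catalog inclusion
#'   threshold).
#' @param columns Named list mapping the logical column roles
#'   `phenotype`, `snp`, `chrom`, `pos`, `pvalue` (mandatory) and
#'   `genes`, `sample_size`, `study` (optional) to the column names used
#'   in the file. Partial lists are merged over the defaults
#'   (`trait`, `snp`, `chrom`, `pos`, `pvalue`, `reported_genes`,
#'   `sample_size`, `study`).
#' @param on_bad_row `"fail"` (default) stops at the first row whose
#'   position or p-value does not parse, reporting its line number;
#'   `"skip"` drops such rows with a warning.
#' @param synonyms Optional two-column data frame (or path to a
#'   two-column TSV) mapping phenotype labels to canonical labels;
#'   applied after normalization, both sides normalized.
#' @param one_based If `TRUE`, positions in the file are 1-based and are
#'   converted to the package's internal 0-based convention on read.
#' @return A data frame with columns `phenotype` (normalized),
#'   `phenotype_raw`, `snp`, `chrom`, `pos` (integer, 0-based), `pvalue`,
#'   `reported_genes` (list column), `sample_size`, `study`.
#' @export
read_association_table <- function(path, pvalue_threshold = 1e-5,
                                   columns = list(),
                                   on_bad_row = c("fail", "skip"),
                                   synonyms = NULL,
                                   one_based = FALSE) {
  on_bad_row <- match.arg(on_bad_row)
  stopifnot(is.numeric(pvalue_threshold), pvalue_threshold > 0)
  cols <- utils::modifyList(.pl_default_columns(), columns)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE, quote = "",
                           colClasses = "character")
  for (role in c("phenotype", "snp", "chrom", "pos", "pvalue")) {
    if (!(cols[[role]] %in% names(raw))) {
      stop("association table is missing mandatory column '", cols[[role]],
           "' (role: ", role, ") in ", path)
    }
  }
  n <- nrow(raw)
  # line numbers in the original file: header is line 1
  line_no <- seq_len(n) + 1L
  pos <- suppressWarnings(as.numeric(raw[[cols$pos]]))
  pval <- suppressWarnings(as.numeric(raw[[cols$pvalue]]))
  bad <- is.na(pos) | is.na(pval) | pos < (if (one_based) 1 else 0) |
    pval <= 0 | pval > 1
  if (any(bad)) {
    msg <- paste0("unparseable position or p-value at line ",
                  paste(line_no[bad][seq_len(min(5L, sum(bad)))], collapse = ", "),
                  if (sum(bad) > 5L) " ..." else "")
    if (on_bad_row == "fail") stop(msg) else warning(msg, "; rows skipped")
  }
  keep <- !bad
  genes <- if (cols$genes %in% names(raw)) raw[[cols$genes]] else rep("", n)
  sample_size <- if (cols$sample_size %in% names(raw)) {
    suppressWarnings(as.integer(round(as.numeric(raw[[cols$sample_size]]))))
  } else rep(NA_integer_, n)
  study <- if (cols$study %in% names(raw)) raw[[cols$study]] else rep(NA_character_, n)

  out <- data.frame(
    phenotype = normalize_phenotype_label(raw[[cols$phenotype]]),
    phenotype_raw = raw[[cols$phenotype]],
    snp = raw[[cols$snp]],
    chrom = raw[[cols$chrom]],
    pos = as.integer(round(pos)) - if (one_based) 1L else 0L,
    pvalue = pval,
    sample_size = sample_size,
    study = study,
    stringsAsFactors = FALSE
  )
  out$reported_genes <- lapply(genes, .pl_split_genes)
  out <- out[keep & pval <= pvalue_threshold, , drop = FALSE]
  empty_lab <- !nzchar(out$phenotype)
  if (any(empty_lab)) stop("empty phenotype label after normalization")
  if (!is.null(synonyms)) {
    if (is.character(synonyms)) synonyms <- utils::read.delim(
      synonyms, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
      comment.char = "#", quote = "")
    from <- normalize_phenotype_label(synonyms[[1L]])
    to <- normalize_phenotype_label(synonyms[[2L]])
    hit <- match(out$phenotype, from)
    out$phenotype[!is.na(hit)] <- to[hit[!is.na(hit)]]
  }
  rownames(out) <- NULL
  out
}

# internal: split a reported-genes cell on commas/semicolons; "" -> empty
.pl_split_genes <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  trimws(strsplit(x, "[,;]")[[1L]])
}

#' Read gene intervals from a BED file
#'
#' Uses the standard BED conventions (0-based half-open); the name field
#' carries the gene symbol. Duplicate gene symbols in the annotation are
#' an error, since the mapper requires symbols to be unique.
#'
#' @param path Path to a BED file (at least 4 columns).
#' @return A data frame with columns `symbol`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand` (`+`, `-` or `*`).
#' @export
read_gene_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  symbol <- gr$name
  if (is.null(symbol)) stop("BED file has no name column: ", path)
  if (anyDuplicated(symbol)) {
    stop("duplicate gene symbol in annotation: ",
         symbol[duplicated(symbol)][1L])
  }
  data.frame(
    symbol = symbol,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write gene intervals to a BED file
#'
#' @param intervals Data frame as returned by [read_gene_intervals()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_intervals <- function(intervals, path) {
  stopifnot(all(c("symbol", "chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end)) stop("interval with start >= end")
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end),
    strand = strand,
    name = intervals$symbol,
    score = 0L
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a phenotype-to-category map
#'
#' Two-column TSV (phenotype label, category). Labels are normalized with
#' [normalize_phenotype_label()].
#'
#' @param path Path to the TSV (header required).
#' @return Named character vector: `category[phenotype]`.
#' @export
read_category_map <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  if (ncol(tab) < 2L) stop("category map must have at least 2 columns")
  setNames(as.character(tab[[2L]]), normalize_phenotype_label(tab[[1L]]))
}

#' Look up phenotype categories, defaulting to "other"
#'
#' Phenotypes absent from the map are assigned `"other"` with a warning,
#' mirroring the catch-all category for unclassifiable phenotypes.
#'
#' @param categories Named character vector from [read_category_map()].
#' @param phenotypes Character vector of normalized phenotype labels.
#' @return Character vector of categories, one per phenotype.
#' @export
category_of <- function(categories, phenotypes) {
  out <- unname(categories[phenotypes])
  missing <- is.na(out)
  if (any(missing)) {
    warning(sum(missing), " phenotype(s) missing from category map; ",
            "assigned 'other'")
    out[missing] <- "other"
  }
  out
}

# internal: write a data frame as TSV with a '#' provenance header.
# List columns are joined with ';'. No timestamps: outputs must be
# byte-identical across reruns with the same seed.
.pl_write_tsv <- function(df, path, params = NULL) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) paste(v, collapse = ";"), "")
    }
  }
  header <- paste0("# pathlink ", .pl_version(),
                   if (length(params)) paste0(" | ",
                     paste(names(params), unlist(params), sep = "=",
                           collapse = " ")) else "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: read back a TSV written by .pl_write_tsv
.pl_read_tsv <- function(path, list_cols = character(0)) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE, quote = "")
  for (col in intersect(list_cols, names(df))) {
    df[[col]] <- lapply(df[[col]], function(x) {
      if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1L]]
    })
  }
  df
}

#' Write / read an enrichment results table
#'
#' TSV with a `#` provenance header naming the tool version and run
#' parameters. `read_results_table(write_results_table(x))` reproduces
#' `x`.
#'
#' @param results Data frame of enrichment results (see [run_enrichment()]).
#' @param path File path.
#' @param params Optional named list of run parameters recorded in the
#'   header line.
#' @return The path (writer, invisibly) or the data frame (reader).
#' @export
write_results_table <- function(results, path, params = NULL) {
  .pl_write_tsv(results, path, params)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  df <- .pl_read_tsv(path)
  if ("significant" %in% names(df)) df$significant <- as.logical(df$significant)
  df
}

#' Write / read a phenotype-phenotype edge list
#'
#' Columns: `phenotype_a`, `phenotype_b`, `weight`, `shared_pathways`
#' (semicolon-joined pathway ids in the file, a list column in memory).
#'
#' @param links Data frame of links (see [build_links()]).
#' @param path File path.
#' @param params Optional named list recorded in the `#` header.
#' @return The path (writer, invisibly) or the data frame (reader).
#' @export
write_edge_list <- function(links, path, params = NULL) {
  .pl_write_tsv(links, path, params)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- .pl_read_tsv(path, list_cols = "shared_pathways")
  class(df) <- c("phenotype_links", "data.frame")
  df
}
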