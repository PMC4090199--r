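#' Construct a pathway database
#'
#' A pathway database holds named gene sets (pathways) together with their
#' gene universe, defined as the exact union of all member genes. The
#' universe is the population from which null gene sets are drawn when
#' scoring phenotype-pathway clustering.
#'
#' @param sets Named list of character vectors; one entry per pathway id.
#'   Genes are deduplicated within each pathway. Empty pathways and
#'   duplicated pathway ids are errors.
#' @param pathway_names Optional character vector of human-readable pathway
#'   names, recycled/matched by pathway id; defaults to the ids.
#' @return An object of class `pathway_db`: a list with elements
#'   `pathways` (named list of character vectors), `pathway_names` (named
#'   character), `universe` (sorted character vector), `P` (number of
#'   pathways) and `N` (universe size).
#' @examples
#' db <- pathway_db(list(P1 = c("g1", "g2"), P2 = c("g2", "g3")))
#' db$N  # 3
#' @export
pathway_db <- function(sets, pathway_names = NULL) {
  if (length(sets) == 0L) stop("pathway database must contain at least one pathway")
  ids <- names(sets)
  if (is.null(ids) || any(!nzchar(ids))) stop("every pathway must have a non-empty id")
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id: ", ids[duplicated(ids)][1L])
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  empty <- lengths(sets) == 0L
  if (any(empty)) stop("empty pathway: ", ids[empty][1L])
  if (is.null(pathway_names)) {
    pathway_names <- setNames(ids, ids)
  } else {
    pathway_names <- setNames(as.character(pathway_names), ids)
  }
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  structure(
    list(pathways = sets, pathway_names = pathway_names,
         universe = universe, P = length(sets), N = length(universe)),
    class = "pathway_db"
  )
}

#' @export
print.pathway_db <- function(x, ...) {
  cat("pathway_db: ", x$P, " pathways, ", x$N, " genes in universe\n", sep = "")
  sizes <- lengths(x$pathways)
  cat("  pathway sizes: ", min(sizes), "-", max(sizes),
      " (median ", stats::median(sizes), ")\n", sep = "")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' GMT is the tab-separated gene-set exchange format: one pathway per line,
#' `id<TAB>description<TAB>gene1<TAB>gene2...`. Genes duplicated within a
#' line are collapsed; a line with fewer than three fields or a repeated
#' pathway id is a format error reported with its line number.
#'
#' @param path Path to a GMT file.
#' @return A [pathway_db()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("GMT format error at line ", bad[1L],
         ": expected at least 3 tab-separated fields")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate pathway id in GMT: ", dup)
  }
  descs <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  pathway_db(sets, pathway_names = descs)
}

#' Write a pathway database to a GMT file
#'
#' @param db A [pathway_db()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  lines <- vapply(names(db$pathways), function(id) {
    paste(c(id, db$pathway_names[[id]], db$pathways[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
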