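#' Build phenotype-phenotype links from shared significant pathways
#'
#' Two phenotypes are linked when at least one pathway is significantly
#' associated with both; the link weight is the number of such shared
#' pathways. Pairs are canonically ordered (`phenotype_a <
#' phenotype_b`), so the output is independent of input row order.
#'
#' @param results Enrichment results data frame ([run_enrichment()])
#'   carrying a logical `significant` column.
#' @return Data frame of class `phenotype_links` with columns
#'   `phenotype_a`, `phenotype_b`, `weight` and list column
#'   `shared_pathways`, sorted by the pair labels.
#' @export
build_links <- function(results) {
  stopifnot(all(c("phenotype", "pathway_id", "significant") %in%
                  names(results)))
  sig <- results[results$significant, , drop = FALSE]
  empty <- data.frame(phenotype_a = character(0),
                      phenotype_b = character(0), weight = integer(0),
                      stringsAsFactors = FALSE)
  empty$shared_pathways <- list()
  class(empty) <- c("phenotype_links", "data.frame")
  if (nrow(sig) == 0L) return(empty)
  sets <- split(sig$pathway_id, sig$phenotype)
  phenos <- sort(names(sets))
  if (length(phenos) < 2L) return(empty)
  pairs <- utils::combn(phenos, 2L)
  shared <- lapply(seq_len(ncol(pairs)), function(j) {
    sort(intersect(sets[[pairs[1L, j]]], sets[[pairs[2L, j]]]))
  })
  keep <- lengths(shared) >= 1L
  out <- data.frame(phenotype_a = pairs[1L, keep],
                    phenotype_b = pairs[2L, keep],
                    weight = lengths(shared)[keep],
                    stringsAsFactors = FALSE)
  out$shared_pathways <- shared[keep]
  rownames(out) <- NULL
  class(out) <- c("phenotype_links", "data.frame")
  out
}

#' Threshold a link set into a phenotype network
#'
#' Retains links whose weight (number of shared significant pathways)
#' meets the threshold and reports connected components. Threshold 1
#' gives the full shared-pathway network; higher thresholds (e.g. 3)
#' keep only strongly co-associated phenotype pairs.
#'
#' @param links A `phenotype_links` data frame ([build_links()]).
#' @param threshold Minimum link weight (integer >= 1).
#' @param categories Optional named category vector
#'   ([read_category_map()]); attached as a node attribute for styling
#'   only, never used in computation.
#' @return Object of class `phenotype_network`: list with `graph`
#'   (igraph, weighted, undirected), `edges` (retained links),
#'   `threshold`, `components` (component sizes, decreasing) and
#'   `membership` (named component id per node).
#' @export
filter_network <- function(links, threshold = 1, categories = NULL) {
  if (threshold < 1) stop("threshold must be >= 1")
  edges <- links[links$weight >= threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$phenotype_a, to = edges$phenotype_b,
               weight = edges$weight, stringsAsFactors = FALSE),
    directed = FALSE
  )
  if (!is.null(categories) && igraph::vcount(g) > 0L) {
    igraph::V(g)$category <- unname(
      ifelse(is.na(categories[igraph::V(g)$name]), "other",
             categories[igraph::V(g)$name]))
  }
  comp <- igraph::components(g)
  structure(
    list(graph = g, edges = edges, threshold = threshold,
         components = sort(comp$csize, decreasing = TRUE),
         membership = comp$membership),
    class = "phenotype_network"
  )
}

#' @export
print.phenotype_network <- function(x, ...) {
  cat("phenotype_network: ", igraph::vcount(x$graph), " phenotypes, ",
      nrow(x$edges), " links (weight >= ", x$threshold, ")\n", sep = "")
  if (length(x$components)) {
    cat("  component sizes: ", paste(x$components, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Export the significant phenotype-pathway bipartite graph
#'
#' One edge per significant phenotype-pathway association. Phenotypes
#' and pathways form the two node classes (igraph `type` attribute:
#' `FALSE` for phenotypes, `TRUE` for pathways).
#'
#' @param results Enrichment results with a `significant` column.
#' @param path Optional output file; written as TSV (edge list) or
#'   GraphML depending on `format`.
#' @param format `"tsv"` or `"graphml"`.
#' @return Invisibly, a list with `edges` (data frame: `phenotype`,
#'   `pathway_id`, `dp`, `p_emp`) and `graph` (bipartite igraph).
#' @export
export_bipartite <- function(results, path = NULL,
                             format = c("tsv", "graphml")) {
  format <- match.arg(format)
  sig <- results[results$significant, , drop = FALSE]
  edges <- data.frame(phenotype = sig$phenotype,
                      pathway_id = sig$pathway_id,
                      dp = sig$dp, p_emp = sig$p_emp,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("phenotype", "pathway_id")], directed = FALSE)
  if (igraph::vcount(g) > 0L) {
    igraph::V(g)$type <- igraph::V(g)$name %in% edges$pathway_id
  }
  if (!is.null(path)) {
    if (format == "tsv") {
      .pl_write_tsv(edges, path)
    } else {
      igraph::write_graph(g, path, format = "graphml")
    }
  }
  invisible(list(edges = edges, graph = g))
}

#' Write a phenotype network as GraphML
#'
#' @param network A `phenotype_network` ([filter_network()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "phenotype_network"))
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}
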