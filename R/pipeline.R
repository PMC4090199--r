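#' Build a validated pipeline run configuration
#'
#' Collects every tunable of the pipeline — file locations, the SNP-gene
#' window, the significance rule, replicate counts, the network
#' threshold and the master seed — into one validated object shared by
#' all stages. Per-stage seeds are derived deterministically from the
#' master seed (stage index mixed through a fixed linear-congruential
#' step), so each stage is independently reproducible and rerunning any
#' stage with the same config gives byte-identical files.
#'
#' @param out_dir Directory for all stage outputs (created if needed).
#' @param seed Master integer seed.
#' @param synthetic A [synthetic_spec()] used by the `simulate` stage
#'   (its own seed is replaced by a derived stage seed).
#' @param mapping_mode `"coordinate"` or `"reported"` SNP-gene mapping.
#' @param window Nearest-gene window in bp.
#' @param pvalue_threshold Catalog inclusion threshold.
#' @param alpha,min_dp Significance rule for enrichment.
#' @param reps Inner resampling replicates per null pool.
#' @param outer_reps Outer replicates of the global-null simulation.
#' @param network_threshold Minimum shared-pathway count for a
#'   phenotype-phenotype link to be kept in the thresholded network.
#' @param null_mode,smooth,fresh_inner Variant switches, see
#'   [run_enrichment()] and [simulate_global_null()].
#' @param columns Column-name mapping for external catalogs (see
#'   [read_association_table()]).
#' @return Object of class `run_config` (validated list).
#' @export
run_config <- function(out_dir, seed = 1, synthetic = synthetic_spec(),
                       mapping_mode = c("coordinate", "reported"),
                       window = 20000, pvalue_threshold = 1e-5,
                       alpha = 0.05, min_dp = 2, reps = 1000,
                       outer_reps = 200, network_threshold = 1,
                       null_mode = "pooled", smooth = FALSE,
                       fresh_inner = FALSE, columns = list()) {
  mapping_mode <- match.arg(mapping_mode)
  stopifnot(is.numeric(seed), length(seed) == 1L,
            inherits(synthetic, "synthetic_spec"),
            window >= 0, pvalue_threshold > 0,
            alpha > 0, alpha <= 1, min_dp >= 0,
            reps >= 1, outer_reps >= 1, network_threshold >= 1)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              synthetic = synthetic, mapping_mode = mapping_mode,
              window = window, pvalue_threshold = pvalue_threshold,
              alpha = alpha, min_dp = min_dp, reps = as.integer(reps),
              outer_reps = as.integer(outer_reps),
              network_threshold = network_threshold,
              null_mode = null_mode, smooth = smooth,
              fresh_inner = fresh_inner, columns = columns)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `synthetic` may be a
#' nested mapping of [synthetic_spec()] arguments. Unset keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after the file (e.g. `seed = 7`).
#' @return A [run_config()].
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    y$synthetic <- do.call(synthetic_spec, y$synthetic)
  }
  y <- utils::modifyList(y, list(...))
  do.call(run_config, y)
}

# internal: canonical stage file paths
.pl_paths <- function(cfg) {
  d <- cfg$out_dir
  list(
    gmt = file.path(d, "pathways.gmt"),
    bed = file.path(d, "genes.bed"),
    catalog = file.path(d, "catalog.tsv"),
    categories = file.path(d, "categories.tsv"),
    truth = file.path(d, "truth.tsv"),
    gene_sets = file.path(d, "gene_sets.tsv"),
    audit = file.path(d, "mapping_audit.tsv"),
    results = file.path(d, "results.tsv"),
    null_totals = file.path(d, "global_null_totals.tsv"),
    null_summary = file.path(d, "global_null_summary.tsv"),
    links = file.path(d, "links.tsv"),
    bipartite = file.path(d, "bipartite.tsv"),
    graphml = file.path(d, "network.graphml"),
    category_summary = file.path(d, "category_summary.tsv"),
    correlations = file.path(d, "correlations.tsv"),
    report = file.path(d, "run_report.md")
  )
}

# internal: require stage inputs, naming the producing stage when absent
.pl_require <- function(paths, stage) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file ", missing[1L],
         "; run stage '", stage, "' first")
  }
}

# stage seeds: fixed tags per stage so insertion of stages never
# renumbers the others
.pl_stage_tags <- c(simulate = 1L, map = 2L, enrich = 3L,
                    globalnull = 4L, network = 5L, summarize = 6L)

#' Run pipeline stages
#'
#' Executes the pipeline as file-to-file stages sharing one
#' configuration: `simulate` writes a synthetic pathway database (GMT),
#' gene annotation (BED), catalog, category map and ground truth; `map`
#' builds per-phenotype gene sets from the catalog; `enrich` scores all
#' phenotype-pathway pairs against the pooled resampling null;
#' `globalnull` runs the pseudo-phenotype multiple-testing calibration;
#' `network` builds the shared-pathway links, the thresholded network
#' (GraphML) and the bipartite export; `summarize` writes category and
#' correlation summaries plus a run report. `"all"` chains every stage.
#' Each stage reads only its predecessors' files, so running stages
#' one-by-one equals one `"all"` run.
#'
#' @param cfg A [run_config()].
#' @param stages Character vector of stage names, or `"all"`.
#' @return Invisibly, the list of output paths.
#' @export
run_pipeline <- function(cfg, stages = "all") {
  stopifnot(inherits(cfg, "run_config"))
  all_stages <- names(.pl_stage_tags)
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage: ", bad[1L])
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- .pl_paths(cfg)
  for (st in all_stages[all_stages %in% stages]) {
    switch(st,
      simulate = .pl_stage_simulate(cfg, p),
      map = .pl_stage_map(cfg, p),
      enrich = .pl_stage_enrich(cfg, p),
      globalnull = .pl_stage_globalnull(cfg, p),
      network = .pl_stage_network(cfg, p),
      summarize = .pl_stage_summarize(cfg, p))
  }
  invisible(p)
}

.pl_stage_simulate <- function(cfg, p) {
  spec <- cfg$synthetic
  spec$seed <- .pl_child_seed(cfg$seed, .pl_stage_tags[["simulate"]])
  gen <- generate_pathway_db(spec)
  cat_out <- generate_catalog(spec, gen$db, gen$annotation)
  write_gmt(gen$db, p$gmt)
  write_gene_intervals(gen$annotation, p$bed)
  .pl_write_tsv(cat_out$catalog, p$catalog, params = list(seed = spec$seed))
  .pl_write_tsv(cat_out$categories, p$categories)
  .pl_write_tsv(cat_out$truth, p$truth)
  invisible(NULL)
}

.pl_stage_map <- function(cfg, p) {
  .pl_require(c(p$catalog, p$bed, p$gmt), "simulate")
  assoc <- read_association_table(p$catalog,
                                  pvalue_threshold = cfg$pvalue_threshold,
                                  columns = cfg$columns)
  ann <- read_gene_intervals(p$bed)
  db <- read_gmt(p$gmt)
  gs <- build_phenotype_gene_sets(assoc, ann, db, window = cfg$window,
                                  mode = cfg$mapping_mode, audit = TRUE)
  write_gene_sets(gs, p$gene_sets,
                  params = list(mode = cfg$mapping_mode,
                                window = cfg$window))
  .pl_write_tsv(attr(gs, "audit"), p$audit)
  invisible(NULL)
}

.pl_stage_enrich <- function(cfg, p) {
  .pl_require(c(p$gene_sets, p$gmt), "map")
  gs <- read_gene_sets(p$gene_sets)
  db <- read_gmt(p$gmt)
  res <- run_enrichment(gs, db, reps = cfg$reps, alpha = cfg$alpha,
                        min_dp = cfg$min_dp,
                        seed = .pl_child_seed(cfg$seed,
                                              .pl_stage_tags[["enrich"]]),
                        null_mode = cfg$null_mode, smooth = cfg$smooth)
  write_results_table(res, p$results,
                      params = list(reps = cfg$reps, alpha = cfg$alpha,
                                    min_dp = cfg$min_dp,
                                    null_mode = cfg$null_mode))
  invisible(NULL)
}

.pl_stage_globalnull <- function(cfg, p) {
  .pl_require(c(p$gene_sets, p$results, p$gmt), "enrich")
  gs <- read_gene_sets(p$gene_sets)
  db <- read_gmt(p$gmt)
  res <- read_results_table(p$results)
  sizes <- gs$G[gs$testable & gs$G >= 2]
  # share the enrich-stage seed so the calibration judges pseudo counts
  # against the same inner pools (same per-G critical counts) as the
  # real enrichment run
  reps <- simulate_global_null(
    sizes, db, outer_reps = cfg$outer_reps, inner_reps = cfg$reps,
    alpha = cfg$alpha, min_dp = cfg$min_dp,
    seed = .pl_child_seed(cfg$seed, .pl_stage_tags[["enrich"]]),
    fresh_inner = cfg$fresh_inner)
  observed <- sum(res$significant)
  smry <- summarize_global_null(observed, reps)
  .pl_write_tsv(reps, p$null_totals,
                params = list(outer_reps = cfg$outer_reps,
                              inner_reps = cfg$reps))
  .pl_write_tsv(
    data.frame(observed_total = smry$observed_total,
               null_median = smry$null_median,
               null_mean = smry$null_mean, null_sd = smry$null_sd,
               z = smry$z, p_global = smry$p_global,
               p_is_upper_bound = smry$p_is_upper_bound),
    p$null_summary)
  invisible(NULL)
}

.pl_stage_network <- function(cfg, p) {
  .pl_require(p$results, "enrich")
  res <- read_results_table(p$results)
  links <- build_links(res)
  categories <- if (file.exists(p$categories)) {
    read_category_map(p$categories)
  } else NULL
  net <- filter_network(links, threshold = cfg$network_threshold,
                        categories = categories)
  write_edge_list(links, p$links,
                  params = list(threshold = cfg$network_threshold))
  export_bipartite(res, p$bipartite, format = "tsv")
  write_graphml(net, p$graphml)
  invisible(NULL)
}

.pl_stage_summarize <- function(cfg, p) {
  .pl_require(c(p$results, p$gene_sets, p$categories, p$links), "network")
  res <- read_results_table(p$results)
  gs <- read_gene_sets(p$gene_sets)
  categories <- read_category_map(p$categories)
  links <- read_edge_list(p$links)
  cs <- category_fractions(res, gs, categories)
  ct <- correlation_table(gs, res)
  .pl_write_tsv(cs, p$category_summary)
  .pl_write_tsv(ct, p$correlations)
  net <- filter_network(links, threshold = cfg$network_threshold)
  lines <- c(
    "# pathlink run report",
    "",
    paste0("- phenotypes in catalog: ", nrow(gs)),
    paste0("- testable phenotypes (>= 2 mapped genes): ",
           sum(gs$testable)),
    paste0("- phenotypes scored (G >= 2): ",
           sum(gs$testable & gs$G >= 2)),
    paste0("- significant phenotype-pathway associations: ",
           sum(res$significant)),
    paste0("- phenotypes with >= 1 significant pathway: ",
           length(unique(res$phenotype[res$significant]))),
    paste0("- phenotype-phenotype links (weight >= 1): ", nrow(links)),
    paste0("- links at network threshold ", cfg$network_threshold, ": ",
           nrow(net$edges)),
    paste0("- connected component sizes: ",
           if (length(net$components))
             paste(net$components, collapse = ", ") else "none"),
    "",
    paste0("parameters: alpha=", cfg$alpha, " min_dp=", cfg$min_dp,
           " reps=", cfg$reps, " outer_reps=", cfg$outer_reps,
           " window=", cfg$window, " mapping=", cfg$mapping_mode,
           " seed=", cfg$seed)
  )
  writeLines(lines, p$report)
  invisible(NULL)
}
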