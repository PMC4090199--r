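test_that("GMT reading computes unions, dedups genes, and flags format errors", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("P1\tdesc\tg1\tg2\tg3\tg4",
               "P2\tdesc\tg3\tg4\tg5\tg6\tg7\tg8"), p)
  db <- read_gmt(p)
  expect_s3_class(db, "pathway_db")
  expect_equal(db$P, 2L)
  expect_equal(db$N, 8L)
  expect_setequal(db$universe, paste0("g", 1:8))

  writeLines("P1\tdesc\tg1\tg1\tg2", p)
  expect_equal(lengths(read_gmt(p)$pathways)[["P1"]], 2L)

  writeLines(paste(c("P1", "d", paste0("g", 1:10)), collapse = "\t"), p)
  expect_equal(read_gmt(p)$N, 10L)

  writeLines(c("P1\tdesc\tg1", "P2\tonlytwo"), p)
  expect_error(read_gmt(p), "line 2")

  writeLines(c("P1\td\tg1", "P1\td\tg2"), p)
  expect_error(read_gmt(p), "duplicate pathway id")
})

test_that("GMT write/read round-trips and agrees with fgsea's parser", {
  set.seed(4)
  db <- random_db(P = 5, N = 30)
  p <- tempfile(fileext = ".gmt")
  write_gmt(db, p)
  back <- read_gmt(p)
  expect_equal(back$pathways, db$pathways)
  expect_equal(back$universe, db$universe)

  skip_if_not_installed("fgsea")
  ref <- fgsea::gmtPathways(p)
  expect_equal(lapply(ref, sort), lapply(db$pathways, sort))
})

test_that("association reading normalizes labels and applies the catalog threshold", {
  p <- write_catalog_fixture(c(
    catalog_row("Celiac disease", "rs1"),
    catalog_row("celiac  Disease ", "rs2"),
    catalog_row("Asthma", "rs3"),
    catalog_row("Asthma", "rs4", pvalue = 2e-5),
    catalog_row("Type 1 diabetes", "rs5")
  ))
  tab <- read_association_table(p, pvalue_threshold = 1e-5)
  expect_equal(nrow(tab), 4L)  # the 2e-5 row is dropped
  expect_equal(sum(tab$phenotype == "celiac disease"), 2L)
  expect_false("rs4" %in% tab$snp)

  # empty file with a valid header
  p2 <- write_catalog_fixture(character(0))
  expect_equal(nrow(read_association_table(p2)), 0L)

  # missing mandatory column is named in the error
  p3 <- tempfile(fileext = ".tsv")
  writeLines(c("trait\tsnp\tchrom\tpvalue", "x\trs1\tchr1\t1e-8"), p3)
  expect_error(read_association_table(p3), "pos")
})

test_that("malformed rows fail with a line number, or are skipped on request", {
  p <- write_catalog_fixture(c(
    catalog_row("a", "rs1"),
    catalog_row("b", "rs2", pos = "oops")
  ))
  expect_error(read_association_table(p), "line 3")
  expect_warning(tab <- read_association_table(p, on_bad_row = "skip"),
                 "skipped")
  expect_equal(tab$snp, "rs1")
})

test_that("synonym maps merge labels and normalization is idempotent", {
  p <- write_catalog_fixture(c(
    catalog_row("T1D", "rs1"),
    catalog_row("type 1 diabetes", "rs2")
  ))
  syn <- data.frame(from = "t1d", to = "Type 1 Diabetes")
  tab <- read_association_table(p, synonyms = syn)
  expect_equal(unique(tab$phenotype), "type 1 diabetes")

  set.seed(1)
  raw <- c("  Celiac   Disease", "ASTHMA ", "a b  c")
  once <- normalize_phenotype_label(raw)
  expect_identical(normalize_phenotype_label(once), once)
})

test_that("lowering the p-value threshold never increases retained rows", {
  set.seed(9)
  rows <- vapply(1:40, function(i) {
    catalog_row(paste0("t", i %% 5), paste0("rs", i),
                pvalue = 10^runif(1, -9, -4))
  }, "")
  p <- write_catalog_fixture(rows)
  thresholds <- 10^seq(-4, -9, by = -0.5)
  counts <- vapply(thresholds, function(th) {
    nrow(read_association_table(p, pvalue_threshold = th))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("BED intervals round-trip through the 0-based half-open convention", {
  p <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tGENE1\t0\t+", p)
  iv <- read_gene_intervals(p)
  expect_equal(iv$symbol, "GENE1")
  expect_equal(iv$start, 100L)
  expect_equal(iv$end, 200L)
  expect_equal(iv$strand, "+")

  ann <- tiny_annotation()
  p2 <- tempfile(fileext = ".bed")
  write_gene_intervals(ann, p2)
  back <- read_gene_intervals(p2)
  expect_equal(back[order(back$symbol), c("symbol", "chrom", "start", "end", "strand")],
               ann[order(ann$symbol), ], ignore_attr = TRUE)

  # duplicate symbols rejected
  writeLines(c("chr1\t0\t10\tG1\t0\t+", "chr2\t0\t10\tG1\t0\t+"), p)
  expect_error(read_gene_intervals(p), "duplicate gene symbol")
})

test_that("category lookups fall back to 'other' with a warning", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("phenotype\tcategory", "Asthma\tautoimmune",
               "melanoma\tcancer"), p)
  cm <- read_category_map(p)
  expect_equal(unname(cm["asthma"]), "autoimmune")
  expect_warning(out <- category_of(cm, c("asthma", "unknown trait")),
                 "other")
  expect_equal(out, c("autoimmune", "other"))
})

test_that("results and edge-list writers round-trip with provenance headers", {
  res <- data.frame(phenotype = c("a", "a", "b"),
                    pathway_id = c("P1", "P2", "P1"),
                    pathway_name = c("one", "two", "one"),
                    G = c(3L, 3L, 4L), dp = c(2L, 0L, 3L),
                    p_emp = c(0.012, 1, 0.004),
                    significant = c(TRUE, FALSE, TRUE),
                    pool_reps = 1000L, stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  write_results_table(res, p, params = list(alpha = 0.05))
  expect_match(readLines(p, n = 1), "^# pathlink")
  expect_equal(read_results_table(p), res)

  links <- make_sig_results(list(a = c("P1", "P2"), b = "P1"))
  lk <- build_links(links)
  p2 <- tempfile(fileext = ".tsv")
  write_edge_list(lk, p2)
  back <- read_edge_list(p2)
  expect_equal(back$weight, lk$weight)
  expect_equal(back$shared_pathways, lk$shared_pathways,
               ignore_attr = TRUE)
})
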