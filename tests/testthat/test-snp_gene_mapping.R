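test_that("coordinate mapping honors containment, window, and ties", {
  ann <- tiny_annotation()

  # containment: SNP inside GENE1 [100, 200)
  hit <- map_snp_to_genes(list(chrom = "chr1", pos = 150), ann)
  expect_equal(as.character(hit), "GENE1")
  expect_equal(attr(hit, "distance"), 0)

  # nearest within window: pos 250 is 50 bp past GENE1's end and 70 bp
  # before GENE2's start
  hit <- map_snp_to_genes(list(chrom = "chr1", pos = 250), ann,
                          window = 100)
  expect_equal(as.character(hit), "GENE1")
  expect_equal(attr(hit, "distance"), 50)

  # beyond the window: no phenotype gene
  hit <- map_snp_to_genes(list(chrom = "chr1", pos = 1e7), ann,
                          window = 20000)
  expect_length(hit, 0)

  # equidistant flanks break toward the lexicographically smaller symbol
  ann2 <- data.frame(symbol = c("B", "A"), chrom = "chr1",
                     start = c(0L, 200L), end = c(100L, 300L),
                     strand = "+", stringsAsFactors = FALSE)
  hit <- map_snp_to_genes(list(chrom = "chr1", pos = 150), ann2,
                          window = 100)
  expect_equal(as.character(hit), "A")

  expect_error(map_snp_to_genes(list(chrom = "chr1", pos = 1), ann,
                                window = -1), "window")
  expect_warning(
    hit <- map_snp_to_genes(list(chrom = "chrX", pos = 1), ann),
    "absent")
  expect_length(hit, 0)
})

test_that("reported mode returns curated genes and splits intergenic placeholders", {
  snp <- list(chrom = "chr1", pos = 0,
              reported_genes = list(c("TP53", "BRCA1 - BRCA2", "NR")))
  expect_equal(as.character(
    map_snp_to_genes(snp, NULL, mode = "reported")),
    c("BRCA1", "BRCA2", "TP53"))
  expect_equal(as.character(
    map_snp_to_genes(snp, NULL, mode = "reported",
                     split_intergenic = FALSE)),
    "TP53")
})

test_that("phenotype gene sets dedup genes, restrict to the universe, and flag untestables", {
  db <- toy_db()
  ann <- data.frame(symbol = paste0("g", 1:9), chrom = "chr1",
                    start = seq(0L, by = 1000L, length.out = 9),
                    end = seq(0L, by = 1000L, length.out = 9) + 100L,
                    strand = "+", stringsAsFactors = FALSE)
  mk <- function(trait, snp, gene) {
    i <- match(gene, ann$symbol)
    data.frame(phenotype = trait, phenotype_raw = trait, snp = snp,
               chrom = "chr1", pos = ann$start[i] + 50L, pvalue = 1e-8,
               sample_size = 500L, study = "s1",
               stringsAsFactors = FALSE)
  }
  assoc <- rbind(
    mk("one gene", "rs1", "g1"), mk("one gene", "rs2", "g1"),
    mk("one gene", "rs3", "g1"),
    mk("three genes", "rs4", "g1"), mk("three genes", "rs5", "g2"),
    mk("three genes", "rs6", "g9"))
  assoc$reported_genes <- replicate(nrow(assoc), character(0),
                                    simplify = FALSE)
  gs <- build_phenotype_gene_sets(assoc, ann, db, mode = "coordinate")

  one <- gs[gs$phenotype == "one gene", ]
  expect_equal(one$all_genes[[1]], "g1")  # 3 SNPs, 1 gene
  expect_false(one$testable)

  three <- gs[gs$phenotype == "three genes", ]
  expect_equal(three$all_genes[[1]], c("g1", "g2", "g9"))
  expect_equal(three$G, 2L)  # g9 is outside the universe
  expect_true(three$testable)

  # G never exceeds the number of distinct SNPs
  expect_true(all(gs$G <= gs$n_snps))

  # empty input -> empty output
  expect_equal(nrow(build_phenotype_gene_sets(assoc[0, ], ann, db,
                                              mode = "coordinate")), 0L)
})

test_that("enlarging the window never shrinks a phenotype's gene set", {
  set.seed(21)
  ann <- data.frame(symbol = sprintf("G%02d", 1:20), chrom = "chr1",
                    start = sort(sample.int(1e6, 20)) * 10L,
                    stringsAsFactors = FALSE)
  ann$end <- ann$start + 500L
  ann$strand <- "+"
  positions <- sample.int(max(ann$end) + 1e5, 50)
  windows <- c(0, 100, 1000, 10000, 1e5)
  for (rep in 1:3) {
    pos <- sample(positions, 10)
    sets <- lapply(windows, function(w) {
      sort(unique(unlist(lapply(pos, function(p) {
        as.character(map_snp_to_genes(list(chrom = "chr1", pos = p),
                                      ann, window = w))
      }))))
    })
    for (i in seq_along(windows)[-1]) {
      expect_true(all(sets[[i - 1]] %in% sets[[i]]))
    }
  }
})

test_that("sample sizes sum over distinct studies, else take the row maximum", {
  db <- toy_db()
  base <- data.frame(
    phenotype = "t", phenotype_raw = "t", snp = c("rs1", "rs2", "rs3"),
    chrom = "chr1", pos = 1L, pvalue = 1e-8,
    sample_size = c(100L, 100L, 250L),
    study = c("s1", "s1", "s2"), stringsAsFactors = FALSE)
  base$reported_genes <- list("g1", "g2", "g3")
  gs <- build_phenotype_gene_sets(base, NULL, db, mode = "reported")
  expect_equal(gs$sample_size, 350L)  # s1 (100) + s2 (250)

  base$study <- NA_character_
  gs <- build_phenotype_gene_sets(base, NULL, db, mode = "reported")
  expect_equal(gs$sample_size, 250L)
})

test_that("gene-set tables round-trip through TSV", {
  db <- toy_db()
  gs <- make_gene_sets(list(c("g1", "g2"), c("g3", "g4", "zz")), db,
                       sample_size = c(100L, 200L))
  p <- tempfile(fileext = ".tsv")
  write_gene_sets(gs, p)
  back <- read_gene_sets(p)
  expect_equal(back$phenotype, gs$phenotype)
  expect_equal(back$G, gs$G)
  expect_equal(back$testable, gs$testable)
  expect_equal(back$universe_genes, gs$universe_genes,
               ignore_attr = TRUE)
})
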