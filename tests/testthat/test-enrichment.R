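test_that("pathway counts are exact intersections, zeros included", {
  db <- toy_db()
  dp <- compute_dp(c("g1", "g2"), db)
  expect_equal(dp, c(P1 = 2L, P2 = 0L))
  expect_equal(compute_dp(c("g5", "g6"), db), c(P1 = 0L, P2 = 2L))
  expect_error(compute_dp(c("g1", "nope"), db), "outside")
})

test_that("null pools honor forced structure and argument checks", {
  # one pathway equal to the whole universe: every pooled score equals G
  db1 <- pathway_db(list(ALL = paste0("g", 1:10)))
  pool <- sample_null_pool(4, db1, reps = 50, seed = 1)
  expect_true(all(pool$scores == 4L))

  # G = N: every score equals the pathway's size
  db <- toy_db()
  pool <- sample_null_pool(8, db, reps = 20, seed = 1)
  expect_setequal(unique(pool$scores), c(4L, 6L))
  expect_equal(sum(pool$scores == 4L), 20L)

  expect_error(sample_null_pool(9, db, reps = 10), "G must be")
  expect_error(sample_null_pool(0, db, reps = 10), "G must be")
})

test_that("the exact pooled tail matches brute-force enumeration on the toy database", {
  db <- toy_db()
  # enumerate all C(8,2) = 28 gene pairs
  pairs <- combn(db$universe, 2)
  tail_brute <- function(k) {
    mean(c(
      vapply(seq_len(ncol(pairs)), function(j)
        sum(pairs[, j] %in% db$pathways$P1) >= k, logical(1)),
      vapply(seq_len(ncol(pairs)), function(j)
        sum(pairs[, j] %in% db$pathways$P2) >= k, logical(1))))
  }
  for (k in 0:2) {
    expect_equal(exact_pooled_tail(k, 2, db), tail_brute(k))
  }
  expect_equal(exact_pooled_tail(2, 2, db), 21 / 56)
  expect_equal(exact_pooled_tail(0, 5, db), 1)
  expect_equal(exact_pooled_tail(3, 2, db), 0)
  db1 <- pathway_db(list(ALL = paste0("g", 1:9)))
  expect_equal(exact_pooled_tail(3, 3, db1), 1)
})

test_that("empirical pool tails match the analytic mixture on random databases", {
  reps <- 2e4
  for (seed in c(3, 14)) {
    db <- random_db(P = 4, N = 18, seed = seed)
    for (G in c(2, 4)) {
      pool <- sample_null_pool(G, db, reps = reps, seed = seed + 100)
      for (k in 0:G) {
        p_exact <- exact_pooled_tail(k, G, db)
        p_emp <- empirical_pvalue(k, pool)
        # conservative SE: per-replicate means have variance <= p(1-p)
        se <- sqrt(p_exact * (1 - p_exact) / reps)
        expect_lt(abs(p_emp - p_exact), 3 * se + 1e-12)
      }
    }
  }
})

test_that("empirical p-values count tail mass directly", {
  pool <- structure(list(G = 2L, reps = 5L,
                         scores = c(0L, 0L, 0L, 1L, 2L),
                         tail_counts = c(5L, 2L, 1L), seed = NULL),
                    class = "null_pool")
  expect_equal(empirical_pvalue(0, pool), 1)
  expect_equal(empirical_pvalue(2, pool), 0.2)
  expect_equal(empirical_pvalue(3, pool), 0)          # above pool maximum
  expect_equal(empirical_pvalue(3, pool, smooth = TRUE), 1 / 6)
  expect_gt(empirical_pvalue(99, pool, smooth = TRUE), 0)
})

test_that("p-values depend on (G, dp) only and are monotone in dp and G", {
  set.seed(8)
  db <- random_db(P = 6, N = 30, seed = 8)
  gs <- make_gene_sets(list(
    db$universe[1:4], db$universe[5:8], db$universe[c(1, 2, 9, 10)],
    db$universe[11:13]), db)
  res <- run_enrichment(gs, db, reps = 500, seed = 42)

  # pathway-agnostic: one p-value per (G, dp) across all phenotypes
  by_gdp <- tapply(res$p_emp, paste(res$G, res$dp), function(x)
    length(unique(x)))
  expect_true(all(by_gdp == 1L))

  # monotone in dp for fixed G
  for (G in unique(res$G)) {
    sub <- res[res$G == G, ]
    ord <- order(sub$dp)
    expect_true(all(diff(sub$p_emp[ord]) <= 1e-12))
  }

  # exact tail non-decreasing in G for fixed k >= 1
  tails <- vapply(2:10, function(G) exact_pooled_tail(2, G, db),
                  numeric(1))
  expect_true(all(diff(tails) >= -1e-12))
})

test_that("enrichment runs are deterministic and respect the min_dp rule", {
  db <- random_db(P = 5, N = 25, seed = 2)
  gs <- make_gene_sets(list(db$universe[1:3], db$universe[4:9]), db)
  r1 <- run_enrichment(gs, db, reps = 400, seed = 7)
  r2 <- run_enrichment(gs, db, reps = 400, seed = 7)
  expect_identical(r1, r2)

  # all dp <= 1 cannot be significant when min_dp = 2
  one_per <- make_gene_sets(list(db$universe[1:2]), db)
  res <- run_enrichment(one_per, db, reps = 400, seed = 1, alpha = 1,
                        min_dp = 2)
  expect_true(all(res$significant == (res$dp >= 2)))
})

test_that("a phenotype filling a small pathway in a sparse database is detected", {
  sets <- c(list(TARGET = paste0("t", 1:4)),
            setNames(lapply(1:20, function(j) sprintf("f%02d_%d", j, 1:10)),
                     paste0("F", 1:20)))
  db <- pathway_db(sets)
  # detectability precondition via the analytic oracle
  expect_lt(exact_pooled_tail(4, 4, db), 0.05)
  gs <- make_gene_sets(list(paste0("t", 1:4)), db)
  res <- run_enrichment(gs, db, reps = 1000, seed = 3)
  expect_true(res$significant[res$pathway_id == "TARGET"])
})

test_that("per-pathway conditional nulls give valid, pathway-specific p-values", {
  db <- random_db(P = 4, N = 20, seed = 5)
  gs <- make_gene_sets(list(db$universe[1:5]), db)
  res <- run_enrichment(gs, db, reps = 500, seed = 9,
                        null_mode = "per_pathway")
  expect_true(all(res$p_emp >= 0 & res$p_emp <= 1))
  expect_equal(res$p_emp[res$dp == 0], rep(1, sum(res$dp == 0)))
})

test_that("null phenotypes are called significant at no more than the nominal rate", {
  spec <- synthetic_spec(n_phenotypes_planted = 0, n_phenotypes_null = 30,
                         seed = 17)
  gen <- generate_pathway_db(spec)
  cat_out <- generate_catalog(spec, gen$db, gen$annotation)
  assoc <- catalog_to_associations(cat_out$catalog)
  gs <- build_phenotype_gene_sets(assoc, gen$annotation, gen$db,
                                  mode = "coordinate")
  res <- run_enrichment(gs, gen$db, reps = 1000, seed = 23)
  n_pairs <- nrow(res)
  se <- sqrt(0.05 * 0.95 / n_pairs)
  expect_lte(mean(res$significant), 0.05 + 3 * se)
})

test_that("pool histograms tabulate the pooled scores", {
  db <- toy_db()
  pool <- sample_null_pool(2, db, reps = 1000, seed = 6)
  h <- pool_histogram(pool)
  expect_equal(sum(h$count), 2000L)
  expect_equal(h$score, 0:2)
  expect_equal(sum(h$frequency), 1)
})
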