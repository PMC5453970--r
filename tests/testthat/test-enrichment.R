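test_that("feature membership respects half-open boundaries and dedupes", {
  fs <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
  v <- toy_variants(pos = c(1L, 10L, 11L), ref = "A", alt = "G")
  expect_equal(intersect_variants(v, fs), c(TRUE, TRUE, FALSE))
  # overlapping intervals flag a covered variant once; merging never changes
  # membership
  fs2 <- tibble::tibble(chrom = "chr1", start = c(0, 5), end = c(10, 15))
  merged <- tibble::tibble(chrom = "chr1", start = 0, end = 15)
  v2 <- toy_variants(pos = c(7L, 12L, 20L), ref = "A", alt = "G")
  expect_equal(intersect_variants(v2, fs2), intersect_variants(v2, merged))
})

test_that("novel enrichment builds the documented 2x2 and exact p", {
  # 20 novel all inside, 20 known all outside -> p = 1/choose(40,20)
  v <- toy_variants(pos = c(1:20, 201:220), ref = "A", alt = "G")
  v$novel <- rep(c(TRUE, FALSE), each = 20)
  fs <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  res <- novel_enrichment(v, fs)
  expect_equal(c(res$a, res$b, res$c, res$d), c(20, 0, 0, 20))
  expect_equal(res$p, 1 / choose(40, 20), tolerance = 1e-12)
  # table always accounts for every classified variant
  expect_equal(res$a + res$b + res$c + res$d, nrow(v))
  expect_error(novel_enrichment(dplyr::mutate(v, novel = FALSE), fs),
               "no novel")
  expect_error(novel_enrichment(dplyr::select(v, -novel), fs),
               "mark_novelty")
})

test_that("under a seeded null the enrichment p-value is unremarkable", {
  set.seed(99)
  n <- 400
  v <- toy_variants(pos = sample.int(1e6, n), ref = "A", alt = "G")
  v$novel <- runif(n) < 0.3  # independent of position
  fs <- tibble::tibble(chrom = "chr1", start = seq(0, 9e5, by = 1e5),
                       end = seq(0, 9e5, by = 1e5) + 3e4)
  res <- novel_enrichment(v, fs)
  expect_gt(res$p, 0.05)
})

test_that("RP threshold enrichment: boundary, fold arithmetic, exclusions", {
  # variants 1..200; blocks cover 1..100; RP track scores everything
  v <- toy_variants(pos = 1:200, ref = "A", alt = "G")
  blocks <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  # scores: 17 high in-block, 10 high out-of-block (boundary value 0.5 = high)
  score <- rep(0.1, 200)
  score[1:17] <- c(rep(0.9, 16), 0.5)
  score[101:110] <- 0.8
  rp <- tibble::tibble(chrom = "chr1", start = 0:199, end = 1:200,
                       score = score)
  res <- rp_threshold_enrichment(v, rp, blocks, rp_min = 0.5)
  expect_equal(c(res$a, res$b, res$c, res$d), c(17, 83, 10, 90))
  expect_equal(res$fold, 1.7)
  # equal proportions give fold 1
  score2 <- rep(c(0.9, rep(0.1, 9)), 20)
  rp2 <- tibble::tibble(chrom = "chr1", start = 0:199, end = 1:200,
                        score = score2)
  expect_equal(rp_threshold_enrichment(v, rp2, blocks)$fold, 1)
  # uncovered variants are excluded; fully uncovered errors
  rp3 <- rp[1:100, ]
  res3 <- rp_threshold_enrichment(v, rp3, blocks)
  expect_equal(res3$a + res3$b + res3$c + res3$d, 100)
  expect_error(rp_threshold_enrichment(v, rp3[0, ], blocks), "covered")
  # overlapping score intervals resolve to the maximum
  rp4 <- tibble::tibble(chrom = "chr1", start = c(0, 0), end = c(1, 1),
                        score = c(0.2, 0.7))
  expect_equal(rp_lookup(v[1, ], rp4), 0.7)
})

test_that("rank-sum test: exact small-sample tail and tie behaviour", {
  expect_equal(rank_sum_test(c(4, 5, 6), c(1, 2, 3))$p, 1 / choose(6, 3))
  # identical multisets are never 'significantly greater'
  expect_gte(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p, 0.5)
  # one-sided tails from the two orderings cover the distribution
  x <- c(0.3, 2.1, 3.3, 4.9); y <- c(1.1, 1.8, 5.2)
  expect_gte(rank_sum_test(x, y)$p + rank_sum_test(y, x)$p, 1)
  # large samples fall back to the normal approximation
  set.seed(1)
  big <- rank_sum_test(rnorm(50, 1), rnorm(50))
  expect_equal(big$method, "normal approximation")
  expect_lt(big$p, 0.05)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("enrichment report: one row per type x feature, stable order", {
  st <- generate_study(tiny_study_config(seed = 51, sim_genotypes = FALSE))
  ann <- mark_novelty(st$cohort, st$catalog)
  fsets <- st$features[c("dnase", "ctcf")]
  rep <- feature_enrichment_report(ann, fsets)
  expect_equal(nrow(rep), 4)
  expect_equal(rep$class, c("INDEL", "INDEL", "SNP", "SNP"))
  expect_equal(rep$feature, rep(c("ctcf", "dnase"), 2))
  v <- as_variants(ann)
  snp_rows <- rep[rep$class == "SNP", ]
  expect_equal(unique(snp_rows$a + snp_rows$b + snp_rows$c + snp_rows$d),
               sum(v$var_class == "SNP"))
  # empty feature set: all-zero "in" counts and p = 1
  rep2 <- feature_enrichment_report(
    ann, list(empty = tibble::tibble(chrom = character(), start = double(),
                                     end = double())))
  expect_equal(rep2$a + rep2$c, c(0, 0))
  expect_equal(rep2$p, c(1, 1))
  expect_named(glance(rep), c("n_tests", "n_sig_05", "min_p"))
})
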