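test_that("novelty is an exact key match for sequence-resolved variants", {
  v <- toy_variants(pos = c(100L, 100L, 200L), ref = c("A", "A", "C"),
                    alt = c("G", "T", "T"))
  cat_obj <- catalog(tibble::tibble(chrom = "chr1", pos = 100L,
                                    ref = "A", alt = "G"))
  out <- mark_novelty(v, cat_obj)
  expect_equal(out$novel, c(FALSE, TRUE, TRUE))
  # empty catalog: everything novel; record order irrelevant
  expect_true(all(mark_novelty(v, catalog())$novel))
  shuf <- mark_novelty(v[c(3, 1, 2), ], cat_obj)
  expect_equal(shuf$novel[order(shuf$pos, shuf$alt)],
               out$novel[order(out$pos, out$alt)])
})

test_that("SV novelty uses same-type reciprocal overlap", {
  sv <- tibble::tibble(chrom = "chr1", start = c(0, 0, 0), end = 100,
                       type = c("DEL", "DUP", "DEL"))
  cat_obj <- catalog(sv = tibble::tibble(chrom = "chr1", start = 0,
                                         end = 100, type = "DEL"))
  expect_equal(sv_novelty(sv, cat_obj), c(FALSE, TRUE, FALSE))

  # 60% reciprocal overlap at threshold 0.5: [0,100) vs [40,140), both 100 bp,
  # overlap 60 bp -> 0.6 on each side -> known
  q <- tibble::tibble(chrom = "chr1", start = 0, end = 100, type = "DEL")
  c60 <- catalog(sv = tibble::tibble(chrom = "chr1", start = 40, end = 140,
                                     type = "DEL"))
  expect_false(sv_novelty(q, c60, min_reciprocal = 0.5))
  # 40% reciprocal overlap -> novel at the same threshold
  c40 <- catalog(sv = tibble::tibble(chrom = "chr1", start = 60, end = 160,
                                     type = "DEL"))
  expect_true(sv_novelty(q, c40, min_reciprocal = 0.5))
  # one-sided containment is not reciprocal: 100/1000 fails on the catalog side
  cbig <- catalog(sv = tibble::tibble(chrom = "chr1", start = 0, end = 1000,
                                      type = "DEL"))
  expect_true(sv_novelty(q, cbig, min_reciprocal = 0.5))
})

test_that("novelty_rate reproduces its definition and complements to 100", {
  expect_equal(round(novelty_rate(1902, 7063), 1), 26.9)
  expect_equal(round(novelty_rate(96855, 473261), 1), 20.5)
  expect_equal(novelty_rate(0, 100), 0)
  expect_error(novelty_rate(1, 0), "n_total")
  n <- c(17, 230, 999)
  k <- c(3, 115, 0)
  expect_equal(novelty_rate(k, n) + novelty_rate(n - k, n), rep(100, 3))
})

test_that("AAF counts alt alleles over non-missing diploid calls", {
  v <- toy_variants(pos = 100L, ref = "A", alt = "G")
  v$variant_id <- "chr1:100:A:G"
  mk <- function(gts) {
    g <- tibble::tibble(variant_id = v$variant_id,
                        sample = sprintf("S%02d", seq_along(gts)), gt = gts,
                        dp = 30L, gq = 60L, ad_ref = 15L, ad_alt = 15L)
    compute_aaf(callset(v, g))$variants
  }
  all_het <- mk(rep("0/1", 48))
  expect_equal(all_het$aaf, 0.5)
  expect_equal(all_het$freq_class, "COMMON")
  one_het <- mk(c("0/1", rep("0/0", 47)))
  expect_equal(one_het$aaf, 1 / 96)
  expect_equal(one_het$freq_class, "LOW")
  expect_equal(one_het$n_samples_present, 1)
  expect_equal(mk(rep("1/1", 10))$aaf, 1)
  # missing genotypes shrink the denominator
  expect_equal(mk(c("0/1", NA, NA, "0/0"))$aaf, 1 / 4)
  # common/low boundary is strict: aaf exactly 0.05 is LOW
  at_boundary <- mk(c("0/1", rep("0/0", 9)))  # 1/20 = 0.05
  expect_equal(at_boundary$freq_class, "LOW")
})

test_that("common-SV boundary uses the ceiling of the carrier fraction", {
  expect_true(flag_common_sv(16, 48))
  expect_false(flag_common_sv(15, 48))
  expect_true(flag_common_sv(1, 1))
  expect_equal(flag_common_sv(c(0, 8, 16), 48), c(FALSE, FALSE, TRUE))
})

test_that("observed novelty on synthetic data tracks 1 - catalog_prob", {
  q <- 0.7
  st <- generate_study(tiny_study_config(seed = 31, catalog_prob = q,
                                         sim_genotypes = FALSE))
  ann <- mark_novelty(st$cohort, st$catalog)
  n <- length(ann)
  rate <- mean(ann$variants$novel)
  se <- sqrt(q * (1 - q) / n)
  expect_lt(abs(rate - (1 - q)), 3 * se + 1e-9)
})
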