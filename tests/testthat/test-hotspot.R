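test_that("bins tile each chromosome; the last bin may be short", {
  b <- make_bins(c(chrA = 2.5e6))
  expect_equal(b$start, c(0, 1e6, 2e6))
  expect_equal(b$end, c(1e6, 2e6, 2.5e6))
  expect_equal(make_bins(c(chrA = 1e6))$end, 1e6)
  # tiling: spans sum to chromosome lengths, no overlap
  cz <- c(chr1 = 7.3e6, chr2 = 1e6 - 1)
  b2 <- make_bins(cz)
  spans <- tapply(b2$end - b2$start, b2$chrom, sum)
  expect_equal(as.numeric(spans[names(cz)]), unname(cz))
  expect_error(make_bins(c(chr1 = 1e6), width = 0), "positive")
})

test_that("bin membership follows the 0-based conversion of 1-based positions", {
  bins <- make_bins(c(chr1 = 3e6))
  v <- toy_variants(pos = c(1000000L, 1000001L, 1L), ref = "A", alt = "G")
  counts <- count_per_bin(v, bins)
  expect_equal(counts$n, c(2L, 1L, 0L))
  # shuffling records leaves counts unchanged
  expect_equal(count_per_bin(v[c(2, 3, 1), ], bins), counts)
  # variants off the binned genome are excluded with a warning
  v2 <- toy_variants(pos = c(5L, 5L), chrom = c("chr1", "chrZ"),
                     ref = "A", alt = "G")
  expect_warning(c2 <- count_per_bin(v2, bins), "chrZ")
  expect_equal(sum(c2$n), 1)
})

test_that("fold ratio is the ratio of proportions with stated zero rules", {
  expect_equal(fold_ratio(30, 1000, 10, 1000), 3)
  expect_equal(fold_ratio(10, 1000, 10, 1000), 1)
  expect_equal(fold_ratio(5, 1000, 0, 1000), Inf)
  expect_equal(fold_ratio(0, 1000, 5, 1000), 0)
  # scale invariance
  expect_equal(fold_ratio(3 * 7, 100 * 7, 11 * 7, 500 * 7),
               fold_ratio(3, 100, 11, 500))
  expect_error(fold_ratio(1, 0, 1, 10), "totals")
})

test_that("fisher_exact_greater matches the enumeration oracle", {
  expect_equal(fisher_exact_greater(0, 10, 7, 3), 1)
  expect_equal(fisher_exact_greater(10, 0, 0, 10), 1 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_greater(10, 990, 10, 990),
               fisher_oracle(10, 990, 10, 990), tolerance = 1e-12)
  # spot grid, exact agreement
  for (a in c(0, 1, 5)) for (c_ in c(0, 2, 9)) {
    expect_equal(fisher_exact_greater(a, 12 - a, c_, 9),
                 fisher_oracle(a, 12 - a, c_, 9), tolerance = 1e-12)
  }
  # agreement with the standard implementation on a non-trivial table
  ft <- stats::fisher.test(matrix(c(14, 6, 8, 12), 2, byrow = TRUE),
                           alternative = "greater")
  expect_equal(fisher_exact_greater(14, 6, 8, 12), ft$p.value,
               tolerance = 1e-10)
  expect_error(fisher_exact_greater(-1, 2, 3, 4), "non-negative")
})

test_that("increasing the top-left count never increases the p-value", {
  a <- 0:15
  p <- fisher_exact_greater(a, 20 - a, 5, 25)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("hotspot thresholds are inclusive on both fold and p", {
  # craft counts with fold exactly 1.5: a/total_a = 1.5 * b/total_b
  bins <- make_bins(c(chr1 = 2e6))
  mkv <- function(n_bin1, n_bin2) {
    toy_variants(pos = c(seq_len(n_bin1),
                         1e6 + seq_len(n_bin2)),
                 ref = "A", alt = "G")
  }
  cohort <- mkv(150, 850)
  reference <- mkv(100, 900)
  hs <- call_hotspots(cohort, reference, bins = bins)
  expect_equal(hs$fold[1], 1.5)
  expect_equal(hs$is_hotspot[1], hs$p[1] <= 0.05)
  # p_max boundary: set p_max to the computed p, flag must stay on
  hs2 <- call_hotspots(cohort, reference, bins = bins, p_max = hs$p[1])
  expect_true(hs2$is_hotspot[1])
  # fold below threshold is never a hotspot, however small p is
  hs3 <- call_hotspots(cohort, reference, bins = bins, fold_min = 1.51)
  expect_false(any(hs3$is_hotspot[1]))
})

test_that("tidy/glance expose bins and thresholds", {
  bins <- make_bins(c(chr1 = 2e6))
  cohort <- toy_variants(pos = c(10L, 20L, 1000010L), ref = "A", alt = "G")
  reference <- toy_variants(pos = c(15L, 1000001L, 1000002L),
                            ref = "A", alt = "G")
  hs <- call_hotspots(cohort, reference, bins = bins)
  td <- tidy(hs)
  expect_named(td, c("chrom", "start", "end", "bin", "n_cohort",
                     "n_reference", "fold", "p.value", "fdr", "is_hotspot"))
  gl <- glance(hs)
  expect_equal(gl$n_bins, 2)
  expect_equal(gl$total_cohort, 3)
  expect_equal(gl$fold_min, 1.5)
})

test_that("gene association flank boundary is inclusive at exactly 5 kb", {
  bins <- make_bins(c(chr1 = 3e6))
  hs <- tibble::tibble(chrom = "chr1", start = 1e6, end = 2e6, bin = 1L,
                       is_hotspot = TRUE)
  genes <- tibble::tibble(
    chrom = "chr1",
    start = c(1.2e6, 1e6 - 5000 - 300, 1e6 - 5001 - 300, 2e6 + 5000),
    end = c(1.3e6, 1e6 - 5000, 1e6 - 5001, 2e6 + 5300),
    name = c("inside", "at_flank", "beyond_flank", "at_right_flank"))
  out <- associate_genes(hs, genes, flank = 5000)
  expect_setequal(out$genes[[1]], c("inside", "at_flank", "at_right_flank"))
  # non-hotspot bins get no gene lookup
  hs$is_hotspot <- FALSE
  expect_equal(associate_genes(hs, genes)$genes[[1]], character(0))
})

test_that("hotspot BED output carries score, fold and gene columns", {
  bins <- make_bins(c(chr1 = 2e6))
  cohort <- toy_variants(pos = as.integer(seq(1, 9e5, length.out = 60)),
                         ref = "A", alt = "G")
  reference <- toy_variants(pos = as.integer(seq(1, 2e6 - 1,
                                                 length.out = 60)),
                            ref = "A", alt = "G")
  hs <- call_hotspots(cohort, reference, bins = bins)
  hs <- associate_genes(hs, tibble::tibble(chrom = "chr1", start = 100,
                                           end = 500, name = "g1"))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_hotspot_bed(hs, bed)
  lines <- readLines(bed)
  expect_equal(length(lines), sum(hs$is_hotspot))
  expect_true(all(lengths(strsplit(lines, "\t")) == 8))
})
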