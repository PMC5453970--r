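test_that("generation is deterministic: same config, same bytes", {
  cfg <- tiny_study_config(seed = 61)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixture(generate_study(cfg), d1)
  p2 <- write_fixture(generate_study(cfg), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
  # a different seed changes the cohort
  other <- generate_study(tiny_study_config(seed = 62))
  expect_false(identical(other$cohort$variants,
                         generate_study(cfg)$cohort$variants))
})

test_that("catalog_prob = 1 gives novelty rate 0 for sequence-resolved variants", {
  st <- generate_study(tiny_study_config(seed = 63, catalog_prob = 1,
                                         sim_genotypes = FALSE))
  ann <- tidy(mark_novelty(st$cohort, st$catalog))
  expect_equal(sum(ann$novel[!grepl("^SV_", ann$var_class)]), 0)
})

test_that("a null configuration plants nothing", {
  st <- generate_study(tiny_study_config(seed = 64, sim_genotypes = FALSE))
  expect_equal(nrow(st$truth$planted_bins), 0)
  truth_file <- file.path(withr::local_tempdir(), "x")
  paths <- write_fixture(st, truth_file)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_length(truth$planted_bins, 0)
})

test_that("planted truth bins exist in the binned genome", {
  cfg <- synthetic_config(seed = 65, chrom_sizes = c(chr1 = 3e6),
                          bin_width = 1e6,
                          planted_bins = tibble::tibble(chrom = "chr1",
                                                        bin = 2L,
                                                        multiplier = 3),
                          sim_genotypes = FALSE)
  st <- generate_study(cfg)
  bins <- make_bins(st$chrom_sizes, cfg$bin_width)
  expect_true(all(paste(st$truth$planted_bins$chrom,
                        st$truth$planted_bins$bin) %in%
                    paste(bins$chrom, bins$bin)))
})

test_that("generated Ti/Tv converges to p_ts/(1-p_ts)", {
  p_ts <- 2 / 3
  cfg <- synthetic_config(seed = 66, chrom_sizes = c(chr1 = 1e7, chr2 = 1e7),
                          planted_bins = NULL, n_sv = 0, indel_fraction = 0,
                          transition_prob = p_ts, sim_genotypes = FALSE)
  st <- generate_study(cfg)
  v <- st$cohort$variants
  n <- nrow(v)
  obs <- titv_ratio(v$ref, v$alt)
  target <- p_ts / (1 - p_ts)
  se_ratio <- sqrt(p_ts * (1 - p_ts) / n) / (1 - p_ts)^2  # delta method
  expect_lt(abs(obs - target), 3 * se_ratio)
})

test_that("per-bin counts are Poisson-dispersed at the configured rate", {
  cfg <- synthetic_config(seed = 67, chrom_sizes = c(chr1 = 1e7, chr2 = 1e7),
                          planted_bins = NULL, n_sv = 0,
                          background_rate = 1e-3, sim_genotypes = FALSE)
  st <- generate_study(cfg)
  bins <- make_bins(st$chrom_sizes, cfg$bin_width)
  counts <- count_per_bin(st$cohort, bins)$n
  # position de-duplication trims ~0.05% at this density; allow for it
  lambda <- 1e-3 * 1e6
  expect_lt(abs(mean(counts) - lambda) / lambda, 0.01)
  disp <- sum((counts - mean(counts))^2) / mean(counts)
  df <- length(counts) - 1
  expect_gt(disp, qchisq(0.001, df))
  expect_lt(disp, qchisq(0.999, df))
})

test_that("fixtures round-trip through the readers", {
  st <- generate_study(tiny_study_config(seed = 68))
  d <- withr::local_tempdir()
  p <- write_fixture(st, d)
  back <- read_vcf(p[["cohort"]])
  expect_setequal(back$variants$variant_id, st$cohort$variants$variant_id)
  cat_back <- read_catalog(p[["catalog"]], p[["catalog_sv"]])
  expect_setequal(cat_back$keys, st$catalog$keys)
  cz <- read_chrom_sizes(p[["chrom_sizes"]])
  expect_equal(cz, st$chrom_sizes)
  expect_equal(read_bed(p[["feature_dnase"]])[, c("chrom", "start", "end")],
               st$features$dnase)
  rp <- read_bed(p[["rp_track"]])
  expect_equal(rp$score, st$rp_track$score)
})
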