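#' Configuration for the synthetic study generator
#'
#' The generator emulates the data shape the pipeline consumes: a cohort and
#' a reference call set sharing a genome, a known-variant catalog controlling
#' the novelty fraction, regulatory feature sets with an optional
#' over-representation of novel variants, gene models, and a scored
#' regulatory-potential track. Identical config + seed gives byte-identical
#' output; each stage draws from its own derived substream, so adding a stage
#' never perturbs earlier stages.
#'
#' @param seed Integer seed for all randomness.
#' @param chrom_sizes Named numeric vector or chrom/size table (default three
#'   10 Mb chromosomes).
#' @param bin_width Bin width (bp) used for density planting (default 1 Mb).
#' @param n_samples_cohort,n_samples_reference Sample counts (defaults 48 and
#'   8; reference genotype fields are carried but unused by the analyses).
#' @param background_rate Variants per bp per population (default 1e-3, i.e.
#'   an expected 1,000 variants per 1 Mb bin).
#' @param planted_bins Tibble with `chrom`, `bin` (0-based index within the
#'   chromosome) and `multiplier`: cohort bins whose variant rate is
#'   multiplied. Default: three bins at multiplier 3, one per chromosome.
#'   Use `NULL` or multiplier 1 everywhere for a null genome.
#' @param catalog_prob Probability a cohort variant is present in the
#'   catalog; the expected novelty rate is `1 - catalog_prob`.
#' @param transition_prob Probability a simulated SNP is a transition
#'   (default 2/3, i.e. an expected Ti/Tv of 2.0).
#' @param indel_fraction Fraction of sequence-resolved variants simulated as
#'   1-10 bp indels.
#' @param n_sv Number of structural variants per population.
#' @param feature_config Tibble with `name`, `n_intervals`, `mean_length`
#'   (bp) and `novel_multiplier` (>= 1 plants over-representation of novel
#'   variants inside that feature set; 1 = null).
#' @param het_fraction Probability a carrier call is heterozygous (0.6 gives
#'   an expected Het/Hom of 1.5).
#' @param carrier_prob Per-sample carrier probability (each variant is forced
#'   to have at least one carrier).
#' @param missing_prob Probability a non-carrier genotype is missing (`./.`).
#' @param depth_mean,gq_mean,qual_mean Means of the Poisson depth, Poisson
#'   genotype quality (capped at 99) and Gamma site-quality generators.
#' @param sim_genotypes Generate per-sample GT/DP/GQ/AD tables (disable for
#'   large position-only simulations).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             chrom_sizes = c(chr1 = 1e7, chr2 = 1e7,
                                             chr3 = 1e7),
                             bin_width = 1e6,
                             n_samples_cohort = 48L,
                             n_samples_reference = 8L,
                             background_rate = 1e-3,
                             planted_bins = tibble(
                               chrom = c("chr1", "chr2", "chr3"),
                               bin = c(2L, 4L, 7L),
                               multiplier = 3),
                             catalog_prob = 0.8,
                             transition_prob = 2 / 3,
                             indel_fraction = 0.1,
                             n_sv = 150L,
                             feature_config = tibble(
                               name = c("ld_blocks", "h3k4me3", "dnase",
                                        "ctcf"),
                               n_intervals = c(60L, 300L, 300L, 400L),
                               mean_length = c(5e4, 2e3, 1e3, 500),
                               novel_multiplier = 1),
                             het_fraction = 0.6,
                             carrier_prob = 0.15,
                             missing_prob = 0.01,
                             depth_mean = 38,
                             gq_mean = 60,
                             qual_mean = 100,
                             sim_genotypes = TRUE) {
  cz <- as_chrom_sizes(chrom_sizes)
  if (is.null(planted_bins)) {
    planted_bins <- tibble(chrom = character(), bin = integer(),
                           multiplier = double())
  }
  planted_bins <- as_tibble(planted_bins)
  stopifnot(catalog_prob >= 0, catalog_prob <= 1,
            transition_prob >= 0, transition_prob <= 1,
            het_fraction >= 0, het_fraction <= 1,
            all(planted_bins$multiplier > 0),
            all(feature_config$novel_multiplier > 0),
            all(planted_bins$chrom %in% cz$chrom))
  cfg <- list(seed = as.integer(seed), chrom_sizes = cz, bin_width = bin_width,
              n_samples_cohort = as.integer(n_samples_cohort),
              n_samples_reference = as.integer(n_samples_reference),
              background_rate = background_rate, planted_bins = planted_bins,
              catalog_prob = catalog_prob, transition_prob = transition_prob,
              indel_fraction = indel_fraction, n_sv = as.integer(n_sv),
              feature_config = as_tibble(feature_config),
              het_fraction = het_fraction, carrier_prob = carrier_prob,
              missing_prob = missing_prob, depth_mean = depth_mean,
              gq_mean = gq_mean, qual_mean = qual_mean,
              sim_genotypes = isTRUE(sim_genotypes))
  structure(cfg, class = "synthetic_config")
}

stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 1000003) %% 2147483629)
}

# allele lookup tables, all ordered to index by position in BASES
BASES <- c("A", "C", "G", "T")
TRANSITION <- c(A = "G", C = "T", G = "A", T = "C")
TRANSVERSION_1 <- c(A = "C", C = "A", G = "C", T = "A")
TRANSVERSION_2 <- c(A = "T", C = "G", G = "T", T = "G")

sim_sites <- function(cfg, planted) {
  bins <- make_bins(cfg$chrom_sizes, cfg$bin_width)
  bins$multiplier <- 1
  if (nrow(planted) > 0) {
    key <- paste(planted$chrom, planted$bin)
    idx <- match(paste(bins$chrom, bins$bin), key)
    bins$multiplier[!is.na(idx)] <- planted$multiplier[idx[!is.na(idx)]]
  }
  lambda <- cfg$background_rate * (bins$end - bins$start) * bins$multiplier
  n <- rpois(nrow(bins), lambda)
  cz <- cfg$chrom_sizes
  chrom_i <- rep(match(bins$chrom, cz$chrom), n)
  start <- rep(bins$start, n)
  len <- rep(bins$end - bins$start, n)
  pos <- as.integer(start + floor(runif(sum(n)) * len) + 1)
  key <- chrom_i * 2^33 + pos  # exact in doubles for any real chromosome
  ord <- order(key)
  key <- key[ord]
  keep <- !duplicated(key)
  tibble(chrom = cz$chrom[chrom_i[ord][keep]], pos = pos[ord][keep])
}

sim_alleles <- function(n, cfg) {
  ref_i <- sample.int(4L, n, replace = TRUE)
  ref <- BASES[ref_i]
  is_ts <- runif(n) < cfg$transition_prob
  tv_pick <- runif(n) < 0.5
  alt <- unname(TRANSITION[ref_i])
  alt[!is_ts & tv_pick] <- unname(TRANSVERSION_1[ref_i[!is_ts & tv_pick]])
  alt[!is_ts & !tv_pick] <- unname(TRANSVERSION_2[ref_i[!is_ts & !tv_pick]])
  kind <- runif(n)
  is_indel <- kind < cfg$indel_fraction
  is_ins <- is_indel & kind < cfg$indel_fraction / 2
  is_del <- is_indel & !is_ins
  out_ref <- ref
  out_alt <- alt
  cls <- rep("SNP", n)
  cls[is_ins] <- "INSERTION"
  cls[is_del] <- "DELETION"
  if (any(is_indel)) {
    ilen <- sample.int(10, sum(is_indel), replace = TRUE)
    extra <- vapply(ilen, function(k)
      paste(sample(BASES, k, replace = TRUE), collapse = ""), "")
    ins_extra <- extra[is_ins[is_indel]]
    del_extra <- extra[is_del[is_indel]]
    out_alt[is_ins] <- paste0(ref[is_ins], ins_extra)
    out_ref[is_del] <- paste0(ref[is_del], del_extra)
    out_alt[is_del] <- ref[is_del]
  }
  list(ref = out_ref, alt = out_alt, var_class = cls)
}

sim_genotype_table <- function(variant_id, n_samples, cfg) {
  nv <- length(variant_id)
  ns <- n_samples
  carrier <- matrix(runif(nv * ns) < cfg$carrier_prob, nrow = nv)
  none <- rowSums(carrier) == 0
  if (any(none)) {
    carrier[cbind(which(none),
                  sample.int(ns, sum(none), replace = TRUE))] <- TRUE
  }
  carrier <- as.vector(carrier)
  het <- carrier & runif(nv * ns) < cfg$het_fraction
  missing <- !carrier & runif(nv * ns) < cfg$missing_prob
  gt <- rep("0/0", nv * ns)
  gt[carrier] <- ifelse(het[carrier], "0/1", "1/1")
  gt[missing] <- NA_character_
  dp <- rpois(nv * ns, cfg$depth_mean)
  gq <- pmin(99L, rpois(nv * ns, cfg$gq_mean))
  ad_alt <- integer(nv * ns)
  ad_alt[het] <- rbinom(sum(het), dp[het], 0.5)
  hom_alt <- carrier & !het
  ad_alt[hom_alt] <- dp[hom_alt] - rbinom(sum(hom_alt), dp[hom_alt], 0.02)
  ad_ref <- dp - ad_alt
  tibble(variant_id = rep(variant_id, ns),
         sample = rep(sprintf("S%03d", seq_len(ns)), each = nv),
         gt = gt, dp = as.integer(dp), gq = as.integer(gq),
         ad_ref = as.integer(ad_ref), ad_alt = as.integer(ad_alt))
}

sim_features <- function(cfg) {
  cz <- cfg$chrom_sizes
  out <- list()
  for (i in seq_len(nrow(cfg$feature_config))) {
    fc <- cfg$feature_config[i, ]
    n <- fc$n_intervals
    chrom <- sample(cz$chrom, n, replace = TRUE,
                    prob = cz$size / sum(cz$size))
    len <- pmax(50, round(stats::rexp(n, 1 / fc$mean_length)))
    size <- cz$size[match(chrom, cz$chrom)]
    len <- pmin(len, size - 1)
    start <- floor(runif(n) * (size - len))
    out[[fc$name]] <- tibble(chrom = chrom, start = start,
                             end = start + len) %>%
      arrange(.data$chrom, .data$start)
  }
  out
}

#' Generate a synthetic cohort/reference study
#'
#' Draws variant positions per genome bin as Poisson with rate
#' `background_rate * multiplier` (planted bins only affect the cohort),
#' assigns alleles, SVs, catalog membership (novelty), optional per-sample
#' genotype fields, regulatory feature sets, gene models and an RP score
#' track, and records the planted truth.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with elements `cohort` and `reference` ([callset()]s),
#'   `catalog` ([catalog()]), `features` (named list of interval tibbles),
#'   `genes`, `rp_track`, `chrom_sizes` and `truth` (planted bins, feature
#'   multipliers, catalog probability, seed).
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cz <- cfg$chrom_sizes

  # stage 1-2: cohort / reference positions
  set.seed(stage_seed(cfg$seed, 1))
  cohort_sites <- sim_sites(cfg, cfg$planted_bins)
  set.seed(stage_seed(cfg$seed, 2))
  ref_sites <- sim_sites(cfg, cfg$planted_bins[0, ])

  # stage 3: alleles + site quality
  set.seed(stage_seed(cfg$seed, 3))
  ca <- sim_alleles(nrow(cohort_sites), cfg)
  ra <- sim_alleles(nrow(ref_sites), cfg)
  cohort_v <- mutate(cohort_sites, ref = ca$ref, alt = ca$alt,
                     qual = round(rgamma(nrow(cohort_sites), shape = 20,
                                         rate = 20 / cfg$qual_mean), 2),
                     var_class = ca$var_class, sv_end = NA_integer_)
  ref_v <- mutate(ref_sites, ref = ra$ref, alt = ra$alt,
                  qual = round(rgamma(nrow(ref_sites), shape = 20,
                                      rate = 20 / cfg$qual_mean), 2),
                  var_class = ra$var_class, sv_end = NA_integer_)

  # stage 4: structural variants
  set.seed(stage_seed(cfg$seed, 4))
  sv <- sim_sv(cfg)
  cohort_v <- bind_rows(cohort_v, sv)
  cohort_v <- cohort_v[order(cohort_v$chrom, cohort_v$pos), ]
  if (cfg$sim_genotypes) {
    cohort_v$variant_id <- variant_key(cohort_v)
    ref_v$variant_id <- variant_key(ref_v)
  }

  # stage 5: feature sets, genes, RP track
  set.seed(stage_seed(cfg$seed, 5))
  features <- sim_features(cfg)
  genes <- sim_genes(cfg)
  rp_track <- sim_rp_track(cfg)

  # stage 6: catalog membership (novelty), boosted inside flagged features
  set.seed(stage_seed(cfg$seed, 6))
  p_novel <- rep(1 - cfg$catalog_prob, nrow(cohort_v))
  for (i in seq_len(nrow(cfg$feature_config))) {
    fc <- cfg$feature_config[i, ]
    if (fc$novel_multiplier != 1) {
      inside <- intersect_variants(cohort_v, features[[fc$name]])
      p_novel[inside] <- pmin(1, p_novel[inside] * fc$novel_multiplier)
    }
  }
  truly_novel <- runif(nrow(cohort_v)) < p_novel
  is_sv <- grepl("^SV_", cohort_v$var_class)
  known <- cohort_v[!truly_novel, , drop = FALSE]
  cat_snv <- known[!grepl("^SV_", known$var_class),
                   c("chrom", "pos", "ref", "alt")]
  decoys <- sim_catalog_decoys(cfg, exclude = cat_snv)
  cat_sv <- if (any(is_sv & !truly_novel)) {
    k <- cohort_v[is_sv & !truly_novel, ]
    tibble(chrom = k$chrom, start = k$pos - 1, end = k$sv_end,
           type = sub("^SV_", "", k$var_class))
  } else NULL
  cat_obj <- catalog(bind_rows(cat_snv, decoys), cat_sv)

  # stage 7-8: genotype fields
  gt_cohort <- gt_ref <- NULL
  if (cfg$sim_genotypes) {
    set.seed(stage_seed(cfg$seed, 7))
    gt_cohort <- sim_genotype_table(cohort_v$variant_id,
                                    cfg$n_samples_cohort, cfg)
    set.seed(stage_seed(cfg$seed, 8))
    gt_ref <- sim_genotype_table(ref_v$variant_id,
                                 cfg$n_samples_reference, cfg)
  }

  truth <- list(
    planted_bins = cfg$planted_bins,
    feature_multipliers = setNames(cfg$feature_config$novel_multiplier,
                                   cfg$feature_config$name),
    catalog_prob = cfg$catalog_prob,
    # aligned with the cohort variant table's row order
    truly_novel = truly_novel,
    seed = cfg$seed
  )

  list(
    cohort = callset(cohort_v, gt_cohort, label = "cohort",
                     n_samples = cfg$n_samples_cohort),
    reference = callset(ref_v, gt_ref, label = "reference",
                        n_samples = cfg$n_samples_reference),
    catalog = cat_obj,
    features = features,
    genes = genes,
    rp_track = rp_track,
    chrom_sizes = cz,
    truth = truth
  )
}

sim_sv <- function(cfg) {
  cz <- cfg$chrom_sizes
  n <- cfg$n_sv
  if (n == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), qual = double(), var_class = character(),
                  sv_end = integer()))
  }
  chrom <- sample(cz$chrom, n, replace = TRUE, prob = cz$size / sum(cz$size))
  size <- cz$size[match(chrom, cz$chrom)]
  len <- as.integer(round(runif(n, 1e3, 1e5)))
  pos <- as.integer(floor(runif(n) * (size - len)) + 1)
  type <- sample(c("DEL", "DUP", "INV"), n, replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  tibble(chrom = chrom, pos = pos, ref = "N",
         alt = sprintf("<%s>", type),
         qual = round(rgamma(n, shape = 20, rate = 20 / cfg$qual_mean), 2),
         var_class = paste0("SV_", type),
         sv_end = pos + len) %>%
    distinct(.data$chrom, .data$pos, .keep_all = TRUE)
}

sim_genes <- function(cfg, n_genes = 200L) {
  cz <- cfg$chrom_sizes
  chrom <- sample(cz$chrom, n_genes, replace = TRUE,
                  prob = cz$size / sum(cz$size))
  size <- cz$size[match(chrom, cz$chrom)]
  len <- as.integer(round(runif(n_genes, 5e3, 5e4)))
  start <- floor(runif(n_genes) * (size - len))
  tibble(chrom = chrom, start = start, end = start + len,
         name = sprintf("gene%04d", seq_len(n_genes))) %>%
    arrange(.data$chrom, .data$start)
}

sim_rp_track <- function(cfg, n_intervals = 600L) {
  cz <- cfg$chrom_sizes
  chrom <- sample(cz$chrom, n_intervals, replace = TRUE,
                  prob = cz$size / sum(cz$size))
  size <- cz$size[match(chrom, cz$chrom)]
  len <- pmax(200, round(stats::rexp(n_intervals, 1 / 2000)))
  start <- floor(runif(n_intervals) * (size - len))
  tibble(chrom = chrom, start = start, end = start + len,
         name = sprintf("rp%04d", seq_len(n_intervals)),
         score = round(rbeta(n_intervals, 1, 2), 4)) %>%
    arrange(.data$chrom, .data$start)
}

# decoy entries make the catalog a superset of the cohort's known keys, as a
# real archive is; collisions with known cohort keys are harmless (already
# known) and are the only ones excluded. A decoy landing on a *novel* cohort
# key is possible but has probability ~1e-4 per decoy at the default density.
sim_catalog_decoys <- function(cfg, exclude, n_decoys = 1000L) {
  cz <- cfg$chrom_sizes
  chrom <- sample(cz$chrom, n_decoys, replace = TRUE,
                  prob = cz$size / sum(cz$size))
  pos <- as.integer(floor(runif(n_decoys) *
                            cz$size[match(chrom, cz$chrom)]) + 1)
  ref <- sample(BASES, n_decoys, replace = TRUE)
  alt <- unname(TRANSITION[ref])
  out <- tibble(chrom = chrom, pos = pos, ref = ref, alt = alt)
  # positional collision check (stricter than full-key; collisions are rare)
  key_out <- match(out$chrom, cz$chrom) * 2^33 + out$pos
  key_ex <- match(exclude$chrom, cz$chrom) * 2^33 + exclude$pos
  out[!key_out %in% key_ex, , drop = FALSE]
}

#' Write a generated study to disk as plain-text fixtures
#'
#' Emits exactly the formats the readers consume: two VCFs, a 4-column
#' catalog TSV plus a typed SV BED, a chromosome-size TSV, one BED per
#' feature set, gene and RP-track BEDs, and a truth JSON.
#'
#' @param study Output of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "features"), showWarnings = FALSE)
  paths <- c(
    cohort = file.path(dir, "cohort.vcf"),
    reference = file.path(dir, "reference.vcf"),
    catalog = file.path(dir, "catalog.tsv"),
    catalog_sv = file.path(dir, "catalog_sv.bed"),
    chrom_sizes = file.path(dir, "chrom_sizes.tsv"),
    genes = file.path(dir, "genes.bed"),
    rp_track = file.path(dir, "rp_track.bed"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(study$cohort, paths["cohort"], study$chrom_sizes)
  write_vcf(study$reference, paths["reference"], study$chrom_sizes)
  snv_keys <- study$catalog$keys
  parts <- strsplit(snv_keys, ":", fixed = TRUE)
  cat_tbl <- tibble(chrom = vapply(parts, `[`, "", 1),
                    pos = vapply(parts, `[`, "", 2),
                    ref = vapply(parts, `[`, "", 3),
                    alt = vapply(parts, `[`, "", 4))
  readr::write_tsv(cat_tbl, paths["catalog"], col_names = FALSE,
                   progress = FALSE)
  sv <- study$catalog$sv
  if (is.null(sv)) {
    sv <- tibble(chrom = character(), start = double(), end = double(),
                 type = character())
  }
  write_bed(dplyr::rename(sv, name = "type"), paths["catalog_sv"])
  readr::write_tsv(study$chrom_sizes, paths["chrom_sizes"],
                   col_names = FALSE, progress = FALSE)
  write_bed(study$genes, paths["genes"])
  write_bed(study$rp_track, paths["rp_track"])
  for (nm in names(study$features)) {
    p <- file.path(dir, "features", paste0(nm, ".bed"))
    write_bed(study$features[[nm]], p)
    paths[paste0("feature_", nm)] <- p
  }
  truth <- study$truth
  truth$truly_novel <- NULL  # keyed vector is session state, not a fixture
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
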