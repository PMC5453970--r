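# Small in-code fixtures shared across test files.

toy_variants <- function(pos = c(100L, 200L, 300L),
                         ref = c("A", "C", "G"),
                         alt = c("G", "T", "A"),
                         chrom = "chr1",
                         qual = 50) {
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt, qual = qual)
}

# one variant, one sample per row of the given genotype spec
toy_callset <- function(gt = c("0/1", "0/1", "1/1"),
                        dp = 30L, gq = 60L, qual = 50,
                        ref = NULL, alt = NULL) {
  n <- length(gt)
  v <- toy_variants(pos = seq(100L, by = 100L, length.out = n),
                    ref = ref %||% rep("A", n),
                    alt = alt %||% rep("G", n),
                    qual = qual)
  v$variant_id <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  het <- gt %in% c("0/1", "1/0", "0|1", "1|0")
  g <- tibble::tibble(
    variant_id = v$variant_id, sample = "S1", gt = gt,
    dp = as.integer(dp), gq = as.integer(gq),
    ad_ref = as.integer(ifelse(het, dp %/% 2, ifelse(gt == "1/1", 0L, dp))),
    ad_alt = as.integer(ifelse(het, dp - dp %/% 2, ifelse(gt == "1/1", dp, 0L)))
  )
  callset(v, g, label = "toy")
}

# brute-force hypergeometric upper-tail oracle for a 2x2 table
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(probs[xs >= a])
}

tiny_study_config <- function(seed = 11, ...) {
  synthetic_config(
    seed = seed,
    chrom_sizes = c(chr1 = 1e6, chr2 = 1e6),
    n_samples_cohort = 6, n_samples_reference = 3,
    n_sv = 25, planted_bins = NULL, ...
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
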