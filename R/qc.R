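#' Heterozygous-to-homozygous ratio of one sample
#'
#' Ratio of heterozygous to homozygous-alternate genotype calls; hom-ref
#' sites and missing genotypes are ignored (a VCF of variant sites carries no
#' informative hom-ref denominator). Genome-wide human values sit near 1.5.
#'
#' @param gt Character vector of genotypes (`"0/1"`, `"1/1"`, `"0|1"`, ...).
#' @return The ratio, or `NA` when there is no hom-alt call.
#' @export
#' @examples
#' het_hom_ratio(c("0/1", "0/1", "1/1"))  # 2
het_hom_ratio <- function(gt) {
  het <- sum(is_het(gt), na.rm = TRUE)
  hom <- sum(is_hom_alt(gt), na.rm = TRUE)
  if (hom == 0) return(NA_real_)
  het / hom
}

#' Transition/transversion ratio of a SNP set
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine changes
#' (A<->G, C<->T); all other single-base changes are transversions. Deep
#' whole-genome call sets are expected near 2.0.
#'
#' @param ref,alt Single-base reference/alternate alleles (non-SNP rows may
#'   be passed and are ignored).
#' @return Ti/Tv ratio, or `NA` when there is no transversion.
#' @export
#' @examples
#' titv_ratio(c("A", "C", "A"), c("G", "T", "C"))  # 2
titv_ratio <- function(ref, alt) {
  snp <- nchar(ref) == 1 & nchar(alt) == 1 & ref != alt
  ref <- toupper(ref[snp]); alt <- toupper(alt[snp])
  ti <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
        (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  n_ti <- sum(ti)
  n_tv <- sum(!ti)
  if (n_tv == 0) return(NA_real_)
  n_ti / n_tv
}

#' Concordance rate between two call sets
#'
#' The percentage of the observed set's variants whose exact
#' (chrom, pos, ref, alt) key also occurs in the other set. Asymmetric by
#' construction: the denominator is the observed set.
#'
#' @param observed,other [callset()]s or variant tibbles.
#' @return Percentage in `[0, 100]`.
#' @export
concordance_rate <- function(observed, other) {
  a <- unique(ensure_key(as_variants(observed))$variant_id)
  b <- unique(ensure_key(as_variants(other))$variant_id)
  if (length(a) == 0) abort("concordance undefined for an empty observed set")
  100 * sum(a %in% b) / length(a)
}

#' Variant counts per chromosome
#'
#' @param x A [callset()] or variant tibble.
#' @return Tibble with `chrom` and `n`, summing to the total record count.
#' @export
per_chrom_counts <- function(x) {
  v <- as_variants(x)
  if (nrow(v) == 0) return(tibble(chrom = character(), n = integer()))
  count(v, .data$chrom, name = "n")
}

#' Per-sample QC report
#'
#' One row per sample with call counts, Het/Hom, Ti/Tv and singleton count
#' (variants whose only carrier in the cohort is that sample), plus a final
#' cohort summary row (totals; ratio columns hold the cohort-wide values).
#'
#' @param cs A [callset()] with genotypes.
#' @return A tibble, one row per sample plus a `"<cohort>"` row.
#' @export
qc_report <- function(cs) {
  stopifnot(inherits(cs, "callset"))
  if (is.null(cs$genotypes)) abort("qc_report needs per-sample genotypes")
  g <- cs$genotypes
  v <- cs$variants
  g <- left_join(g, v[, c("variant_id", "ref", "alt", "var_class")],
                 by = "variant_id")
  carrier <- !is.na(g$gt) & n_alt_alleles(g$gt) > 0
  carriers_per_variant <- tapply(carrier, g$variant_id, sum)
  singleton_ids <- names(carriers_per_variant)[carriers_per_variant == 1]
  g$is_singleton_carrier <- carrier & g$variant_id %in% singleton_ids

  per_sample <- g %>%
    group_by(.data$sample) %>%
    summarise(
      n_calls = sum(!is.na(.data$gt) & n_alt_alleles(.data$gt) > 0),
      n_het = sum(is_het(.data$gt), na.rm = TRUE),
      n_hom_alt = sum(is_hom_alt(.data$gt), na.rm = TRUE),
      het_hom = het_hom_ratio(.data$gt),
      titv = titv_ratio(.data$ref[!is.na(.data$gt) & .data$var_class == "SNP" &
                                    n_alt_alleles(.data$gt) > 0],
                        .data$alt[!is.na(.data$gt) & .data$var_class == "SNP" &
                                    n_alt_alleles(.data$gt) > 0]),
      n_singletons = sum(.data$is_singleton_carrier),
      .groups = "drop"
    )
  cohort <- tibble(
    sample = "<cohort>",
    n_calls = sum(per_sample$n_calls),
    n_het = sum(per_sample$n_het),
    n_hom_alt = sum(per_sample$n_hom_alt),
    het_hom = if (sum(per_sample$n_hom_alt) > 0)
      sum(per_sample$n_het) / sum(per_sample$n_hom_alt) else NA_real_,
    titv = titv_ratio(v$ref[v$var_class == "SNP"],
                      v$alt[v$var_class == "SNP"]),
    n_singletons = sum(per_sample$n_singletons)
  )
  bind_rows(per_sample, cohort)
}

#' Write a QC report as TSV
#'
#' @param report Output of [qc_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  readr::write_tsv(report, path, progress = FALSE)
  invisible(path)
}
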