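#' Construct a call set
#'
#' A call set bundles a variant table with the per-sample genotype table of a
#' multi-sample VCF, plus a free-text label. Variant positions are 1-based
#' (VCF convention); all interval containers elsewhere in the package are
#' 0-based half-open (BED convention), converted exactly once at parse time.
#'
#' @param variants A data frame with at least `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `qual`. `var_class` is derived with [classify_variant()] when
#'   absent; `sv_end` (1-based inclusive end) is required for SV classes.
#' @param genotypes Long per-sample table with columns `variant_id`, `sample`,
#'   `gt` (e.g. `"0/1"`, `NA` for missing), `dp`, `gq`, `ad_ref`, `ad_alt`.
#'   May be `NULL` for site-only call sets.
#' @param label Free-text provenance label.
#' @param n_samples Sample count; inferred from `genotypes` when `NULL`.
#'
#' @return An object of class `callset`.
#' @export
#' @examples
#' v <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
#'                     qual = 50)
#' callset(v, label = "toy")
callset <- function(variants, genotypes = NULL, label = "callset",
                    n_samples = NULL) {
  variants <- as_tibble(variants)
  needed <- c("chrom", "pos", "ref", "alt", "qual")
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols) > 0) {
    abort(paste0("variants table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(variants) > 0 && any(variants$pos < 1, na.rm = TRUE)) {
    abort("variant positions must be >= 1 (1-based VCF convention)")
  }
  if (!"var_class" %in% names(variants)) {
    variants$var_class <- classify_variant(variants$ref, variants$alt)
  }
  if (!"sv_end" %in% names(variants)) variants$sv_end <- NA_integer_
  # the key column links genotypes to variants; for site-only call sets it
  # is added lazily by as_variants() on first use
  if (!"variant_id" %in% names(variants) && !is.null(genotypes)) {
    variants$variant_id <- variant_key(variants)
  }
  is_sv <- grepl("^SV_", variants$var_class)
  if (any(is_sv) &&
      any(is.na(variants$sv_end[is_sv]) |
          variants$sv_end[is_sv] <= variants$pos[is_sv])) {
    abort("SV records require sv_end > pos")
  }
  if (!is.null(genotypes)) {
    genotypes <- as_tibble(genotypes)
    gneed <- c("variant_id", "sample", "gt", "dp", "gq", "ad_ref", "ad_alt")
    gmiss <- setdiff(gneed, names(genotypes))
    if (length(gmiss) > 0) {
      abort(paste0("genotypes table lacks column(s): ",
                   paste(gmiss, collapse = ", ")))
    }
    if (is.null(n_samples)) n_samples <- dplyr::n_distinct(genotypes$sample)
  }
  n_samples <- as.integer(n_samples %||% 0L)
  structure(
    list(variants = variants, genotypes = genotypes, label = label,
         n_samples = n_samples),
    class = "callset"
  )
}

variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Coerce a call set or data frame to a variant tibble
#'
#' Most analysis functions accept either a [callset()] or a plain variant
#' table; this is the common coercion.
#'
#' @param x A `callset` or data frame of variants.
#' @return A tibble of variants.
#' @export
as_variants <- function(x) {
  if (inherits(x, "callset")) x <- x$variants
  as_tibble(x)
}

# add the (chrom,pos,ref,alt) key column where a consumer needs it
ensure_key <- function(v) {
  if (!"variant_id" %in% names(v)) v$variant_id <- variant_key(v)
  v
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("<callset> %s: %d variants, %d samples\n",
              x$label, nrow(x$variants), x$n_samples))
  print(x$variants, n = 5)
  invisible(x)
}

#' @describeIn callset Number of variant records.
#' @param x A `callset`.
#' @export
length.callset <- function(x) nrow(x$variants)

#' Tidy a call set into its variant table
#'
#' @param x A [callset()].
#' @param ... Unused.
#' @return The variant tibble (one row per record).
#' @method tidy callset
#' @export
tidy.callset <- function(x, ...) x$variants

#' One-row summary of a call set
#'
#' @param x A [callset()].
#' @param ... Unused.
#' @return A one-row tibble with label, sample count and per-class totals.
#' @method glance callset
#' @export
glance.callset <- function(x, ...) {
  v <- x$variants
  tibble(
    label = x$label,
    n_samples = x$n_samples,
    n_variants = nrow(v),
    n_snp = sum(v$var_class == "SNP"),
    n_insertion = sum(v$var_class == "INSERTION"),
    n_deletion = sum(v$var_class == "DELETION"),
    n_sv = sum(grepl("^SV_", v$var_class))
  )
}
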