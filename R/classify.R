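#' Classify a variant by its alleles
#'
#' Sequence-resolved records are classified from allele lengths: equal-length
#' single bases are SNPs; length differences of 1-50 bp are small insertions
#' or deletions; anything larger, or any record carrying an explicit SV type
#' tag, is a structural variant (`SV_DEL`, `SV_DUP`, `SV_INV`).
#'
#' @param ref,alt Character vectors of reference/alternate alleles. A
#'   comma-separated `alt` (multi-allelic record) is rejected: the pipeline
#'   operates on bi-allelic records and multi-allelics must be split upstream.
#' @param sv_type Optional SV type tag per record (`"DEL"`, `"DUP"`, `"INV"`),
#'   `NA` where absent.
#' @param sv_len Optional SV length in bp (unused for classification beyond
#'   the tag, retained for interface symmetry).
#' @param max_indel Largest length difference (bp) still called an indel
#'   (default 50).
#'
#' @return Character vector with values in
#'   `SNP, INSERTION, DELETION, SV_DEL, SV_DUP, SV_INV`.
#' @export
#' @examples
#' classify_variant("A", "G")            # SNP
#' classify_variant("A", "AT")           # INSERTION
#' classify_variant("ACGTACGT", "A")     # DELETION
#' classify_variant("N", "<DEL>", sv_type = "DEL", sv_len = 5000)  # SV_DEL
classify_variant <- function(ref, alt, sv_type = NULL, sv_len = NULL,
                             max_indel = 50L) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  sv_type <- if (is.null(sv_type)) rep(NA_character_, n) else
    rep_len(as.character(sv_type), n)

  if (any(grepl(",", alt, fixed = TRUE))) {
    bad <- which(grepl(",", alt, fixed = TRUE))[1]
    abort(sprintf(
      "multi-allelic record (alt = '%s'): split required before analysis",
      alt[bad]))
  }
  has_tag <- !is.na(sv_type) & sv_type != ""
  symbolic <- grepl("^<.*>$", alt)
  if (any(!has_tag & !symbolic & (is.na(ref) | ref == "" | is.na(alt) | alt == ""))) {
    abort("ref and alt must be non-empty for sequence-resolved records")
  }

  out <- rep(NA_character_, n)
  out[has_tag] <- paste0("SV_", toupper(sv_type[has_tag]))

  plain <- !has_tag
  size <- abs(nchar(ref) - nchar(alt))
  out[plain & nchar(ref) == 1 & nchar(alt) == 1] <- "SNP"
  ins <- plain & nchar(alt) > nchar(ref)
  del <- plain & nchar(ref) > nchar(alt)
  out[ins & size <= max_indel] <- "INSERTION"
  out[del & size <= max_indel] <- "DELETION"
  out[ins & size > max_indel] <- "SV_DUP"
  out[del & size > max_indel] <- "SV_DEL"
  if (any(is.na(out))) {
    abort("unclassifiable record (same-length multi-base substitution?)")
  }
  bad_class <- !out %in% c("SNP", "INSERTION", "DELETION",
                           "SV_DEL", "SV_DUP", "SV_INV")
  if (any(bad_class)) {
    abort(sprintf("unknown SV type tag: %s",
                  paste(unique(sv_type[bad_class]), collapse = ", ")))
  }
  out
}

#' Minor-read ratio of a heterozygous call
#'
#' The minor-read ratio (MRR) is the smaller of the reference- and
#' alternate-supporting read counts divided by their sum; a balanced
#' heterozygote has MRR 0.5 and strongly skewed support pushes it toward 0.
#'
#' @param ad_ref,ad_alt Non-negative read counts supporting the reference and
#'   alternate allele (the two components of the VCF `AD` field).
#' @return Numeric vector in `[0, 0.5]`; `NA` when total depth is zero
#'   (such calls fail filtering).
#' @export
#' @examples
#' compute_mrr(10, 30)  # 0.25
#' compute_mrr(20, 20)  # 0.5
compute_mrr <- function(ad_ref, ad_alt) {
  total <- ad_ref + ad_alt
  out <- pmin(ad_ref, ad_alt) / total
  out[!is.na(total) & total == 0] <- NA_real_
  out
}
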