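#' Hard-filter thresholds for variant retention
#'
#' Defaults follow the common deep-WGS hard-filtering recipe: per-sample read
#' depth >= 20x, genotype quality >= 20 (Phred), site variant quality >= 30
#' (Phred) and, for heterozygous calls, minor-read ratio >= 0.2. All criteria
#' are inclusive at the boundary.
#'
#' @param min_dp Minimum per-sample read depth (reads).
#' @param min_gq Minimum genotype quality (Phred).
#' @param min_qual Minimum site variant quality (Phred).
#' @param min_mrr Minimum minor-read ratio of heterozygous calls (fraction,
#'   at most 0.5).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_dp = 20, min_gq = 20, min_qual = 30,
                              min_mrr = 0.2) {
  stopifnot(min_dp >= 0, min_gq >= 0, min_qual >= 0,
            min_mrr >= 0, min_mrr <= 0.5)
  structure(list(min_dp = min_dp, min_gq = min_gq, min_qual = min_qual,
                 min_mrr = min_mrr),
            class = "filter_thresholds")
}

#' Apply hard filters to a call set
#'
#' A record is retained iff its site quality passes and at least one
#' non-missing sample call passes all per-sample criteria (depth, genotype
#' quality and, for heterozygous calls only, minor-read ratio). Missing
#' genotypes (`./.`) never contribute. A site-only call set (no genotype
#' table) is filtered on site quality alone.
#'
#' @param cs A [callset()].
#' @param thresholds A [filter_thresholds()] object.
#' @return A `callset` containing the retained records (genotype rows of
#'   dropped records are removed too). Filtering is idempotent.
#' @export
filter_callset <- function(cs, thresholds = filter_thresholds()) {
  stopifnot(inherits(cs, "callset"), inherits(thresholds, "filter_thresholds"))
  v <- cs$variants
  qual_ok <- !is.na(v$qual) & v$qual >= thresholds$min_qual

  if (is.null(cs$genotypes)) {
    keep <- qual_ok
    gt_keep <- NULL
  } else {
    g <- cs$genotypes
    is_called <- !is.na(g$gt) & !grepl("\\.", g$gt)
    het <- is_called & is_het(g$gt)
    mrr <- compute_mrr(g$ad_ref, g$ad_alt)
    sample_pass <- is_called &
      !is.na(g$dp) & g$dp >= thresholds$min_dp &
      !is.na(g$gq) & g$gq >= thresholds$min_gq &
      (!het | (!is.na(mrr) & mrr >= thresholds$min_mrr))
    ok_ids <- unique(g$variant_id[sample_pass])
    keep <- qual_ok & v$variant_id %in% ok_ids
    gt_keep <- g[g$variant_id %in% v$variant_id[keep], , drop = FALSE]
  }

  callset(v[keep, , drop = FALSE], gt_keep, label = cs$label,
          n_samples = cs$n_samples)
}

# "0/1", "1|0" etc. -> TRUE; missing / half-missing -> NA
is_het <- function(gt) {
  a <- gt_alleles(gt)
  ifelse(is.na(a$a1) | is.na(a$a2), NA, a$a1 != a$a2)
}

is_hom_alt <- function(gt) {
  a <- gt_alleles(gt)
  ifelse(is.na(a$a1) | is.na(a$a2), NA, a$a1 == a$a2 & a$a1 > 0)
}

gt_alleles <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) >= 1) p[1] else NA_character_, character(1))))
  a2 <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) >= 2) p[2] else NA_character_, character(1))))
  list(a1 = a1, a2 = a2)
}

n_alt_alleles <- function(gt) {
  a <- gt_alleles(gt)
  (a$a1 > 0) + (a$a2 > 0)
}
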