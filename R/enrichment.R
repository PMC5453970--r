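#' Flag variants inside a feature set
#'
#' A sequence-resolved variant at 1-based position p is inside a 0-based
#' half-open interval `[start, end)` iff `start <= p - 1 < end`; indels are
#' anchored at their leftmost affected base. A variant covered by several
#' overlapping intervals is flagged once, so merging a feature set never
#' changes any flag.
#'
#' @param x A [callset()] or variant tibble.
#' @param features Interval tibble with `chrom`, `start`, `end`.
#' @return Logical vector, one flag per variant record.
#' @export
intersect_variants <- function(x, features) {
  v <- as_variants(x)
  features <- as_tibble(features)
  if (nrow(v) == 0) return(logical(0))
  if (nrow(features) == 0) return(rep(FALSE, nrow(v)))
  q <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  s <- GenomicRanges::GRanges(features$chrom,
                              IRanges::IRanges(features$start + 1,
                                               features$end))
  GenomicRanges::countOverlaps(q, s) > 0
}

new_enrichment <- function(a, b, c, d, class_in = "class1",
                           feature = "features") {
  odds <- (a * d) / (b * c)
  fold <- if (a + b > 0 && c + d > 0 && c > 0) {
    (a / (a + b)) / (c / (c + d))
  } else if (a + b > 0 && a > 0 && c == 0) Inf else NA_real_
  p <- if (a + b > 0 && c + d > 0) fisher_exact_greater(a, b, c, d)
       else NA_real_
  out <- tibble(class = class_in, feature = feature,
                a = a, b = b, c = c, d = d,
                odds_ratio = odds, fold = fold, p = p)
  class(out) <- c("varscape_enrichment", class(out))
  out
}

#' Fisher enrichment of novel variants within a feature set
#'
#' Builds the 2x2 table (novel-in, novel-out; known-in, known-out) from the
#' variants' novelty flags and feature membership, and tests one-sided for
#' over-representation of novel variants inside the features.
#'
#' @param x A [callset()] or variant tibble carrying a logical `novel`
#'   column (see [mark_novelty()]).
#' @param features Interval tibble (`chrom`, `start`, `end`).
#' @param feature_name Label used in the result row.
#' @return A one-row tibble of class `varscape_enrichment` with the four
#'   counts, odds ratio, density fold and p-value.
#' @export
novel_enrichment <- function(x, features, feature_name = "features") {
  v <- as_variants(x)
  if (!"novel" %in% names(v)) abort("novelty flags missing: run mark_novelty()")
  if (!any(v$novel)) abort("no novel variants: enrichment undefined")
  inside <- intersect_variants(v, features)
  new_enrichment(a = sum(v$novel & inside), b = sum(v$novel & !inside),
                 c = sum(!v$novel & inside), d = sum(!v$novel & !inside),
                 class_in = "novel", feature = feature_name)
}

#' Look up regulatory-potential scores for variants
#'
#' Each variant takes the score of the interval containing its position;
#' when several scored intervals overlap, the maximum wins. Variants with no
#' covering interval get `NA`.
#'
#' @param x A [callset()] or variant tibble.
#' @param rp_track Scored intervals: `chrom`, `start`, `end`, `score` in
#'   `[0, 1]`.
#' @return Numeric vector of scores, one per variant.
#' @export
rp_lookup <- function(x, rp_track) {
  v <- as_variants(x)
  rp_track <- as_tibble(rp_track)
  stopifnot("score" %in% names(rp_track))
  if (any(rp_track$score < 0 | rp_track$score > 1, na.rm = TRUE)) {
    abort("RP scores must lie in [0, 1]")
  }
  out <- rep(NA_real_, nrow(v))
  if (nrow(v) == 0 || nrow(rp_track) == 0) return(out)
  q <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  s <- GenomicRanges::GRanges(rp_track$chrom,
                              IRanges::IRanges(rp_track$start + 1,
                                               rp_track$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  if (length(hits) > 0) {
    best <- tapply(rp_track$score[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), max)
    out[as.integer(names(best))] <- as.numeric(best)
  }
  out
}

#' Enrichment of high-RP variants within interval blocks
#'
#' Variants are scored against the RP track ([rp_lookup()]; uncovered
#' variants are excluded), split at `rp_min` (inclusive: a score equal to
#' the threshold counts as high), and cross-tabulated against block
#' membership: (high-RP in blocks, low-RP in blocks; high-RP outside,
#' low-RP outside). One-sided Fisher tests whether the in-block high-RP
#' proportion exceeds the out-of-block proportion; the fold is the ratio of
#' those proportions.
#'
#' @param x A [callset()] or variant tibble.
#' @param rp_track Scored intervals (`score` in `[0, 1]`).
#' @param blocks Interval tibble (e.g. LD blocks).
#' @param rp_min High/low score boundary (default 0.5, inclusive on high).
#' @return A one-row `varscape_enrichment` tibble.
#' @export
rp_threshold_enrichment <- function(x, rp_track, blocks, rp_min = 0.5) {
  v <- as_variants(x)
  score <- rp_lookup(v, rp_track)
  keep <- !is.na(score)
  if (!any(keep)) abort("no variant is covered by the RP track")
  v <- v[keep, , drop = FALSE]
  score <- score[keep]
  in_block <- intersect_variants(v, blocks)
  high <- score >= rp_min
  new_enrichment(a = sum(high & in_block), b = sum(!high & in_block),
                 c = sum(high & !in_block), d = sum(!high & !in_block),
                 class_in = sprintf("RP>=%g", rp_min), feature = "blocks")
}

#' One-sided rank-sum (Mann-Whitney) test
#'
#' Tests whether `x` is stochastically greater than `y` (default side).
#' Small untied samples (both sizes <= 20) use the exact null distribution;
#' larger or tied samples use the tie-corrected normal approximation.
#'
#' @param x,y Numeric metric values (e.g. per-variant sequencing depth).
#' @param side `"greater"` (x greater), `"less"`, or `"two.sided"`.
#' @return A one-row tibble with `statistic` (U for `x`), `p`, and `method`.
#' @export
#' @examples
#' rank_sum_test(c(4, 5, 6), c(1, 2, 3))$p  # 0.05 = 1/choose(6,3)
rank_sum_test <- function(x, y, side = c("greater", "less", "two.sided")) {
  side <- match.arg(side)
  if (length(x) == 0 || length(y) == 0) {
    abort("rank_sum_test needs non-empty samples")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 20 && length(y) <= 20
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = side, exact = exact,
                correct = !exact)
  )
  tibble(statistic = unname(res$statistic), p = res$p.value,
         method = if (exact) "exact" else "normal approximation")
}

#' Enrichment report across variant types and feature sets
#'
#' One row per (variant type, feature set): the novel-vs-known Fisher
#' enrichment of [novel_enrichment()], computed for SNPs and for indels
#' (insertions plus deletions), with an additional BH-FDR column across the
#' report's rows. Rows are ordered by variant type then feature name.
#'
#' @param x A [callset()] or variant tibble with `novel` flags.
#' @param feature_sets Named list of interval tibbles.
#' @return A tibble of class `varscape_enrichment`, one row per combination.
#' @export
feature_enrichment_report <- function(x, feature_sets) {
  stopifnot(is.list(feature_sets), !is.null(names(feature_sets)))
  v <- as_variants(x)
  if (!"novel" %in% names(v)) abort("novelty flags missing: run mark_novelty()")
  types <- list(SNP = v$var_class == "SNP",
                INDEL = v$var_class %in% c("INSERTION", "DELETION"))
  rows <- purrr::map_dfr(sort(names(types)), function(ty) {
    sub <- v[types[[ty]], , drop = FALSE]
    purrr::map_dfr(sort(names(feature_sets)), function(fn) {
      if (nrow(sub) == 0 || !any(sub$novel) || all(sub$novel)) {
        return(new_enrichment(0, sum(sub$novel), 0, sum(!sub$novel),
                              class_in = ty, feature = fn) %>%
                 mutate(p = NA_real_, odds_ratio = NA_real_,
                        fold = NA_real_))
      }
      novel_enrichment(sub, feature_sets[[fn]], feature_name = fn) %>%
        mutate(class = ty)
    })
  })
  rows$fdr <- p.adjust(rows$p, method = "BH")
  class(rows) <- c("varscape_enrichment", class(rows))
  rows
}

#' Tidy an enrichment result
#'
#' @param x A `varscape_enrichment` tibble.
#' @param ... Unused.
#' @return A plain tibble with one row per test: counts, `estimate`
#'   (odds ratio), `fold` and `p.value`.
#' @method tidy varscape_enrichment
#' @export
tidy.varscape_enrichment <- function(x, ...) {
  as_tibble(x) %>%
    mutate(estimate = .data$odds_ratio, p.value = .data$p) %>%
    select("class", "feature", "a", "b", "c", "d", "estimate", "fold",
           "p.value", dplyr::any_of("fdr"))
}

#' Summarise an enrichment result
#'
#' @param x A `varscape_enrichment` tibble.
#' @param ... Unused.
#' @return One-row tibble: number of tests, number significant at 0.05, and
#'   the smallest p-value.
#' @method glance varscape_enrichment
#' @export
glance.varscape_enrichment <- function(x, ...) {
  tibble(n_tests = nrow(x),
         n_sig_05 = sum(x$p <= 0.05, na.rm = TRUE),
         min_p = suppressWarnings(min(x$p, na.rm = TRUE)))
}
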