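#' Tidy a hotspot scan
#'
#' @param x A `varscape_hotspots` tibble from [call_hotspots()].
#' @param ... Unused.
#' @return A plain tibble with one row per bin and a `p.value` column.
#' @method tidy varscape_hotspots
#' @export
tidy.varscape_hotspots <- function(x, ...) {
  as_tibble(x) %>%
    mutate(p.value = .data$p) %>%
    select("chrom", "start", "end", "bin", "n_cohort", "n_reference",
           "fold", "p.value", "fdr", "is_hotspot",
           dplyr::any_of("genes"))
}

#' Summarise a hotspot scan
#'
#' @param x A `varscape_hotspots` tibble.
#' @param ... Unused.
#' @return One-row tibble: bins scanned, hotspots called, genome-wide totals
#'   and the thresholds used.
#' @method glance varscape_hotspots
#' @export
glance.varscape_hotspots <- function(x, ...) {
  totals <- attr(x, "totals")
  th <- attr(x, "thresholds")
  tibble(n_bins = nrow(x),
         n_hotspots = sum(x$is_hotspot),
         total_cohort = unname(totals["cohort"]),
         total_reference = unname(totals["reference"]),
         fold_min = unname(th["fold_min"]),
         p_max = unname(th["p_max"]))
}
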