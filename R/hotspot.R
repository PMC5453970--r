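#' Tile a genome into fixed-width bins
#'
#' Bins are 0-based half-open, tile each chromosome without gap or overlap,
#' and the final bin of a chromosome may be shorter than `width`.
#'
#' @param chrom_sizes Chrom/size data frame or named numeric vector (bp).
#' @param width Bin width in bp (default 1 Mb).
#' @return Tibble with `chrom`, `start`, `end` and a per-chromosome 0-based
#'   `bin` index.
#' @export
#' @examples
#' make_bins(c(chrA = 2.5e6))
make_bins <- function(chrom_sizes, width = 1e6) {
  if (width <= 0) abort("bin width must be positive")
  cz <- as_chrom_sizes(chrom_sizes)
  n <- ceiling(cz$size / width)
  idx <- rep(seq_len(nrow(cz)), n)
  bin <- unlist(lapply(n, seq_len), use.names = FALSE) - 1L
  start <- bin * width
  tibble(chrom = cz$chrom[idx], start = start,
         end = pmin(start + width, cz$size[idx]), bin = bin)
}

#' Count variants per genome bin
#'
#' A variant at 1-based position p falls in the bin containing p - 1 (the
#' 0-based coordinate), so position 1,000,000 belongs to the first 1 Mb bin
#' and 1,000,001 to the second. Variants on chromosomes absent from the bins
#' are excluded with a warning.
#'
#' @param x A [callset()] or variant tibble.
#' @param bins Output of [make_bins()].
#' @return `bins` with an `n` count column.
#' @export
count_per_bin <- function(x, bins) {
  v <- as_variants(x)
  width <- max(bins$end - bins$start)
  chroms <- unique(bins$chrom)
  ci <- match(v$chrom, chroms)
  if (anyNA(ci)) {
    warn(sprintf("excluding %d variant(s) on chromosome(s) not in bins: %s",
                 sum(is.na(ci)),
                 paste(unique(v$chrom[is.na(ci)]), collapse = ", ")))
    v <- v[!is.na(ci), , drop = FALSE]
    ci <- ci[!is.na(ci)]
  }
  # bins are ordered by chromosome; global bin id = chrom row offset + index
  offset <- match(chroms, bins$chrom) - 1L
  gid <- offset[ci] + (v$pos - 1) %/% width + 1
  bins$n <- tabulate(gid, nbins = nrow(bins))
  bins
}

#' Density fold ratio between two populations for one bin
#'
#' The bin's share of cohort variants divided by its share of reference
#' variants: `(n_a_bin/total_a) / (n_b_bin/total_b)`. An empty reference bin
#' with a non-empty cohort bin yields `Inf` (still eligible for hotspot
#' status); an empty cohort bin yields 0. Scale-invariant in the four counts.
#'
#' @param n_a_bin,total_a Cohort count in the bin and genome-wide.
#' @param n_b_bin,total_b Reference count in the bin and genome-wide.
#' @return Numeric fold ratio.
#' @export
#' @examples
#' fold_ratio(30, 1000, 10, 1000)  # 3
fold_ratio <- function(n_a_bin, total_a, n_b_bin, total_b) {
  if (any(total_a <= 0) || any(total_b <= 0)) {
    abort("fold_ratio needs positive genome-wide totals")
  }
  pa <- n_a_bin / total_a
  pb <- n_b_bin / total_b
  out <- pa / pb
  out[n_a_bin == 0] <- 0
  out[n_a_bin > 0 & n_b_bin == 0] <- Inf
  out
}

#' One-sided Fisher exact test for a 2x2 table (enrichment direction)
#'
#' Exact hypergeometric upper tail `P(X >= a)` given the table margins, for
#' the table (a, b; c, d) with rows cohort/reference and columns
#' in-bin/out-of-bin. Vectorized over tables.
#'
#' @param a,b,c,d Non-negative counts; `a + b > 0` and `c + d > 0`.
#' @return p-value(s) in (0, 1].
#' @export
#' @examples
#' fisher_exact_greater(10, 0, 0, 10)  # 1/choose(20,10)
fisher_exact_greater <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("counts must be non-negative")
  if (any(a + b <= 0) || any(c + d <= 0)) abort("both row margins must be > 0")
  # upper tail of Hypergeometric(m = a+b, n = c+d, k = a+c) at a
  phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Call variant-density hotspots from two call sets
#'
#' Bins the genome, counts cohort and reference variants per bin, computes
#' the density fold ratio and a one-sided Fisher exact p-value per bin, and
#' flags hotspots where `fold >= fold_min` and `p <= p_max` (both
#' boundaries inclusive). A Benjamini-Hochberg FDR column is reported for
#' reference but never gates hotspot status.
#'
#' @param cohort,reference [callset()]s or variant tibbles.
#' @param chrom_sizes Chrom/size table (used when `bins` is `NULL`).
#' @param bins Optional precomputed [make_bins()] output.
#' @param width Bin width in bp when building bins.
#' @param fold_min Minimum density fold ratio (default 1.5).
#' @param p_max Maximum Fisher p-value (default 0.05).
#' @return A tibble of class `varscape_hotspots`: one row per bin with
#'   counts `n_cohort`/`n_reference`, `fold`, `p`, `fdr`, `is_hotspot`.
#' @export
call_hotspots <- function(cohort, reference, chrom_sizes = NULL, bins = NULL,
                          width = 1e6, fold_min = 1.5, p_max = 0.05) {
  if (is.null(bins)) {
    if (is.null(chrom_sizes)) abort("supply either bins or chrom_sizes")
    bins <- make_bins(chrom_sizes, width = width)
  }
  ca <- count_per_bin(cohort, bins)
  cb <- count_per_bin(reference, bins)
  total_a <- sum(ca$n)
  total_b <- sum(cb$n)
  if (total_a == 0 || total_b == 0) {
    abort("both populations need at least one binned variant")
  }
  out <- bins %>%
    mutate(n_cohort = ca$n, n_reference = cb$n,
           fold = fold_ratio(.data$n_cohort, total_a,
                             .data$n_reference, total_b),
           p = fisher_exact_greater(.data$n_cohort, total_a - .data$n_cohort,
                                    .data$n_reference,
                                    total_b - .data$n_reference),
           fdr = p.adjust(.data$p, method = "BH"),
           # cross-multiplied so the inclusive fold boundary is exact in
           # integer arithmetic (a/ta >= f*b/tb without division rounding)
           is_hotspot = .data$n_cohort * as.numeric(total_b) >=
             fold_min * .data$n_reference * as.numeric(total_a) &
             .data$p <= p_max)
  attr(out, "totals") <- c(cohort = total_a, reference = total_b)
  attr(out, "thresholds") <- c(fold_min = fold_min, p_max = p_max)
  class(out) <- c("varscape_hotspots", class(out))
  out
}

#' Associate genes with hotspot bins
#'
#' A gene is associated with a hotspot when its interval lies within the
#' hotspot expanded by `flank` bp on both sides (clipped at chromosome
#' bounds). The boundary is inclusive: a gene ending exactly `flank` bp
#' upstream of the hotspot start still counts.
#'
#' @param hotspots Output of [call_hotspots()] (all bins are carried through;
#'   genes are looked up for hotspot bins only).
#' @param genes Gene models: tibble with `chrom`, `start`, `end` (0-based
#'   half-open) and `name`.
#' @param flank Flank in bp added on each side (default 5 kb).
#' @param chrom_sizes Optional chrom/size table for clipping the expansion.
#' @return `hotspots` with a `genes` list-column of associated gene names
#'   (character(0) for non-hotspot bins).
#' @export
associate_genes <- function(hotspots, genes, flank = 5000,
                            chrom_sizes = NULL) {
  genes <- as_tibble(genes)
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(genes)))
  cz <- if (!is.null(chrom_sizes)) as_chrom_sizes(chrom_sizes) else NULL
  gene_list <- purrr::map(seq_len(nrow(hotspots)), function(i) {
    if (!hotspots$is_hotspot[i]) return(character(0))
    lo <- max(0, hotspots$start[i] - flank)
    hi <- hotspots$end[i] + flank
    if (!is.null(cz)) {
      sz <- cz$size[match(hotspots$chrom[i], cz$chrom)]
      if (!is.na(sz)) hi <- min(hi, sz)
    }
    hit <- genes$chrom == hotspots$chrom[i] &
      genes$end >= lo & genes$start <= hi
    unique(genes$name[hit])
  })
  hotspots$genes <- gene_list
  hotspots
}

#' Write hotspot calls as BED5+
#'
#' Columns: chrom, start, end, name, -log10(p), fold, hotspot flag and
#' (when present) the comma-separated associated genes.
#'
#' @param hotspots Output of [call_hotspots()] / [associate_genes()].
#' @param path Output path.
#' @param hotspots_only Write only flagged bins (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_hotspot_bed <- function(hotspots, path, hotspots_only = TRUE) {
  h <- as_tibble(hotspots)
  if (hotspots_only) h <- h[h$is_hotspot, , drop = FALSE]
  df <- tibble(
    chrom = h$chrom,
    start = format(h$start, scientific = FALSE, trim = TRUE),
    end = format(h$end, scientific = FALSE, trim = TRUE),
    name = sprintf("%s_bin%d", h$chrom, h$bin),
    neg_log10_p = round(-log10(pmax(h$p, .Machine$double.xmin)), 4),
    fold = round(h$fold, 4),
    is_hotspot = as.integer(h$is_hotspot)
  )
  if ("genes" %in% names(h)) {
    df$genes <- vapply(h$genes, function(g)
      if (length(g) == 0) "." else paste(g, collapse = ","), "")
  }
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
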