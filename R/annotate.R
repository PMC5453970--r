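#' Known-variant catalog
#'
#' A catalog stands in for a dbSNP-like archive of sequence-resolved variants
#' plus a DGV-like archive of structural variants. SNP/indel membership is by
#' exact (chrom, pos, ref, alt) key; SV membership is by reciprocal overlap of
#' same-type intervals (see [sv_novelty()]).
#'
#' @param snv Data frame with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param sv Optional data frame of typed SV intervals with `chrom`, `start`,
#'   `end` (0-based half-open) and `type` (`DEL`, `DUP`, `INV`).
#' @return An object of class `catalog`.
#' @export
catalog <- function(snv = NULL, sv = NULL) {
  if (is.null(snv)) {
    snv <- tibble(chrom = character(), pos = integer(),
                  ref = character(), alt = character())
  }
  snv <- as_tibble(snv)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(snv)))
  if (!is.null(sv)) {
    sv <- as_tibble(sv)
    stopifnot(all(c("chrom", "start", "end", "type") %in% names(sv)))
    if (any(sv$end <= sv$start)) abort("catalog SV intervals need end > start")
  }
  structure(list(keys = unique(variant_key(snv)), sv = sv), class = "catalog")
}

#' @export
print.catalog <- function(x, ...) {
  cat(sprintf("<catalog> %d SNV/indel keys, %d SV intervals\n",
              length(x$keys), if (is.null(x$sv)) 0L else nrow(x$sv)))
  invisible(x)
}

#' Read a known-variant catalog from VCF or 4-column TSV
#'
#' @param path A VCF file or a headerless TSV with columns chrom, pos
#'   (1-based), ref, alt.
#' @param sv_path Optional SV catalog: BED3 plus a 4th type column
#'   (`DEL`/`DUP`/`INV`).
#' @return A [catalog()].
#' @export
read_catalog <- function(path, sv_path = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readLines(path, n = 1)
  if (grepl("^##fileformat=VCF", first)) {
    snv <- as_variants(read_vcf(path))[, c("chrom", "pos", "ref", "alt")]
  } else {
    snv <- readr::read_tsv(path, col_names = c("chrom", "pos", "ref", "alt"),
                           col_types = "cicc", comment = "#",
                           progress = FALSE)
    if (any(is.na(snv$pos))) {
      abort(sprintf("malformed catalog line %d: non-integer position",
                    which(is.na(snv$pos))[1]))
    }
  }
  sv <- NULL
  if (!is.null(sv_path)) {
    b <- read_bed(sv_path)
    if (!"name" %in% names(b)) abort("SV catalog needs a 4th (type) column")
    sv <- dplyr::rename(b, type = "name")
  }
  catalog(snv, sv)
}

#' Flag variants as novel relative to a catalog
#'
#' Sequence-resolved variants are known iff their exact (chrom, pos, ref,
#' alt) key is in the catalog; SVs are known iff a same-type catalog SV
#' reciprocally overlaps them by at least `min_reciprocal`. Everything else
#' is novel. The result does not depend on record order.
#'
#' @param x A [callset()] or variant tibble.
#' @param cat A [catalog()].
#' @param min_reciprocal Reciprocal-overlap threshold for SV matching.
#' @return Same kind as `x`, with a logical `novel` column added.
#' @export
mark_novelty <- function(x, cat, min_reciprocal = 0.5) {
  stopifnot(inherits(cat, "catalog"))
  v <- ensure_key(as_variants(x))
  novel <- !(v$variant_id %in% cat$keys)
  cls <- if ("var_class" %in% names(v)) v$var_class else
    classify_variant(v$ref, v$alt)
  is_sv <- grepl("^SV_", cls)
  if (any(is_sv)) {
    novel[is_sv] <- sv_novelty(v[is_sv, , drop = FALSE], cat,
                               min_reciprocal = min_reciprocal)
  }
  v$novel <- novel
  replace_variants(x, v)
}

replace_variants <- function(x, v) {
  if (inherits(x, "callset")) {
    x$variants <- v
    x
  } else {
    v
  }
}

#' SV novelty by reciprocal overlap
#'
#' An SV is known iff the catalog holds an SV of the same type whose overlap
#' covers at least `min_reciprocal` of *both* intervals' lengths.
#'
#' @param sv SV records: a variant tibble (rows with `SV_*` classes, using
#'   `pos`..`sv_end` 1-based inclusive) or an interval tibble with `chrom`,
#'   `start`, `end` (0-based half-open) and `type`.
#' @param cat A [catalog()] with an SV table.
#' @param min_reciprocal Fraction in (0, 1].
#' @return Logical vector: `TRUE` where novel.
#' @export
sv_novelty <- function(sv, cat, min_reciprocal = 0.5) {
  stopifnot(inherits(cat, "catalog"))
  sv <- as_tibble(sv)
  if (!"start" %in% names(sv)) {
    sv <- tibble(chrom = sv$chrom, start = sv$pos - 1, end = sv$sv_end,
                 type = sub("^SV_", "", sv$var_class))
  }
  if (nrow(sv) == 0) return(logical(0))
  if (is.null(cat$sv) || nrow(cat$sv) == 0) return(rep(TRUE, nrow(sv)))

  q <- GenomicRanges::GRanges(sv$chrom,
                              IRanges::IRanges(sv$start + 1, sv$end))
  s <- GenomicRanges::GRanges(cat$sv$chrom,
                              IRanges::IRanges(cat$sv$start + 1, cat$sv$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(q)[qi],
                                           IRanges::ranges(s)[si]))
  same_type <- sv$type[qi] == cat$sv$type[si]
  recip <- ov / IRanges::width(q)[qi] >= min_reciprocal &
    ov / IRanges::width(s)[si] >= min_reciprocal
  known_idx <- unique(qi[same_type & recip])
  !(seq_len(nrow(sv)) %in% known_idx)
}

#' Novelty rate as a percentage
#'
#' @param n_novel Count of novel variants.
#' @param n_total Total variant count (> 0).
#' @return `100 * n_novel / n_total`.
#' @export
#' @examples
#' novelty_rate(1902, 7063)  # 26.9 (to 1 d.p.)
novelty_rate <- function(n_novel, n_total) {
  if (any(n_total <= 0)) abort("novelty_rate undefined for n_total = 0")
  if (any(n_novel > n_total) || any(n_novel < 0)) {
    abort("need 0 <= n_novel <= n_total")
  }
  100 * n_novel / n_total
}

#' Alternative allele frequency and frequency class
#'
#' AAF is the count of alternate alleles over non-missing diploid calls
#' divided by twice the number of non-missing calls. A variant is `COMMON`
#' iff its AAF strictly exceeds `common_min` (default 5%), else `LOW`.
#'
#' @param cs A [callset()] with genotypes.
#' @param common_min Common/low AAF boundary (fraction).
#' @return The call set with `aaf`, `freq_class` and `n_samples_present`
#'   columns added to its variant table.
#' @export
compute_aaf <- function(cs, common_min = 0.05) {
  stopifnot(inherits(cs, "callset"))
  if (is.null(cs$genotypes)) abort("compute_aaf needs per-sample genotypes")
  g <- cs$genotypes
  called <- !is.na(g$gt)
  nalt <- ifelse(called, n_alt_alleles(g$gt), NA_integer_)
  per <- tibble(variant_id = g$variant_id, called = called, nalt = nalt) %>%
    group_by(.data$variant_id) %>%
    summarise(n_called = sum(.data$called),
              alt_alleles = sum(.data$nalt, na.rm = TRUE),
              n_present = sum(!is.na(.data$nalt) & .data$nalt > 0),
              .groups = "drop") %>%
    mutate(aaf = ifelse(.data$n_called > 0,
                        .data$alt_alleles / (2 * .data$n_called), NA_real_))
  v <- cs$variants %>%
    left_join(per[, c("variant_id", "aaf", "n_present")], by = "variant_id") %>%
    rename(n_samples_present = "n_present") %>%
    mutate(freq_class = if_else(.data$aaf > common_min, "COMMON", "LOW"))
  cs$variants <- v
  cs
}

#' Flag a structural variant as cohort-common
#'
#' An SV is common when carried by at least `ceiling(fraction * n_samples)`
#' samples; with the default third, 16 of 48 samples is the inclusive
#' boundary.
#'
#' @param n_present Number of carrier samples.
#' @param n_samples Cohort size.
#' @param fraction Required carrier fraction (default 1/3).
#' @return Logical vector.
#' @export
#' @examples
#' flag_common_sv(16, 48)  # TRUE
#' flag_common_sv(15, 48)  # FALSE
flag_common_sv <- function(n_present, n_samples, fraction = 1 / 3) {
  stopifnot(all(n_present >= 0), all(n_present <= n_samples))
  n_present >= ceiling(fraction * n_samples)
}

#' Annotate a call set: novelty, AAF class, common-SV flag
#'
#' Convenience wrapper chaining [mark_novelty()], [compute_aaf()] (when
#' genotypes are available) and [flag_common_sv()] on SV records.
#'
#' @inheritParams mark_novelty
#' @inheritParams compute_aaf
#' @inheritParams flag_common_sv
#' @return The annotated [callset()].
#' @export
annotate_callset <- function(x, cat, min_reciprocal = 0.5, common_min = 0.05,
                             fraction = 1 / 3) {
  cs <- mark_novelty(x, cat, min_reciprocal = min_reciprocal)
  if (inherits(cs, "callset") && !is.null(cs$genotypes)) {
    cs <- compute_aaf(cs, common_min = common_min)
    v <- cs$variants
    is_sv <- grepl("^SV_", v$var_class)
    v$common_sv <- NA
    if (any(is_sv)) {
      v$common_sv[is_sv] <- flag_common_sv(v$n_samples_present[is_sv],
                                           cs$n_samples, fraction = fraction)
    }
    cs$variants <- v
  }
  cs
}
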