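#' Read a multi-sample VCF into a call set
#'
#' Parses site fields (CHROM/POS/REF/ALT/QUAL) and the per-sample FORMAT
#' fields GT, DP, GQ and AD. Positions stay 1-based. Symbolic SV ALT alleles
#' (`<DEL>`, `<DUP>`, `<INV>`) are classified from `INFO/SVTYPE` with
#' `INFO/END` as the 1-based inclusive end. Multi-allelic records are
#' rejected (split required).
#'
#' @param path Path to a VCF v4.x file (plain or bgzipped).
#' @param label Provenance label; defaults to the file name.
#' @return A [callset()].
#' @export
read_vcf <- function(path, label = basename(path)) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  x <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(x@fix, stringsAsFactors = FALSE)
  samples <- colnames(x@gt)
  samples <- samples[samples != "FORMAT"]

  if (nrow(fix) == 0) {
    v <- tibble(chrom = character(), pos = integer(), ref = character(),
                alt = character(), qual = double(),
                var_class = character(), sv_end = integer())
    return(callset(v, NULL, label = label,
                   n_samples = max(length(samples), 0L)))
  }
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    bad <- which(grepl(",", fix$ALT, fixed = TRUE))[1]
    abort(sprintf("multi-allelic record at data line %d: split required", bad))
  }

  info <- fix$INFO %||% rep(NA_character_, nrow(fix))
  sv_type <- info_field(info, "SVTYPE")
  sv_end <- suppressWarnings(as.integer(info_field(info, "END")))

  v <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    var_class = classify_variant(fix$REF, fix$ALT, sv_type = sv_type),
    sv_end = sv_end
  )
  v$variant_id <- variant_key(v)

  gt_tbl <- NULL
  if (length(samples) > 0) {
    gt <- vcfR::extract.gt(x, "GT")
    dp <- suppressWarnings(vcfR::extract.gt(x, "DP", as.numeric = TRUE))
    gq <- suppressWarnings(vcfR::extract.gt(x, "GQ", as.numeric = TRUE))
    ad <- vcfR::extract.gt(x, "AD")
    split_ad <- function(i) {
      p <- strsplit(ad[, i], ",", fixed = TRUE)
      list(ref = suppressWarnings(as.integer(vapply(p, `[`, "", 1))),
           alt = suppressWarnings(as.integer(vapply(p, function(q)
             if (length(q) >= 2) q[2] else NA_character_, ""))))
    }
    gt_tbl <- purrr::map_dfr(seq_along(samples), function(i) {
      adi <- if (is.null(ad)) list(ref = NA_integer_, alt = NA_integer_)
             else split_ad(i)
      tibble(variant_id = v$variant_id, sample = samples[i],
             gt = unname(gt[, i]),
             dp = as.integer(unname(dp[, i])),
             gq = as.integer(unname(gq[, i])),
             ad_ref = adi$ref, ad_alt = adi$alt)
    })
    gt_tbl$gt[grepl("\\.", gt_tbl$gt)] <- NA_character_
  }

  callset(v, gt_tbl, label = label, n_samples = length(samples))
}

info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

#' Write a call set as a plain-text VCF v4.2 file
#'
#' Emits site fields and GT:DP:GQ:AD per sample; SV records carry
#' `SVTYPE`/`END` in INFO. Fields the pipeline does not use are not invented,
#' so `read_vcf(write_vcf(cs))` round-trips the fields the pipeline touches.
#'
#' @param cs A [callset()].
#' @param path Output path.
#' @param chrom_sizes Optional chrom/size table for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cs, path, chrom_sizes = NULL) {
  stopifnot(inherits(cs, "callset"))
  v <- cs$variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=varscape (%s)", cs$label),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end (1-based)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">"
  )
  if (!is.null(chrom_sizes)) {
    cz <- as_chrom_sizes(chrom_sizes)
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", cz$chrom,
                          as.integer(cz$size)))
  }
  is_sv <- grepl("^SV_", v$var_class)
  info <- rep(".", nrow(v))
  info[is_sv] <- sprintf("SVTYPE=%s;END=%d", sub("^SV_", "", v$var_class[is_sv]),
                         v$sv_end[is_sv])
  alt <- v$alt
  alt[is_sv & !grepl("^<", alt)] <-
    sprintf("<%s>", sub("^SV_", "", v$var_class[is_sv & !grepl("^<", v$alt)]))

  if (is.null(cs$genotypes)) {
    cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
    body <- paste(v$chrom, v$pos, ".", v$ref, alt, format_qual(v$qual),
                  "PASS", info, sep = "\t")
  } else {
    g <- cs$genotypes
    samples <- sort(unique(g$sample))
    gstr <- sprintf("%s:%s:%s:%s,%s",
                    ifelse(is.na(g$gt), "./.", g$gt),
                    ifelse(is.na(g$dp), ".", g$dp),
                    ifelse(is.na(g$gq), ".", g$gq),
                    ifelse(is.na(g$ad_ref), ".", g$ad_ref),
                    ifelse(is.na(g$ad_alt), ".", g$ad_alt))
    m <- matrix(NA_character_, nrow = nrow(v), ncol = length(samples),
                dimnames = list(NULL, samples))
    m[cbind(match(g$variant_id, v$variant_id), match(g$sample, samples))] <- gstr
    m[is.na(m)] <- "./.:.:.:.,."
    cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", samples)
    body <- paste(v$chrom, v$pos, ".", v$ref, alt, format_qual(v$qual),
                  "PASS", info, "GT:DP:GQ:AD",
                  apply(m, 1, paste, collapse = "\t"), sep = "\t")
    if (nrow(v) == 0) body <- character()
  }
  writeLines(c(hdr, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

format_qual <- function(q) {
  out <- ifelse(is.na(q), ".",
                ifelse(q == round(q), sprintf("%d", as.integer(round(q))),
                       sprintf("%.6g", q)))
  out
}

#' Read a BED file of genomic features
#'
#' BED is 0-based half-open: a line `chr1 0 1000000` covers 1-based positions
#' 1..1,000,000. Columns beyond the third are taken as `name` and `score`.
#'
#' @param path Path to a BED3/BED4/BED5 file.
#' @param genome Optional chrom/size table; intervals on chromosomes absent
#'   from it are dropped with a warning.
#' @return A tibble with `chrom`, `start`, `end` and, when present, `name`
#'   and `score`.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    abort(sprintf("malformed BED line %d: fewer than 3 fields",
                  which(nf < 3)[1]))
  }
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  bad <- is.na(start) | is.na(end) | start < 0 | end <= start
  if (any(bad)) {
    abort(sprintf("malformed BED line %d: bad interval coordinates",
                  which(bad)[1]))
  }
  out <- tibble(chrom = vapply(parts, `[`, "", 1), start = start, end = end)
  if (max(nf) >= 4) {
    out$name <- vapply(parts, function(p)
      if (length(p) >= 4) p[4] else NA_character_, "")
  }
  if (max(nf) >= 5) {
    out$score <- suppressWarnings(as.numeric(vapply(parts, function(p)
      if (length(p) >= 5) p[5] else NA_character_, "")))
  }
  if (!is.null(genome)) {
    cz <- as_chrom_sizes(genome)
    unknown <- !out$chrom %in% cz$chrom
    if (any(unknown)) {
      warn(sprintf("dropping %d BED interval(s) on chromosome(s) absent from genome table: %s",
                   sum(unknown),
                   paste(unique(out$chrom[unknown]), collapse = ", ")))
      out <- out[!unknown, , drop = FALSE]
    }
  }
  out
}

#' Write genomic features as BED
#'
#' @param features Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score` (written in canonical BED column order).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(features, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"),
                    names(features))
  # BED is rectangular: can't have score without name
  if ("score" %in% cols && !"name" %in% cols) {
    features$name <- "."
    cols <- c("chrom", "start", "end", "name", "score")
  }
  df <- features[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a two-column chromosome-size table
#'
#' @param path TSV with chromosome name and length (bp).
#' @return Tibble with `chrom` and `size`.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_tsv(path, col_names = c("chrom", "size"),
                        col_types = "cd", progress = FALSE)
  if (any(is.na(df$size) | df$size <= 0)) {
    abort(sprintf("malformed chrom-size line %d: non-positive or missing size",
                  which(is.na(df$size) | df$size <= 0)[1]))
  }
  df
}

as_chrom_sizes <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "size") %in% names(x)))
    return(as_tibble(x[, c("chrom", "size")]))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    return(tibble(chrom = names(x), size = unname(x)))
  }
  abort("chrom_sizes must be a chrom/size data frame or a named numeric vector")
}
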