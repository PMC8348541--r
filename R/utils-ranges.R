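# Internal bridges between tidy interval tables and IRanges/GenomicRanges.
#
# All user-facing coordinates are 0-based, half-open (BED convention).
# GRanges is 1-based, closed, so conversion is start + 1 on the way in and
# start - 1 on the way out.

interval_cols <- c("chrom", "start", "end")

abort_usage <- function(msg) rlang::abort(msg, class = "cregnet_usage_error")
abort_parse <- function(msg) rlang::abort(msg, class = "cregnet_parse_error")

validate_intervals <- function(x, arg = "x") {
  if (!is.data.frame(x)) {
    abort_usage(sprintf("`%s` must be a data frame of intervals", arg))
  }
  missing <- setdiff(interval_cols, names(x))
  if (length(missing) > 0) {
    abort_usage(sprintf("`%s` lacks column(s): %s", arg,
                        paste(missing, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom)))) {
    abort_usage(sprintf("`%s` has empty chromosome names", arg))
  }
  if (any(x$start < 0)) {
    abort_usage(sprintf("`%s` has negative start coordinates", arg))
  }
  if (any(x$end <= x$start)) {
    bad <- which(x$end <= x$start)[1]
    abort_usage(sprintf("`%s` row %d has end <= start (half-open intervals must be non-empty)",
                        arg, bad))
  }
  invisible(x)
}

sort_intervals <- function(x) {
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

# 0-based half-open tibble -> GRanges (1-based closed)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges   = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

granges_to_tbl <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr)
  )
}

# Number of blacklist intervals each query overlaps by >= minoverlap bp.
count_overlaps_tbl <- function(query, subject, minoverlap = 1L) {
  if (nrow(query) == 0) return(integer(0))
  if (nrow(subject) == 0) return(integer(nrow(query)))
  # disjoint chromosome sets between query and subject are routine here
  suppressWarnings(
    GenomicRanges::countOverlaps(as_granges(query), as_granges(subject),
                                 minoverlap = as.integer(minoverlap)))
}

# Logical: does each query interval overlap any subject interval (>= 1 bp)?
overlaps_any <- function(query, subject, minoverlap = 1L) {
  count_overlaps_tbl(query, subject, minoverlap) > 0L
}

# Overlap pairs with overlap widths, as a tibble of (query, subject, overlap_bp).
overlap_pairs_tbl <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble::tibble(query = integer(0), subject = integer(0),
                          overlap_bp = integer(0)))
  }
  qg <- as_granges(query)
  sg <- as_granges(subject)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(qg, sg))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(query$end[qi], subject$end[si]) -
    pmax(query$start[qi], subject$start[si])
  tibble::tibble(query = qi, subject = si, overlap_bp = as.integer(ov))
}
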