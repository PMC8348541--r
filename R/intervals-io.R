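#' Read genomic intervals or interaction loops from standard formats
#'
#' Reads BED (3+ columns), ENCODE broadPeak and BEDPE files into tidy
#' tibbles. All coordinates are 0-based, half-open. Records are returned
#' sorted by `(chrom, start, end)` (BED/broadPeak) or
#' `(chrom1, start1, end1, start2)` (BEDPE).
#'
#' Column mapping follows the conventions of each format:
#' * `bed`: columns 4 and 5, when present, become `name` and `score`;
#'   an absent score defaults to 0.
#' * `broadpeak`: column 7 (`signalValue`) becomes `score`; column 4
#'   becomes `name`.
#' * `bedpe`: column 7 becomes the interaction `count`, defaulting to 1.
#'
#' @param path Path to a tab-separated file.
#' @param format One of `"bed"`, `"broadpeak"`, `"bedpe"`.
#' @param chrom_prefix Chromosome-name normalization applied at read time:
#'   `"asis"` (default, exact string comparison downstream), `"add"`
#'   (prepend `"chr"` where missing), or `"strip"` (remove a leading
#'   `"chr"`).
#' @return A tibble. For `bed`/`broadpeak`: columns `chrom`, `start`,
#'   `end`, `name`, `score`. For `bedpe`: `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`, `count`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200", "chr1\t50\t80"), f)
#' read_intervals(f, "bed")
#' @export
read_intervals <- function(path, format = c("bed", "broadpeak", "bedpe"),
                           chrom_prefix = c("asis", "add", "strip")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort_usage(
                       sprintf("unknown format token '%s'", format[1])))
  chrom_prefix <- match.arg(chrom_prefix)
  if (!file.exists(path)) abort_usage(sprintf("file not found: %s", path))

  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) {
    return(if (format == "bedpe") empty_loops() else empty_peaks())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  min_cols <- if (format == "bedpe") 6L else 3L
  nf <- lengths(fields)
  if (any(nf < min_cols)) {
    abort_parse(sprintf("line %d: expected >= %d tab-separated columns, got %d",
                        which(nf < min_cols)[1], min_cols, nf[which(nf < min_cols)[1]]))
  }

  get_col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, character(1))
  as_coord <- function(v, col) {
    n <- suppressWarnings(as.numeric(v))
    bad <- is.na(n) | n != floor(n)
    if (any(bad)) {
      abort_parse(sprintf("line %d: non-integer coordinate '%s' in column %d",
                          which(bad)[1], v[which(bad)[1]], col))
    }
    n
  }
  fix_chrom <- function(ch) {
    switch(chrom_prefix,
           asis  = ch,
           add   = ifelse(startsWith(ch, "chr"), ch, paste0("chr", ch)),
           strip = sub("^chr", "", ch))
  }

  if (format == "bedpe") {
    out <- tibble::tibble(
      chrom1 = fix_chrom(get_col(1)), start1 = as_coord(get_col(2), 2),
      end1 = as_coord(get_col(3), 3),
      chrom2 = fix_chrom(get_col(4)), start2 = as_coord(get_col(5), 5),
      end2 = as_coord(get_col(6), 6)
    )
    cnt <- suppressWarnings(as.numeric(get_col(7)))
    out$count <- ifelse(is.na(cnt), 1, cnt)
    bad <- which(out$end1 <= out$start1 | out$end2 <= out$start2)
    if (length(bad) > 0) {
      abort_parse(sprintf("line %d: anchor end <= start", bad[1]))
    }
    return(dplyr::arrange(out, .data$chrom1, .data$start1, .data$end1, .data$start2))
  }

  out <- tibble::tibble(
    chrom = fix_chrom(get_col(1)),
    start = as_coord(get_col(2), 2),
    end   = as_coord(get_col(3), 3)
  )
  bad <- which(out$end <= out$start)
  if (length(bad) > 0) abort_parse(sprintf("line %d: end <= start", bad[1]))
  out$name <- if (max(nf) >= 4) get_col(4) else "."
  out$name[is.na(out$name)] <- "."
  score_col <- if (format == "broadpeak") 7L else 5L
  if (max(nf) >= score_col) {
    sc <- suppressWarnings(as.numeric(get_col(score_col)))
    out$score <- ifelse(is.na(sc), 0, sc)
  } else {
    out$score <- 0
  }
  if (any(out$score < 0)) {
    out$score[out$score < 0] <- 0
  }
  sort_intervals(out)
}

empty_peaks <- function() {
  tibble::tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                 name = character(0), score = numeric(0))
}

empty_loops <- function() {
  tibble::tibble(chrom1 = character(0), start1 = numeric(0), end1 = numeric(0),
                 chrom2 = character(0), start2 = numeric(0), end2 = numeric(0),
                 count = numeric(0))
}

#' Write intervals or loops to standard tab-separated formats
#'
#' Emits tab-separated, newline-terminated records with base-10 integer
#' coordinates and Unix newlines, so that `write` then `read` round-trips
#' exactly.
#'
#' @param x A tibble of intervals (`chrom`, `start`, `end`, optionally
#'   `name` and `score`) or loops (`chrom1` ... `count`).
#' @param path Output file path.
#' @param format One of `"bed"`, `"broadpeak"`, `"bedpe"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, format = c("bed", "broadpeak", "bedpe")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort_usage(
                       sprintf("unknown format token '%s'", format[1])))
  fmt_int <- function(v) format(v, scientific = FALSE, trim = TRUE)
  col_or <- function(nm, default) {
    if (nm %in% names(x)) x[[nm]] else rep(default, nrow(x))
  }
  if (format == "bedpe") {
    lines <- paste(x$chrom1, fmt_int(x$start1), fmt_int(x$end1),
                   x$chrom2, fmt_int(x$start2), fmt_int(x$end2),
                   fmt_num(col_or("count", 1)), sep = "\t")
  } else if (format == "broadpeak") {
    lines <- paste(x$chrom, fmt_int(x$start), fmt_int(x$end),
                   col_or("name", "."), "0", ".",
                   fmt_num(col_or("score", 0)), "-1", "-1", sep = "\t")
  } else {
    cols <- list(x$chrom, fmt_int(x$start), fmt_int(x$end))
    if ("name" %in% names(x)) {
      cols <- c(cols, list(x$name))
      if ("score" %in% names(x)) cols <- c(cols, list(fmt_num(x$score)))
    }
    lines <- do.call(paste, c(cols, sep = "\t"))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

fmt_num <- function(v) {
  ifelse(v == floor(v), format(v, scientific = FALSE, trim = TRUE),
         format(v, scientific = FALSE, trim = TRUE, digits = 15))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge overlapping or nearby intervals
#'
#' Produces the union of the input intervals, additionally joining
#' intervals separated by at most `gap` bp. With `gap = 0`, abutting
#' half-open intervals (`end == next start`) merge. Input need not be
#' sorted; output is sorted and pairwise non-overlapping. Extra columns
#' are dropped.
#'
#' @param x Interval tibble (`chrom`, `start`, `end`).
#' @param gap Maximum separation (bp, >= 0) between two intervals for them
#'   to be joined.
#' @return Tibble with columns `chrom`, `start`, `end`.
#' @examples
#' merge_intervals(tibble::tibble(chrom = "chr1",
#'                                start = c(100, 150), end = c(200, 250)))
#' @export
merge_intervals <- function(x, gap = 0) {
  validate_intervals(x)
  if (length(gap) != 1 || is.na(gap) || gap < 0) {
    abort_usage("`gap` must be a single nonnegative number of bp")
  }
  if (nrow(x) == 0) return(tibble::as_tibble(x[interval_cols]))
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = gap + 1)
  sort_intervals(granges_to_tbl(gr))
}

#' Remove query intervals overlapping a blacklist
#'
#' Returns exactly the query intervals whose overlap with every blacklist
#' interval is below `min_overlap_bp`; surviving intervals are returned
#' whole (never truncated). Half-open abutment (shared boundary, zero
#' shared bp) is not overlap.
#'
#' @param query Interval tibble; extra columns are preserved.
#' @param blacklist Interval tibble.
#' @param min_overlap_bp Minimum shared bp (>= 1) for a blacklist hit to
#'   disqualify a query interval.
#' @return The surviving rows of `query`.
#' @export
subtract_overlapping <- function(query, blacklist, min_overlap_bp = 1) {
  validate_intervals(query, "query")
  validate_intervals(blacklist, "blacklist")
  if (length(min_overlap_bp) != 1 || is.na(min_overlap_bp) || min_overlap_bp < 1) {
    abort_usage("`min_overlap_bp` must be a single number >= 1")
  }
  if (nrow(query) == 0 || nrow(blacklist) == 0) return(tibble::as_tibble(query))
  hit <- count_overlaps_tbl(query, blacklist, minoverlap = min_overlap_bp) > 0
  tibble::as_tibble(query[!hit, , drop = FALSE])
}
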