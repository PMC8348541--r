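loop_anchor <- function(loops, which = 1) {
  tibble::tibble(chrom = loops[[paste0("chrom", which)]],
                 start = loops[[paste0("start", which)]],
                 end   = loops[[paste0("end", which)]])
}

validate_loops <- function(loops, arg = "loops") {
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  missing <- setdiff(need, names(loops))
  if (length(missing) > 0) {
    abort_usage(sprintf("`%s` lacks column(s): %s", arg,
                        paste(missing, collapse = ", ")))
  }
  invisible(loops)
}

#' Loop span: midpoint-to-midpoint anchor distance
#'
#' The length of a chromatin interaction loop, defined as the distance
#' between the midpoints of its two anchors (rounded down to integer bp).
#' This definition is symmetric in the anchors and insensitive to anchor
#' width. Inter-chromosomal loops have undefined span (`NA`).
#'
#' @param loops Loop tibble (`chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`).
#' @return Numeric vector of spans in bp, `NA` for trans loops.
#' @examples
#' loop_span(tibble::tibble(chrom1 = "chr1", start1 = 0, end1 = 10000,
#'                          chrom2 = "chr1", start2 = 90000, end2 = 1e5))
#' @export
loop_span <- function(loops) {
  validate_loops(loops)
  m1 <- floor((loops$start1 + loops$end1) / 2)
  m2 <- floor((loops$start2 + loops$end2) / 2)
  ifelse(loops$chrom1 == loops$chrom2, abs(m2 - m1), NA_real_)
}

#' Annotate loops by enhancer anchor overlap
#'
#' Labels each loop by whether its anchors touch a tissue-specific
#' enhancer: `specific_enhancer` if either anchor overlaps (>= 1 bp) any
#' interval of `specific`; otherwise `nonspecific_enhancer` if either
#' anchor overlaps `nonspecific`; otherwise `other`. Inter-chromosomal
#' loops are retained (with `span = NA`, excluded from span statistics)
#' and noted via a message.
#'
#' @param loops Loop tibble; a `count` column defaults to 1.
#' @param specific Non-overlapping interval tibble of specific enhancers.
#' @param nonspecific Non-overlapping interval tibble of non-specific
#'   enhancers.
#' @return `loops` with added columns `class_label` (factor with levels
#'   `specific_enhancer`, `nonspecific_enhancer`, `other`) and `span`.
#' @export
annotate_loops <- function(loops, specific, nonspecific) {
  validate_loops(loops)
  validate_intervals(specific, "specific")
  validate_intervals(nonspecific, "nonspecific")
  loops <- tibble::as_tibble(loops)
  if (!"count" %in% names(loops)) loops$count <- 1
  if (any(loops$count < 1)) abort_usage("loop counts must be >= 1")

  a1 <- loop_anchor(loops, 1)
  a2 <- loop_anchor(loops, 2)
  hit_spec <- overlaps_any(a1, specific) | overlaps_any(a2, specific)
  hit_nons <- overlaps_any(a1, nonspecific) | overlaps_any(a2, nonspecific)
  lab <- ifelse(hit_spec, "specific_enhancer",
                ifelse(hit_nons, "nonspecific_enhancer", "other"))
  loops$class_label <- factor(lab, levels = c("specific_enhancer",
                                              "nonspecific_enhancer", "other"))
  loops$span <- loop_span(loops)
  n_trans <- sum(is.na(loops$span))
  if (n_trans > 0) {
    rlang::inform(sprintf("%d inter-chromosomal loop(s): span undefined, excluded from span statistics",
                          n_trans))
  }
  loops
}

default_span_bins <- function(max_span) {
  top <- max(max_span, 100000) * 1.0001
  edges <- c(0, 20000, 100000)
  if (top > 100000) {
    k <- ceiling(log2(top / 100000))
    edges <- c(edges, 100000 * 2^seq_len(k))
  }
  edges
}

#' Binned span distribution of a set of loops
#'
#' @param spans Numeric vector of loop spans (bp); `NA` values dropped.
#' @param bin_edges Increasing bin edges in bp (left-closed bins);
#'   defaults to edges at 20 kb and 100 kb with log2-spaced bins above.
#' @return Tibble with `bin_lo`, `bin_hi`, `n`, `proportion`
#'   (proportions sum to 1).
#' @export
span_distribution <- function(spans, bin_edges = NULL) {
  spans <- spans[!is.na(spans)]
  if (length(spans) == 0) abort_usage("no finite spans to bin")
  if (is.null(bin_edges)) bin_edges <- default_span_bins(max(spans))
  bin <- cut(spans, breaks = bin_edges, right = FALSE, include.lowest = TRUE)
  tab <- table(bin)
  tibble::tibble(
    bin_lo = bin_edges[-length(bin_edges)],
    bin_hi = bin_edges[-1],
    n = as.integer(tab),
    proportion = as.integer(tab) / length(spans)
  )
}

#' Compare loop-span distributions across enhancer classes
#'
#' Compares the span distributions of annotated loop classes against each
#' other and against a seeded uniform random subsample of all loops (the
#' "random loop" reference). Reports per-class binned proportions and a
#' two-sample test (Kolmogorov-Smirnov by default, Mann-Whitney as an
#' option) for every class pair. Inter-chromosomal loops are excluded.
#'
#' @param loops Annotated loop tibble from [annotate_loops()].
#' @param n_random Size of the random reference subsample (capped at the
#'   number of loops, with a warning, if larger).
#' @param seed Integer seed making the random reference reproducible.
#' @param bin_edges Optional bin edges (see [span_distribution()]).
#' @param test `"ks"` or `"wilcox"`.
#' @return An object of class `span_comparison`: a list with
#'   `proportions` (class, bin, proportion), `tests` (pairwise statistic
#'   and p-value) and `spans` (per-class span lists).
#' @export
compare_span_distributions <- function(loops, n_random = 1000, seed = 1,
                                       bin_edges = NULL,
                                       test = c("ks", "wilcox")) {
  test <- match.arg(test)
  stopifnot("class_label" %in% names(loops))
  if (!"span" %in% names(loops)) loops$span <- loop_span(loops)
  cis <- loops[!is.na(loops$span), , drop = FALSE]
  if (nrow(cis) == 0) abort_usage("no intra-chromosomal loops")
  if (n_random > nrow(cis)) {
    rlang::warn(sprintf("n_random (%d) exceeds loop count (%d); capped",
                        n_random, nrow(cis)))
    n_random <- nrow(cis)
  }
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  ref_idx <- sample.int(nrow(cis), n_random, replace = FALSE)

  spans_by_class <- split(cis$span, cis$class_label)
  spans_by_class <- spans_by_class[vapply(spans_by_class, length, 1L) > 0]
  spans_by_class$random <- cis$span[ref_idx]

  if (is.null(bin_edges)) bin_edges <- default_span_bins(max(cis$span))
  proportions <- purrr::imap(spans_by_class, function(sp, cl) {
    dplyr::mutate(span_distribution(sp, bin_edges), class = cl, .before = 1)
  }) |> dplyr::bind_rows()

  classes <- names(spans_by_class)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  tests <- purrr::map(pairs, function(p) {
    a <- spans_by_class[[p[1]]]
    b <- spans_by_class[[p[2]]]
    ht <- if (test == "ks") {
      suppressWarnings(stats::ks.test(a, b))
    } else {
      suppressWarnings(stats::wilcox.test(a, b))
    }
    tibble::tibble(class_a = p[1], class_b = p[2],
                   statistic = unname(ht$statistic), p_value = ht$p.value,
                   method = test, n_a = length(a), n_b = length(b))
  }) |> dplyr::bind_rows()

  structure(list(proportions = proportions, tests = tests,
                 spans = spans_by_class, bin_edges = bin_edges,
                 seed = seed, n_random = n_random),
            class = "span_comparison")
}

#' @export
print.span_comparison <- function(x, ...) {
  cat(sprintf("Loop span comparison (%s test, random reference n = %d, seed %d)\n",
              x$tests$method[1], x$n_random, x$seed))
  print(x$tests)
  invisible(x)
}

#' Write annotated loops as BEDPE
#'
#' Standard 7-column BEDPE plus the class label as an 8th column.
#'
#' @param loops Annotated loop tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotated_bedpe <- function(loops, path) {
  fmt_int <- function(v) format(v, scientific = FALSE, trim = TRUE)
  lines <- paste(loops$chrom1, fmt_int(loops$start1), fmt_int(loops$end1),
                 loops$chrom2, fmt_int(loops$start2), fmt_int(loops$end2),
                 fmt_num(loops$count), as.character(loops$class_label),
                 sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}
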