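#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a super-enhancer ranking
#'
#' @param x A `super_enhancers` object.
#' @param ... Unused.
#' @return A plain tibble of stitched regions with rank, signal and the
#'   super-enhancer flag.
#' @export
tidy.super_enhancers <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a super-enhancer ranking
#'
#' @param x A `super_enhancers` object.
#' @param ... Unused.
#' @export
glance.super_enhancers <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x),
    n_super = sum(x$is_super),
    cutoff_index = attr(x, "cutoff_index"),
    stitch_gap = attr(x, "stitch_gap"),
    total_signal = sum(x$score)
  )
}

#' Tidy a loop-span comparison: the pairwise test table
#'
#' @param x A `span_comparison` object.
#' @param ... Unused.
#' @export
tidy.span_comparison <- function(x, ...) x$tests

#' One-row summary of a loop-span comparison
#'
#' @param x A `span_comparison` object.
#' @param ... Unused.
#' @export
glance.span_comparison <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$spans),
    n_loops = sum(lengths(x$spans)) - x$n_random,
    n_random = x$n_random,
    min_p_value = min(x$tests$p_value),
    method = x$tests$method[1]
  )
}

#' Tidy a TAD change classification (list columns dropped)
#'
#' @param x A `tad_changes` object.
#' @param ... Unused.
#' @export
tidy.tad_changes <- function(x, ...) {
  out <- tibble::as_tibble(x)[, c("change_id", "chrom", "start", "end",
                                  "category", "n_normal", "n_cancer")]
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a TAD change classification
#'
#' @param x A `tad_changes` object.
#' @param ... Unused.
#' @export
glance.tad_changes <- function(x, ...) {
  ct <- as.character(x$category)
  tibble::tibble(
    n_components = nrow(x),
    n_changed = sum(ct %in% changed_categories),
    n_unchanged = sum(ct == "unchanged"),
    n_complex = sum(ct == "complex"),
    boundary_tol = attr(x, "boundary_tol"),
    min_overlap_frac = attr(x, "min_overlap_frac")
  )
}
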