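#' Drop peaks near transcription start sites
#'
#' Removes every peak that overlaps any window `[tss - window,
#' tss + window)` around an annotated TSS. Surviving peaks are returned
#' whole. H3K27ac signal at promoters marks active transcription rather
#' than distal enhancer activity, so enhancer calling excludes it.
#'
#' @param peaks Interval tibble; extra columns preserved.
#' @param tss TSS annotation tibble with columns `gene_id`, `chrom`,
#'   `tss` (0-based bp) and optionally `strand`.
#' @param window Half-width of the exclusion window in bp (default 2500,
#'   i.e. +/- 2.5 kb).
#' @return The surviving rows of `peaks`.
#' @export
exclude_tss_proximal <- function(peaks, tss, window = 2500) {
  validate_intervals(peaks, "peaks")
  if (length(window) != 1 || is.na(window) || window < 0) {
    abort_usage("`window` must be a single nonnegative number of bp")
  }
  if (is.null(tss) || nrow(tss) == 0) {
    rlang::warn("empty TSS annotation: no peaks excluded")
    return(tibble::as_tibble(peaks))
  }
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(tss)))
  win <- tibble::tibble(chrom = tss$chrom,
                        start = pmax(0, tss$tss - window),
                        end   = tss$tss + window)
  win <- win[win$end > win$start, , drop = FALSE]
  subtract_overlapping(peaks, win)
}

#' Call tissue-specific enhancers from multi-sample peak data
#'
#' Implements the set-operation definition of a tissue-specific enhancer:
#' a non-promoter peak region reproducibly present in every target-class
#' sample and overlapping no peak in any background-class sample.
#' The pipeline is: (1) per target sample, drop TSS-proximal peaks;
#' (2) keep a peak only if an overlapping peak exists in at least
#' `min_target_samples` target samples (all of them by default);
#' (3) merge surviving peaks across target samples (`gap = 0`);
#' (4) remove any merged region with >= 1 bp overlap with any background
#' sample's peak.
#'
#' @param peaks Long tibble of peaks from all samples: columns `chrom`,
#'   `start`, `end`, `score`, `sample_id`.
#' @param targets Character vector of target-class sample ids.
#' @param backgrounds Character vector of background-class sample ids.
#' @param tss TSS annotation (see [exclude_tss_proximal()]).
#' @param tss_window TSS exclusion half-width in bp.
#' @param min_target_samples Number of target samples a region must be
#'   supported by. `NULL` (default) requires unanimity.
#' @param tissue_label Label stored on the result.
#' @return A tibble of enhancer regions (`chrom`, `start`, `end`,
#'   `score`), where `score` is the mean across target samples of the
#'   summed overlapping peak signal. Attributes `tissue_label` and
#'   `provenance` (sample counts) record how the set was derived. An
#'   empty result is valid (returned with a message, not an error).
#' @export
call_specific_enhancers <- function(peaks, targets, backgrounds, tss,
                                    tss_window = 2500,
                                    min_target_samples = NULL,
                                    tissue_label = "target") {
  validate_intervals(peaks, "peaks")
  stopifnot("sample_id" %in% names(peaks))
  targets <- unique(targets)
  backgrounds <- unique(backgrounds)
  if (length(targets) < 1) abort_usage("need at least one target sample")
  if (length(backgrounds) < 1) abort_usage("need at least one background sample")
  if (length(intersect(targets, backgrounds)) > 0) {
    abort_usage("a sample cannot be both target and background")
  }
  if (is.null(min_target_samples)) min_target_samples <- length(targets)
  if (min_target_samples < 1 || min_target_samples > length(targets)) {
    abort_usage("`min_target_samples` must be in [1, number of targets]")
  }
  if (!"score" %in% names(peaks)) peaks$score <- 0

  # (1) per-sample TSS filtering of target peaks
  by_sample <- lapply(targets, function(s) {
    exclude_tss_proximal(peaks[peaks$sample_id == s, , drop = FALSE], tss,
                         window = tss_window)
  })
  names(by_sample) <- targets

  # (2) reproducibility across target samples
  kept <- lapply(targets, function(s) {
    p <- by_sample[[s]]
    if (nrow(p) == 0) return(p)
    support <- rep(1L, nrow(p))  # own sample
    for (o in setdiff(targets, s)) {
      support <- support + as.integer(overlaps_any(p, by_sample[[o]]))
    }
    p[support >= min_target_samples, , drop = FALSE]
  })

  # (3) merge survivors across samples
  pooled <- dplyr::bind_rows(kept)
  merged <- if (nrow(pooled) > 0) merge_intervals(pooled, gap = 0) else
    tibble::tibble(chrom = character(0), start = numeric(0), end = numeric(0))

  # (4) subtract regions overlapping any background peak
  bg <- peaks[peaks$sample_id %in% backgrounds, , drop = FALSE]
  specific <- subtract_overlapping(merged, bg[interval_cols])

  # score: mean over target samples of summed overlapping (TSS-filtered) signal
  if (nrow(specific) > 0) {
    sig <- matrix(0, nrow = nrow(specific), ncol = length(targets))
    for (j in seq_along(targets)) {
      p <- by_sample[[targets[j]]]
      pairs <- overlap_pairs_tbl(specific, p)
      if (nrow(pairs) > 0) {
        acc <- tapply(p$score[pairs$subject], pairs$query, sum)
        sig[as.integer(names(acc)), j] <- acc
      }
    }
    specific$score <- rowMeans(sig)
  } else {
    specific$score <- numeric(0)
    rlang::inform("no specific enhancers survive the filters (valid empty set)")
  }

  out <- sort_intervals(specific)
  attr(out, "tissue_label") <- tissue_label
  attr(out, "provenance") <- list(n_target_samples = length(targets),
                                  n_background_samples = length(backgrounds),
                                  min_target_samples = min_target_samples,
                                  tss_window = tss_window)
  out
}

#' Stitch enhancers and call super enhancers by the rank-curve inflection
#'
#' The ROSE-style procedure: (1) merge enhancers lying within
#' `stitch_gap` bp of one another, summing their signal; (2) rank stitched
#' regions by ascending total signal (score ties broken by chromosome and
#' start so the cutoff is deterministic); (3) rescale rank and signal each
#' to `[0, 1]`; (4) the cutoff is the first rank position where the
#' discrete slope of the scaled curve exceeds 1. Regions ranked above the
#' cutoff are super enhancers. The flag vector is invariant under any
#' positive rescaling of the raw scores.
#'
#' @param enhancers Tibble with `chrom`, `start`, `end`, `score`
#'   (nonnegative signal).
#' @param stitch_gap Stitching distance in bp (default 12500, the
#'   canonical 12.5 kb).
#' @return An object of class `super_enhancers`: a tibble of stitched
#'   regions (`chrom`, `start`, `end`, `score`, `n_members`, `rank`,
#'   `scaled_rank`, `scaled_score`, `is_super`) ordered by rank, with
#'   attribute `cutoff_index`. If all scores are identical the curve has
#'   no inflection and zero regions are flagged.
#' @export
stitch_and_rank_super_enhancers <- function(enhancers, stitch_gap = 12500) {
  validate_intervals(enhancers, "enhancers")
  stopifnot("score" %in% names(enhancers))
  if (any(enhancers$score < 0)) abort_usage("enhancer scores must be >= 0")
  if (nrow(enhancers) == 0) abort_usage("need at least one enhancer")

  stitched <- merge_intervals(enhancers[interval_cols], gap = stitch_gap)
  pairs <- overlap_pairs_tbl(stitched, enhancers)
  score <- rep(0, nrow(stitched))
  nmem <- rep(0L, nrow(stitched))
  acc <- tapply(enhancers$score[pairs$subject], pairs$query, sum)
  score[as.integer(names(acc))] <- acc
  cnt <- table(pairs$query)
  nmem[as.integer(names(cnt))] <- as.integer(cnt)
  stitched$score <- score
  stitched$n_members <- nmem

  ord <- order(stitched$score, stitched$chrom, stitched$start)
  res <- stitched[ord, , drop = FALSE]
  n <- nrow(res)
  res$rank <- seq_len(n)
  rng <- max(res$score) - min(res$score)
  if (n < 2 || rng == 0) {
    if (rng == 0) rlang::inform("degenerate signal curve (all scores equal): no super enhancers")
    res$scaled_rank <- if (n < 2) 0 else (res$rank - 1) / (n - 1)
    res$scaled_score <- 0
    res$is_super <- FALSE
    cutoff <- n
  } else {
    res$scaled_rank <- (res$rank - 1) / (n - 1)
    res$scaled_score <- (res$score - min(res$score)) / rng
    slope <- diff(res$scaled_score) / diff(res$scaled_rank)
    over <- which(slope > 1)
    cutoff <- if (length(over) == 0) n else over[1]
    res$is_super <- res$rank > cutoff
  }
  out <- tibble::as_tibble(res)
  attr(out, "cutoff_index") <- cutoff
  attr(out, "stitch_gap") <- stitch_gap
  class(out) <- c("super_enhancers", class(out))
  out
}

#' @export
print.super_enhancers <- function(x, ...) {
  cat(sprintf("Super-enhancer ranking: %d stitched regions, %d super (cutoff index %d)\n",
              nrow(x), sum(x$is_super), attr(x, "cutoff_index")))
  NextMethod()
}
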