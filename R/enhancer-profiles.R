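#' Build a normalized signal density matrix over enhancer loci
#'
#' For each (locus, sample) cell, sums the scores of the sample's peaks
#' overlapping the locus, weighting each peak by the fraction of the peak
#' (in bp) that lies inside the locus. Each sample column is then scaled
#' to unit total so samples of different sequencing depth are comparable;
#' a per-million scale factor can be applied instead via `scale_factor`.
#'
#' @param peaks Long peak tibble with `chrom`, `start`, `end`, `score`,
#'   `sample_id`.
#' @param loci Non-overlapping interval tibble (the enhancer loci, matrix
#'   rows).
#' @param scale_factor Multiplier applied after unit-total scaling
#'   (default 1; use `1e6` for a counts-per-million-style scale).
#' @return A tibble with one row per locus: `chrom`, `start`, `end`,
#'   `locus` (a `"chrom:start-end"` key) and one numeric column per
#'   sample. Cells with no overlapping peak are 0. Samples with zero
#'   total signal yield all-zero columns with a warning.
#' @export
build_density_matrix <- function(peaks, loci, scale_factor = 1) {
  validate_intervals(peaks, "peaks")
  validate_intervals(loci, "loci")
  stopifnot(all(c("sample_id", "score") %in% names(peaks)))
  loci <- sort_intervals(tibble::as_tibble(loci[interval_cols]))
  if (nrow(loci) > 1) {
    same <- loci$chrom[-1] == loci$chrom[-nrow(loci)]
    if (any(same & loci$start[-1] < loci$end[-nrow(loci)])) {
      abort_usage("`loci` must be non-overlapping")
    }
  }
  samples <- unique(peaks$sample_id)

  pairs <- overlap_pairs_tbl(loci, peaks)
  contrib <- if (nrow(pairs) > 0) {
    tibble::tibble(
      row = pairs$query,
      sample_id = peaks$sample_id[pairs$subject],
      value = peaks$score[pairs$subject] * pairs$overlap_bp /
        (peaks$end[pairs$subject] - peaks$start[pairs$subject])
    ) |>
      dplyr::group_by(.data$row, .data$sample_id) |>
      dplyr::summarise(value = sum(.data$value), .groups = "drop")
  } else {
    tibble::tibble(row = integer(0), sample_id = character(0), value = numeric(0))
  }

  mat <- matrix(0, nrow = nrow(loci), ncol = length(samples),
                dimnames = list(NULL, samples))
  if (nrow(contrib) > 0) {
    mat[cbind(contrib$row, match(contrib$sample_id, samples))] <- contrib$value
  }
  tot <- colSums(mat)
  zero <- tot == 0
  if (any(zero)) {
    rlang::warn(sprintf("sample(s) with zero total signal over loci: %s",
                        paste(samples[zero], collapse = ", ")))
    tot[zero] <- 1
  }
  mat <- sweep(mat, 2, tot, "/") * scale_factor

  out <- dplyr::bind_cols(
    loci,
    tibble::tibble(locus = sprintf("%s:%s-%s", loci$chrom,
                                   format(loci$start, scientific = FALSE, trim = TRUE),
                                   format(loci$end, scientific = FALSE, trim = TRUE))),
    tibble::as_tibble(mat)
  )
  attr(out, "samples") <- samples
  out
}

density_sample_cols <- function(dmat) {
  attr(dmat, "samples") %||% setdiff(names(dmat), c(interval_cols, "locus"))
}

density_as_matrix <- function(dmat) {
  s <- density_sample_cols(dmat)
  m <- as.matrix(dmat[, s, drop = FALSE])
  rownames(m) <- dmat$locus
  m
}

#' Select variant enhancer loci by median absolute deviation
#'
#' Variant enhancer loci (VELs) are the enhancers with the greatest
#' median absolute deviation of normalized signal across samples — the
#' loci that discriminate tissues. Ties in MAD are broken by
#' `(chrom, start)`; selected rows keep their input order.
#'
#' @param dmat Density matrix from [build_density_matrix()].
#' @param n Number of loci to retain (1 <= n <= number of rows).
#' @return The selected rows of `dmat` (same column structure).
#' @export
select_variant_enhancer_loci <- function(dmat, n) {
  if (length(n) != 1 || is.na(n) || n < 1 || n > nrow(dmat)) {
    abort_usage(sprintf("`n` must be in [1, %d]", nrow(dmat)))
  }
  m <- density_as_matrix(dmat)
  mads <- apply(m, 1, stats::mad)
  ord <- order(-mads, dmat$chrom, dmat$start)
  keep <- sort(ord[seq_len(n)])
  out <- dmat[keep, , drop = FALSE]
  attr(out, "samples") <- density_sample_cols(dmat)
  out
}

#' Correlation distance matrix between samples
#'
#' Computes `1 - cor(sample_i, sample_j)` over the locus profiles, with
#' Pearson correlation (for hierarchical clustering) or Spearman rank
#' correlation with mid-rank ties (for embedding input). Values lie in
#' `[0, 2]`; the diagonal is exactly 0 and the matrix symmetric. A
#' zero-variance sample has undefined correlations; its off-diagonal
#' distances are set to 1 with a warning.
#'
#' @param dmat Density matrix from [build_density_matrix()].
#' @param method `"pearson"` or `"spearman"`.
#' @return A symmetric numeric matrix with sample ids as dimnames.
#' @export
correlation_distance_matrix <- function(dmat, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- density_as_matrix(dmat)
  if (ncol(m) < 2) abort_usage("need at least 2 samples")
  if (nrow(m) < 2) abort_usage("need at least 2 loci")
  sds <- apply(m, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(m, method = method))
  d <- 1 - cc
  if (any(sds == 0)) {
    rlang::warn(sprintf("zero-variance sample(s): %s (distances set to 1)",
                        paste(colnames(m)[sds == 0], collapse = ", ")))
    bad <- which(sds == 0)
    d[bad, ] <- 1
    d[, bad] <- 1
  }
  diag(d) <- 0
  d <- (d + t(d)) / 2
  d
}

#' Hierarchical clustering of samples from a distance matrix
#'
#' Average-linkage (UPGMA) clustering by default, matching common
#' practice for correlation distances over enhancer profiles.
#'
#' @param dist_matrix Symmetric distance matrix (e.g. from
#'   [correlation_distance_matrix()]).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An `hclust` object.
#' @export
cluster_samples <- function(dist_matrix, linkage = "average") {
  stats::hclust(stats::as.dist(dist_matrix), method = linkage)
}

#' Export a sample dendrogram in Newick format
#'
#' @param hc An `hclust` object from [cluster_samples()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort_usage("package 'ape' is required for Newick export")
  }
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write a density matrix as TSV
#'
#' Loci rows by sample columns, with a header row of sample ids and a
#' `locus` key column (`"chrom:start-end"`).
#'
#' @param dmat Density matrix tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_density_matrix <- function(dmat, path) {
  readr::write_tsv(dmat[, c("locus", density_sample_cols(dmat))], path)
  invisible(path)
}
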