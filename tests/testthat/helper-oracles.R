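# Brute-force reference implementations used as independent oracles.
# These deliberately avoid the interval machinery of the package:
# all-pairs arithmetic only.

iv <- function(chrom, start, end, ...) {
  tibble::tibble(chrom = chrom, start = start, end = end, ...)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5,
                             max_len = 5000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE)
  )
}

# pairwise overlap in bp between one interval and many (half-open)
overlap_bp_vec <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# O(n^2) merge oracle: connected components of the "within gap" relation,
# merged to [min start, max end] per component.
oracle_merge <- function(x, gap = 0) {
  out <- list()
  for (ch in sort(unique(x$chrom))) {
    y <- x[x$chrom == ch, , drop = FALSE]
    n <- nrow(y)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        near <- which(y$start <= y$end[i] + gap & y$end >= y$start[i] - gap)
        target <- min(comp[near], comp[i])
        if (any(comp[near] != target) || comp[i] != target) {
          comp[near] <- target
          comp[i] <- target
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cp in unique(comp)) {
      m <- comp == cp
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ch, start = min(y$start[m]), end = max(y$end[m]))
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start, end)
}

# O(n*m) subtract oracle: keep query rows whose max overlap with any
# blacklist interval is < min_overlap_bp.
oracle_subtract <- function(query, blacklist, min_overlap_bp = 1) {
  keep <- vapply(seq_len(nrow(query)), function(i) {
    same <- blacklist$chrom == query$chrom[i]
    if (!any(same)) return(TRUE)
    ov <- overlap_bp_vec(query$start[i], query$end[i],
                         blacklist$start[same], blacklist$end[same])
    max(ov) < min_overlap_bp
  }, logical(1))
  query[keep, , drop = FALSE]
}

# brute-force TSS-window filter
oracle_tss_filter <- function(peaks, tss, window = 2500) {
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    same <- tss$chrom == peaks$chrom[i]
    if (!any(same)) return(TRUE)
    lo <- pmax(0, tss$tss[same] - window)
    hi <- tss$tss[same] + window
    !any(peaks$start[i] < hi & peaks$end[i] > lo)
  }, logical(1))
  peaks[keep, , drop = FALSE]
}

# brute-force specific-enhancer pipeline (unanimity), mirroring the
# documented set operations with all-pairs arithmetic
oracle_specific <- function(peaks, targets, backgrounds, tss, window = 2500) {
  filtered <- lapply(targets, function(s) {
    oracle_tss_filter(peaks[peaks$sample_id == s, , drop = FALSE], tss, window)
  })
  names(filtered) <- targets
  kept <- lapply(targets, function(s) {
    p <- filtered[[s]]
    ok <- vapply(seq_len(nrow(p)), function(i) {
      all(vapply(setdiff(targets, s), function(o) {
        q <- filtered[[o]]
        same <- q$chrom == p$chrom[i]
        any(overlap_bp_vec(p$start[i], p$end[i],
                           q$start[same], q$end[same]) > 0)
      }, logical(1)))
    }, logical(1))
    p[ok, , drop = FALSE]
  })
  merged <- oracle_merge(dplyr::bind_rows(kept)[, c("chrom", "start", "end")],
                         gap = 0)
  bg <- peaks[peaks$sample_id %in% backgrounds, , drop = FALSE]
  oracle_subtract(merged, bg)
}

# per-cell density accumulation oracle
oracle_density <- function(peaks, loci) {
  samples <- unique(peaks$sample_id)
  m <- matrix(0, nrow(loci), length(samples), dimnames = list(NULL, samples))
  for (i in seq_len(nrow(loci))) {
    for (j in seq_along(samples)) {
      p <- peaks[peaks$sample_id == samples[j] & peaks$chrom == loci$chrom[i], ]
      if (nrow(p) == 0) next
      ov <- overlap_bp_vec(loci$start[i], loci$end[i], p$start, p$end)
      m[i, j] <- sum(p$score * ov / (p$end - p$start))
    }
  }
  tot <- colSums(m)
  tot[tot == 0] <- 1
  sweep(m, 2, tot, "/")
}

# tiny TSS annotations used across tests
mk_tss <- function(chrom, tss, gene_id = NULL) {
  tibble::tibble(
    gene_id = gene_id %||% sprintf("g%d", seq_along(tss)),
    chrom = chrom, tss = tss, strand = "+"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

swap_map <- c(expand = "narrow", narrow = "expand", fusion = "split",
              split = "fusion", appear = "disappear", disappear = "appear",
              unchanged = "unchanged", complex = "complex")
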