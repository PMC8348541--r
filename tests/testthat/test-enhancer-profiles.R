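mk_sample_peaks <- function(sample_id, chrom, start, end, score) {
  tibble::tibble(sample_id = sample_id, chrom = chrom, start = start,
                 end = end, score = score)
}

test_that("density matrix: unit-total scaling and overlap-fraction weighting", {
  loci <- iv("chr1", c(1000, 5000), c(2000, 6000))
  # one peak exactly equal to a locus; the only peak in its sample
  p1 <- mk_sample_peaks("s1", "chr1", 1000, 2000, 4)
  # a peak of score 4 with half its bp inside the second locus
  p2 <- mk_sample_peaks("s2", "chr1", 5500, 6500, 4)
  d <- build_density_matrix(dplyr::bind_rows(p1, p2), loci)
  expect_equal(d$s1, c(1, 0))
  # pre-normalization contribution 2, then unit-total
  expect_equal(d$s2, c(0, 1))
  d_raw <- build_density_matrix(dplyr::bind_rows(p1, p2,
    mk_sample_peaks("s2", "chr1", 1000, 2000, 2)), loci)
  expect_equal(d_raw$s2, c(2, 2) / 4)
})

test_that("density matrix matches the per-cell accumulation oracle", {
  withr::local_seed(41)
  loci <- iv("chr1", seq(0, 19) * 5000, seq(0, 19) * 5000 + 3000)
  peaks <- dplyr::bind_rows(lapply(c("a", "b", "c"), function(s) {
    x <- random_intervals(80, chroms = "chr1", max_pos = 1e5, max_len = 4000)
    dplyr::mutate(x, sample_id = s, score = runif(80, 0, 10))
  }))
  d <- build_density_matrix(peaks, loci)
  expect_equal(unname(as.matrix(d[, c("a", "b", "c")])),
               unname(oracle_density(peaks, loci)), tolerance = 1e-12)
})

test_that("zero-signal samples give zero columns with a warning", {
  loci <- iv("chr1", 0, 1000)
  peaks <- dplyr::bind_rows(mk_sample_peaks("s1", "chr1", 0, 500, 3),
                            mk_sample_peaks("s2", "chr2", 0, 500, 3))
  expect_warning(d <- build_density_matrix(peaks, loci), "zero total")
  expect_equal(d$s2, 0)
  expect_error(build_density_matrix(peaks, iv("chr1", c(0, 500), c(1000, 1500))),
               "non-overlapping")
})

test_that("VEL selection keeps the rows with largest MAD", {
  loci <- iv("chr1", (0:3) * 1e4, (0:3) * 1e4 + 1000)
  d <- dplyr::bind_cols(loci, tibble::tibble(
    locus = sprintf("L%d", 1:4),
    a = c(1, 1, 5, 1), b = c(1, 1, 1, 1), c = c(1, 1, 9, 1)))
  attr(d, "samples") <- c("a", "b", "c")
  top1 <- select_variant_enhancer_loci(d, 1)
  expect_equal(top1$locus, "L3")
  expect_equal(select_variant_enhancer_loci(d, 4)$locus, d$locus)
  expect_error(select_variant_enhancer_loci(d, 5), class = "cregnet_usage_error")
})

test_that("VEL selection matches an exhaustive MAD sort and respects invariances", {
  withr::local_seed(43)
  n <- 400
  loci <- iv("chr1", (seq_len(n) - 1) * 1e4, (seq_len(n) - 1) * 1e4 + 1000)
  m <- matrix(rlnorm(n * 6), n, 6, dimnames = list(NULL, paste0("s", 1:6)))
  d <- dplyr::bind_cols(loci, tibble::tibble(locus = paste0("L", seq_len(n))),
                        tibble::as_tibble(m))
  attr(d, "samples") <- paste0("s", 1:6)
  sel <- select_variant_enhancer_loci(d, 100)
  mads <- apply(m, 1, mad)
  expected <- sort(order(-mads, loci$chrom, loci$start)[1:100])
  expect_equal(sel$locus, d$locus[expected])
  # adding a constant to a row leaves the selection unchanged
  d2 <- d
  d2[5, paste0("s", 1:6)] <- d2[5, paste0("s", 1:6)] + 100
  attr(d2, "samples") <- paste0("s", 1:6)
  expect_equal(select_variant_enhancer_loci(d2, 100)$locus, sel$locus)
  # scaling a row by c > 0 scales its MAD by c
  expect_equal(mad(3 * m[1, ]), 3 * mad(m[1, ]))
})

test_that("correlation distances: duplicates, anti-monotone columns, oracle", {
  loci <- iv("chr1", (0:9) * 1e4, (0:9) * 1e4 + 1000)
  x <- rlnorm(10)
  d <- dplyr::bind_cols(loci, tibble::tibble(locus = paste0("L", 1:10),
                                             a = x, b = x, c = rev(sort(x))))
  attr(d, "samples") <- c("a", "b", "c")
  dm <- correlation_distance_matrix(d, "pearson")
  expect_equal(dm["a", "b"], 0)
  expect_equal(diag(dm), rep(0, 3), ignore_attr = TRUE)
  expect_equal(dm, t(dm))
  # exactly anti-monotone columns: Spearman rho = -1, distance 2
  d2 <- dplyr::bind_cols(loci, tibble::tibble(locus = paste0("L", 1:10),
                                              a = sort(x), b = rev(sort(x))))
  attr(d2, "samples") <- c("a", "b")
  expect_equal(correlation_distance_matrix(d2, "spearman")["a", "b"], 2)

  # rank-then-correlate oracle with mid-rank ties
  withr::local_seed(47)
  m <- matrix(sample(1:5, 200, TRUE) + rlnorm(200), 50, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  loci50 <- iv("chr1", (0:49) * 1e4, (0:49) * 1e4 + 1000)
  d3 <- dplyr::bind_cols(loci50, tibble::tibble(locus = paste0("L", 1:50)),
                         tibble::as_tibble(m))
  attr(d3, "samples") <- paste0("s", 1:4)
  sp <- correlation_distance_matrix(d3, "spearman")
  ranks <- apply(m, 2, rank)  # mid-ranks for ties
  expect_equal(max(abs(sp - (1 - cor(ranks)))), 0, tolerance = 1e-12)
})

test_that("zero-variance samples get distance 1 with a warning", {
  loci <- iv("chr1", (0:4) * 1e4, (0:4) * 1e4 + 1000)
  d <- dplyr::bind_cols(loci, tibble::tibble(locus = paste0("L", 1:5),
                                             a = rlnorm(5), b = rep(2, 5)))
  attr(d, "samples") <- c("a", "b")
  expect_warning(dm <- correlation_distance_matrix(d, "pearson"), "zero-variance")
  expect_equal(dm["a", "b"], 1)
  expect_equal(diag(dm), rep(0, 2), ignore_attr = TRUE)
})

test_that("average-linkage clustering splits two planted sample blocks", {
  withr::local_seed(53)
  n_loci <- 60
  loci <- iv("chr1", (seq_len(n_loci) - 1) * 1e4,
             (seq_len(n_loci) - 1) * 1e4 + 1000)
  base_a <- rlnorm(n_loci); base_b <- rlnorm(n_loci)
  cols <- c(lapply(1:4, function(i) base_a * rlnorm(n_loci, 0, 0.05)),
            lapply(1:4, function(i) base_b * rlnorm(n_loci, 0, 0.05)))
  names(cols) <- c(paste0("blockA_", 1:4), paste0("blockB_", 1:4))
  d <- dplyr::bind_cols(loci, tibble::tibble(locus = paste0("L", seq_len(n_loci))),
                        tibble::as_tibble(cols))
  attr(d, "samples") <- names(cols)
  hc <- cluster_samples(correlation_distance_matrix(d, "pearson"))
  k2 <- stats::cutree(hc, k = 2)
  expect_equal(length(unique(k2[1:4])), 1)
  expect_equal(length(unique(k2[5:8])), 1)
  expect_true(k2[1] != k2[5])
})
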