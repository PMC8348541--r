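mk_loop <- function(chrom1, start1, end1, chrom2, start2, end2, count = 1) {
  tibble::tibble(chrom1 = chrom1, start1 = start1, end1 = end1,
                 chrom2 = chrom2, start2 = start2, end2 = end2, count = count)
}

test_that("loop span is the floor of the midpoint distance", {
  expect_equal(loop_span(mk_loop("chr1", 0, 10000, "chr1", 90000, 100000)),
               90000)
  expect_equal(loop_span(mk_loop("chr1", 100, 200, "chr1", 100, 200)), 0)
  expect_true(is.na(loop_span(mk_loop("chr1", 0, 100, "chr2", 0, 100))))
  # direct arithmetic on random loops
  withr::local_seed(61)
  l <- mk_loop("chr1", s1 <- sample.int(1e6, 100), s1 + 2000,
               "chr1", s2 <- sample.int(1e6, 100), s2 + 3000)
  expect_equal(loop_span(l),
               abs(floor((s2 + s2 + 3000) / 2) - floor((s1 + s1 + 2000) / 2)))
})

test_that("loop annotation applies the any-overlap anchor rule", {
  spec <- iv("chr1", 4000, 6000)
  nons <- iv("chr1", 50000, 52000)
  loops <- dplyr::bind_rows(
    mk_loop("chr1", 100, 5100, "chr1", 20000, 22000),   # anchor1 hits specific
    mk_loop("chr1", 30000, 32000, "chr1", 51000, 53000),# anchor2 hits nonspecific
    mk_loop("chr1", 70000, 72000, "chr1", 90000, 92000) # neither
  )
  ann <- annotate_loops(loops, spec, nons)
  expect_equal(as.character(ann$class_label),
               c("specific_enhancer", "nonspecific_enhancer", "other"))
})

test_that("annotation matches an all-pairs overlap oracle and is permutation-stable", {
  withr::local_seed(67)
  n <- 1000
  a1 <- random_intervals(n, max_pos = 5e5, max_len = 3000)
  shift <- sample.int(2e5, n)
  loops <- tibble::tibble(chrom1 = a1$chrom, start1 = a1$start, end1 = a1$end,
                          chrom2 = a1$chrom, start2 = a1$start + shift,
                          end2 = a1$end + shift, count = 1)
  spec <- random_intervals(40, max_pos = 7e5, max_len = 4000)
  spec <- merge_intervals(spec)
  nons <- random_intervals(40, max_pos = 7e5, max_len = 4000)
  nons <- merge_intervals(nons)
  ann <- annotate_loops(loops, spec, nons)

  hits_any <- function(ch, s, e, set) {
    vapply(seq_along(ch), function(i) {
      same <- set$chrom == ch[i]
      any(overlap_bp_vec(s[i], e[i], set$start[same], set$end[same]) > 0)
    }, logical(1))
  }
  hs <- hits_any(loops$chrom1, loops$start1, loops$end1, spec) |
    hits_any(loops$chrom2, loops$start2, loops$end2, spec)
  hn <- hits_any(loops$chrom1, loops$start1, loops$end1, nons) |
    hits_any(loops$chrom2, loops$start2, loops$end2, nons)
  expect_equal(as.character(ann$class_label),
               ifelse(hs, "specific_enhancer",
                      ifelse(hn, "nonspecific_enhancer", "other")))

  perm <- sample.int(n)
  ann_p <- annotate_loops(loops[perm, ], spec, nons)
  expect_equal(as.character(ann_p$class_label),
               as.character(ann$class_label)[perm])
})

test_that("inter-chromosomal loops are retained with undefined span", {
  loops <- dplyr::bind_rows(mk_loop("chr1", 0, 1000, "chr2", 0, 1000),
                            mk_loop("chr1", 0, 1000, "chr1", 30000, 31000))
  expect_message(ann <- annotate_loops(loops, iv("chr3", 0, 10),
                                       iv("chr3", 20, 30)),
                 "inter-chromosomal")
  expect_equal(sum(is.na(ann$span)), 1)
  expect_equal(nrow(ann), 2)
})

test_that("span comparison: identical classes give KS 0; shifts give KS near 1", {
  withr::local_seed(71)
  spans_a <- round(runif(500, 5000, 80000))
  mk_class_loops <- function(spans, label) {
    tibble::tibble(chrom1 = "chr1", start1 = 0, end1 = 1000,
                   chrom2 = "chr1", start2 = spans - 500, end2 = spans + 500,
                   count = 1, class_label = label, span = spans)
  }
  same <- dplyr::bind_rows(mk_class_loops(spans_a, "specific_enhancer"),
                           mk_class_loops(spans_a, "other"))
  cmp <- compare_span_distributions(same, n_random = 100, seed = 9)
  pair <- cmp$tests$class_a %in% c("specific_enhancer", "other") &
    cmp$tests$class_b %in% c("specific_enhancer", "other")
  ks_same <- cmp$tests[pair, ]
  expect_equal(ks_same$statistic, 0)

  shifted <- dplyr::bind_rows(mk_class_loops(spans_a, "specific_enhancer"),
                              mk_class_loops(spans_a + 2e5, "other"))
  cmp2 <- compare_span_distributions(shifted, n_random = 500, seed = 9)
  pair2 <- cmp2$tests$class_a %in% c("specific_enhancer", "other") &
    cmp2$tests$class_b %in% c("specific_enhancer", "other")
  ks_shift <- cmp2$tests[pair2, ]
  expect_gte(ks_shift$statistic, 0.9)
  expect_lt(ks_shift$p_value, 1e-6)

  # per-class proportions sum to 1
  sums <- tapply(cmp2$proportions$proportion, cmp2$proportions$class, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
})

test_that("random reference class is seeded and reproducible; capping warns", {
  withr::local_seed(73)
  spans <- round(runif(200, 5000, 3e5))
  loops <- tibble::tibble(chrom1 = "chr1", start1 = 0, end1 = 1000,
                          chrom2 = "chr1", start2 = spans, end2 = spans + 1000,
                          count = 1,
                          class_label = sample(c("specific_enhancer", "other"),
                                               200, TRUE))
  c1 <- compare_span_distributions(loops, n_random = 50, seed = 123)
  c2 <- compare_span_distributions(loops, n_random = 50, seed = 123)
  expect_identical(c1$spans$random, c2$spans$random)
  expect_warning(compare_span_distributions(loops, n_random = 10000, seed = 1),
                 "capped")
})

test_that("distance-decay generator places most spans below 100 kb", {
  cfg <- sim_config(seed = 77, n_target_samples = 2, n_background_samples = 2,
                    n_shared_enhancers = 40, n_specific_enhancers = 120,
                    n_background_enhancers = 20, n_decoy_tss_peaks = 5,
                    n_genes = 300, n_wired_pass = 100, n_decoy_low_count = 5,
                    n_decoy_low_fc = 5, n_decoy_unwired = 5,
                    n_bg_up = 5, n_bg_down = 5, n_noise_loops = 300,
                    n_expr_normal = 4, n_expr_cancer = 4)
  land <- generate_landscape(cfg)
  le <- generate_loops_and_expression(cfg, land)
  spans <- loop_span(le$loops)
  expect_lt(median(spans, na.rm = TRUE), 1e5)
  dist <- span_distribution(spans)
  below_100k <- sum(dist$proportion[dist$bin_hi <= 1e5])
  expect_gt(below_100k, 0.5)
})
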