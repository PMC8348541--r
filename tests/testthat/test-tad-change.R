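test_that("basic change patterns classify as documented", {
  # one boundary moved +200 kb: expand
  ch <- classify_tad_changes(iv("chr1", 0, 5e5), iv("chr1", 0, 7e5))
  expect_equal(as.character(ch$category), "expand")
  # two normal domains covered by one cancer domain: fusion
  ch2 <- classify_tad_changes(iv("chr1", c(0, 5e5), c(5e5, 9e5)),
                              iv("chr1", 0, 9e5))
  expect_equal(as.character(ch2$category), "fusion")
  # reciprocal: split
  ch3 <- classify_tad_changes(iv("chr1", 0, 9e5),
                              iv("chr1", c(0, 5e5), c(5e5, 9e5)))
  expect_equal(as.character(ch3$category), "split")
  # within tolerance: unchanged
  ch4 <- classify_tad_changes(iv("chr1", 0, 5e5), iv("chr1", 10000, 5.2e5))
  expect_equal(as.character(ch4$category), "unchanged")
  # appear / disappear
  ch5 <- classify_tad_changes(iv("chr1", 0, 5e5),
                              iv("chr1", c(0, 2e6), c(5e5, 2.5e6)))
  expect_setequal(as.character(ch5$category), c("unchanged", "appear"))
  ch6 <- classify_tad_changes(iv("chr1", c(0, 2e6), c(5e5, 2.5e6)),
                              iv("chr1", 0, 5e5))
  expect_setequal(as.character(ch6$category), c("unchanged", "disappear"))
  # many-to-many: complex
  ch7 <- classify_tad_changes(iv("chr1", c(0, 4e5), c(4e5, 9e5)),
                              iv("chr1", c(0, 3e5), c(3e5, 9e5)))
  expect_equal(as.character(ch7$category), "complex")
})

test_that("overlapping domains within one condition are rejected by name", {
  expect_error(
    classify_tad_changes(iv("chr1", c(0, 3e5), c(5e5, 9e5)), iv("chr1", 0, 5e5)),
    "overlapping", class = "cregnet_usage_error")
})

test_that("planted categories are recovered and every domain is partitioned", {
  cfg <- sim_config(seed = 83, n_chromosomes = 2, tads_per_category = 5,
                    n_unchanged_tads = 5)
  tp <- generate_tad_pair(cfg)
  ch <- classify_tad_changes(tp$normal, tp$cancer)
  got <- dplyr::arrange(tidy(ch), chrom, start)
  expect_equal(as.character(got$category), tp$truth$category)
  # partition: every input domain appears in exactly one component
  n_in_components <- sum(got$n_normal)
  c_in_components <- sum(got$n_cancer)
  expect_equal(n_in_components, nrow(tp$normal))
  expect_equal(c_in_components, nrow(tp$cancer))
})

test_that("condition swap mirrors the category labels on any input", {
  for (seed in c(5, 17)) {
    cfg <- sim_config(seed = seed, n_chromosomes = 2, tads_per_category = 4,
                      n_unchanged_tads = 3)
    tp <- generate_tad_pair(cfg)
    a <- classify_tad_changes(tp$normal, tp$cancer)
    b <- classify_tad_changes(tp$cancer, tp$normal)
    expect_equal(as.character(b$category),
                 unname(swap_map[as.character(a$category)]))
  }
})

test_that("raising the tolerance never decreases the unchanged count", {
  cfg <- sim_config(seed = 89, n_chromosomes = 2, tads_per_category = 4,
                    n_unchanged_tads = 4)
  tp <- generate_tad_pair(cfg)
  n_unch <- vapply(c(10000, 40000, 130000), function(tol) {
    sum(classify_tad_changes(tp$normal, tp$cancer,
                             boundary_tol = tol)$category == "unchanged")
  }, numeric(1))
  expect_true(all(diff(n_unch) >= 0))
})

test_that("summary fractions and enhancer-containing fractions are exact", {
  # two expands (one with an enhancer inside its cancer domain), two fusions
  normal <- iv("chr1", c(0, 2e6, 4e6, 6.0e6, 8e6, 10.0e6),
               c(5e5, 2.5e6, 4.5e6, 6.4e6, 8.4e6, 10.4e6))
  cancer <- iv("chr1", c(0, 2e6, 4e6, 8e6), c(7e5, 2.7e6, 6.5e6, 10.5e6))
  ch <- classify_tad_changes(normal, cancer)
  expect_equal(sort(as.character(ch$category)),
               c("expand", "expand", "fusion", "fusion"))
  enh <- iv("chr1", c(100000, 4100000), c(101500, 4101500))
  s <- summarize_tad_changes(ch, enh)
  expect_equal(s$fraction_of_changed[s$category == "expand"], 0.5)
  expect_equal(s$fraction_of_changed[s$category == "fusion"], 0.5)
  expect_equal(s$enhancer_fraction[s$category == "expand"], 0.5)
  expect_equal(s$enhancer_fraction[s$category == "fusion"], 0.5)
  expect_equal(attr(s, "n_changed"), 4)

  # brute-force recount on a random planted landscape
  cfg <- sim_config(seed = 97, n_chromosomes = 2, tads_per_category = 3,
                    n_unchanged_tads = 2)
  tp <- generate_tad_pair(cfg)
  ch2 <- classify_tad_changes(tp$normal, tp$cancer)
  enh2 <- random_intervals(300, chroms = c("chr1", "chr2"), max_pos = 5e7,
                           max_len = 2000)
  s2 <- summarize_tad_changes(ch2, enh2)
  cats <- as.character(ch2$category)
  changed <- cats %in% c("expand", "narrow", "fusion", "split", "appear",
                         "disappear")
  for (ct in c("expand", "narrow", "fusion", "split", "appear", "disappear")) {
    expect_equal(s2$n[s2$category == ct], sum(cats == ct))
    expect_equal(s2$fraction_of_changed[s2$category == ct],
                 sum(cats == ct) / sum(changed))
    # recount enhancer containment by all-pairs overlap on the footprint
    idx <- which(cats == ct)
    has <- vapply(idx, function(i) {
      foot <- if (ct == "disappear") ch2$normal_members[[i]] else
        ch2$cancer_members[[i]]
      any(vapply(seq_len(nrow(foot)), function(r) {
        same <- enh2$chrom == foot$chrom[r]
        any(overlap_bp_vec(foot$start[r], foot$end[r],
                           enh2$start[same], enh2$end[same]) > 0)
      }, logical(1)))
    }, logical(1))
    expect_equal(s2$enhancer_fraction[s2$category == ct], mean(has))
  }
  frac <- s2$fraction_of_changed[!is.na(s2$fraction_of_changed)]
  expect_equal(sum(frac), 1, tolerance = 1e-9)
})

test_that("zero changed domains yields undefined fractions, not zeros", {
  ch <- classify_tad_changes(iv("chr1", 0, 5e5), iv("chr1", 0, 5e5))
  expect_warning(s <- summarize_tad_changes(ch, iv("chr1", 0, 100)),
                 "no changed")
  expect_true(all(is.na(s$fraction_of_changed)))
})
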