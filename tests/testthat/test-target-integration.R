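mk_expr <- function(genes, normal_mat, cancer_mat) {
  nn <- ncol(normal_mat); nc <- ncol(cancer_mat)
  ids <- c(sprintf("N%02d", seq_len(nn)), sprintf("C%02d", seq_len(nc)))
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = genes),
                           tibble::as_tibble(`colnames<-`(
                             cbind(normal_mat, cancer_mat), ids)))
  groups <- tibble::tibble(sample_id = ids,
                           group = rep(c("normal", "cancer"), c(nn, nc)))
  list(expr = expr, groups = groups)
}

test_that("identical groups give fold change 1 and no significance", {
  withr::local_seed(101)
  m <- matrix(rlnorm(50 * 4, 2, 1), 50, 4)
  d <- mk_expr(sprintf("g%02d", 1:50), m, m)
  de <- differential_expression(d$expr, d$groups)
  expect_equal(de$fold_change, rep(1, 50))
  expect_equal(de$direction, rep("ns", 50))
  expect_false(any(de$significant))
})

test_that("all-zero genes get fold change 1 and p 1", {
  m0 <- matrix(0, 2, 3)
  m <- rbind(m0, matrix(rlnorm(2 * 3, 2, 0.2), 2, 3))
  d <- mk_expr(paste0("g", 1:4), m, m * c(1, 1, 4, 4))
  de <- differential_expression(d$expr, d$groups)
  expect_equal(de$fold_change[1:2], c(1, 1))
  expect_equal(de$p_value[1:2], c(1, 1))
})

test_that("a planted 4x shift at n=20 per group is detected at q < 0.01", {
  withr::local_seed(103)
  n_genes <- 200
  base <- rlnorm(n_genes, log(50), 0.5)
  s <- sqrt(log(1 + 0.3^2))  # CV 0.3
  noise <- function(k) matrix(rlnorm(n_genes * k, -s^2 / 2, s), n_genes)
  fc <- rep(1, n_genes); fc[1] <- 4
  d <- mk_expr(sprintf("g%03d", seq_len(n_genes)),
               base * noise(20), (base * fc) * noise(20))
  de <- differential_expression(d$expr, d$groups)
  expect_equal(de$direction[1], "up")
  expect_lt(de$q_value[1], 0.01)
  expect_gt(de$fold_change[1], 1.5)
})

test_that("the vectorized Welch test agrees with stats::t.test per gene", {
  withr::local_seed(107)
  m_n <- matrix(rlnorm(10 * 6, 2, 0.8), 10, 6)
  m_c <- matrix(rlnorm(10 * 8, 2.4, 0.8), 10, 8)
  d <- mk_expr(paste0("g", 1:10), m_n, m_c)
  de <- differential_expression(d$expr, d$groups)
  for (i in 1:10) {
    tt <- t.test(log2(m_c[i, ] + 1), log2(m_n[i, ] + 1))
    expect_equal(de$p_value[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("BH significance is invariant to the gene order", {
  withr::local_seed(109)
  n_genes <- 300
  base <- rlnorm(n_genes, log(30), 1)
  fc <- rep(1, n_genes); fc[sample.int(n_genes, 30)] <- runif(30, 2, 5)
  s <- 0.3
  d <- mk_expr(sprintf("g%03d", seq_len(n_genes)),
               base * matrix(rlnorm(n_genes * 10, 0, s), n_genes),
               (base * fc) * matrix(rlnorm(n_genes * 10, 0, s), n_genes))
  de <- differential_expression(d$expr, d$groups)
  perm <- sample.int(n_genes)
  de_p <- differential_expression(d$expr[perm, ], d$groups)
  expect_setequal(de$gene_id[de$significant], de_p$gene_id[de_p$significant])
})

# --- target-gene integration -----------------------------------------

fixture_targets <- function() {
  spec <- iv("chr1", 100000, 102000)
  tss <- mk_tss("chr1", c(150000, 250000, 350000),
                gene_id = c("ITGB4like", "GALK1like", "lowFC"))
  mk_gene_loop <- function(tss_pos, count) {
    tibble::tibble(chrom1 = "chr1", start1 = 100000, end1 = 102000,
                   chrom2 = "chr1", start2 = tss_pos - 1000,
                   end2 = tss_pos + 1000, count = count)
  }
  loops <- dplyr::bind_rows(mk_gene_loop(150000, 6),
                            mk_gene_loop(250000, 3),
                            mk_gene_loop(350000, 10))
  # constant within-group expression pins the fold changes exactly:
  # (mean_c + 1)/(mean_n + 1) with pseudocount 1
  fcs <- c(2.31, 1.97, 1.2)
  mean_n <- 10
  mean_c <- fcs * (mean_n + 1) - 1
  m_n <- matrix(mean_n, 3, 3)
  m_c <- matrix(rep(mean_c, 3), 3, 3)
  d <- mk_expr(tss$gene_id, m_n, m_c)
  de <- differential_expression(d$expr, d$groups)
  list(spec = spec, tss = tss, loops = loops, de = de)
}

test_that("count and expression filters jointly select target genes", {
  fx <- fixture_targets()
  expect_equal(fx$de$fold_change, c(2.31, 1.97, 1.2), tolerance = 1e-12)
  tg <- identify_target_genes(fx$loops, fx$spec, fx$tss, fx$de)
  # count 6, upregulated: reported
  expect_true("ITGB4like" %in% tg$gene_id)
  # upregulated but interaction count 3: excluded by the count filter
  expect_false("GALK1like" %in% tg$gene_id)
  # count 10 but fold change 1.2: excluded by the expression filter
  expect_false("lowFC" %in% tg$gene_id)
  expect_equal(tg$evidence_count, 6)
  # the pre-filter universe still carries all loop-supported genes
  uni <- attr(tg, "universe")
  expect_setequal(uni$gene_id, c("ITGB4like", "GALK1like", "lowFC"))
})

test_that("filter monotonicity: lower thresholds give supersets of targets", {
  fx <- fixture_targets()
  strict <- identify_target_genes(fx$loops, fx$spec, fx$tss, fx$de,
                                  integration_thresholds())
  loose_count <- identify_target_genes(fx$loops, fx$spec, fx$tss, fx$de,
                                       integration_thresholds(count_threshold = 2))
  loose_fc <- identify_target_genes(
    fx$loops, fx$spec, fx$tss, fx$de,
    integration_thresholds(fc_threshold = 1.1, count_threshold = 2))
  expect_true(all(strict$gene_id %in% loose_count$gene_id))
  expect_true(all(loose_count$gene_id %in% loose_fc$gene_id))
  expect_setequal(loose_fc$gene_id, c("ITGB4like", "GALK1like", "lowFC"))
})

test_that("genes missing from the DE table are skipped with a warning", {
  fx <- fixture_targets()
  expect_warning(
    tg <- identify_target_genes(fx$loops, fx$spec, fx$tss,
                                fx$de[fx$de$gene_id != "ITGB4like", ]),
    "absent")
  expect_false("ITGB4like" %in% tg$gene_id)
})

test_that("long-range fraction arithmetic and the 20 kb tie rule", {
  fx <- fixture_targets()
  tg <- identify_target_genes(fx$loops, fx$spec, fx$tss, fx$de,
                              integration_thresholds(fc_threshold = 1.1,
                                                     count_threshold = 1))
  # spans are TSS - enhancer midpoint: 49000, 149000, 249000 -> all >= 20 kb
  expect_equal(long_range_fraction(tg), 1)
  # manual span sets
  mk <- function(spans) {
    tibble::tibble(gene_id = "g", n_loops = length(spans),
                   evidence_count = 10, max_span = max(spans),
                   is_long_range = any(spans >= 20000),
                   fold_change = 2, q_value = 0,
                   supporting_loops = list(tibble::tibble(span = spans)))
  }
  expect_equal(long_range_fraction(mk(c(25000, 10000, 30000, 15000))), 0.5)
  expect_equal(long_range_fraction(mk(c(5000, 19999))), 0)
  expect_equal(long_range_fraction(mk(c(20000))), 1)  # tie counts as long-range
  expect_warning(f <- long_range_fraction(mk(1)[0, ]), "empty")
  expect_true(is.na(f))
})
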