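#' Threshold set for target-gene integration
#'
#' Bundles the filtering thresholds used across the differential
#' expression and target-gene stages: linear fold-change cutoff,
#' Benjamini-Hochberg q-value cutoff, minimum summed interaction count,
#' the long-range span threshold, and the promoter (TSS) window.
#'
#' @param fc_threshold Linear fold-change cutoff (default 1.5).
#' @param q_threshold BH q-value cutoff (default 0.01).
#' @param count_threshold Minimum summed interaction count over a gene's
#'   supporting loops (default 5).
#' @param long_range_bp Span at or above which an interaction is
#'   long-range (default 20000; a tie at exactly 20 kb counts).
#' @param tss_window Promoter half-width in bp (default 2500).
#' @return A named list of class `cregnet_thresholds`.
#' @export
integration_thresholds <- function(fc_threshold = 1.5, q_threshold = 0.01,
                                   count_threshold = 5, long_range_bp = 20000,
                                   tss_window = 2500) {
  th <- list(fc_threshold = fc_threshold, q_threshold = q_threshold,
             count_threshold = count_threshold, long_range_bp = long_range_bp,
             tss_window = tss_window)
  if (any(unlist(th) <= 0)) abort_usage("all thresholds must be positive")
  structure(th, class = "cregnet_thresholds")
}

#' Differential expression between two sample groups
#'
#' Per-gene two-sided Welch t-test on `log2(x + 1)` with
#' Benjamini-Hochberg adjustment across all genes. The reported fold
#' change is computed on the abundance scale with a pseudocount of 1:
#' `(mean_cancer + 1) / (mean_normal + 1)`. A gene is significantly up
#' when `fold_change > fc_threshold` and `q < q_threshold`; significantly
#' down for the reciprocal fold change.
#'
#' @param expr Expression tibble: `gene_id` plus one numeric column per
#'   sample (TPM-like, nonnegative).
#' @param groups Tibble with `sample_id` and `group` (values `"normal"`
#'   and `"cancer"`); at least two samples per group.
#' @param thresholds An [integration_thresholds()] object.
#' @return Tibble with `gene_id`, `mean_normal`, `mean_cancer`,
#'   `fold_change`, `log2_fc`, `p_value`, `q_value`, `direction`
#'   (`"up"`, `"down"`, `"ns"`) and `significant`. Genes that are
#'   all-zero in both groups get `fold_change = 1`, `p = 1`.
#' @export
differential_expression <- function(expr, groups,
                                    thresholds = integration_thresholds()) {
  stopifnot("gene_id" %in% names(expr),
            all(c("sample_id", "group") %in% names(groups)))
  bad_group <- setdiff(unique(groups$group), c("normal", "cancer"))
  if (length(bad_group) > 0) {
    abort_usage(sprintf("unknown group label(s): %s",
                        paste(bad_group, collapse = ", ")))
  }
  sn <- groups$sample_id[groups$group == "normal"]
  sc <- groups$sample_id[groups$group == "cancer"]
  if (length(sn) < 2 || length(sc) < 2) {
    abort_usage("need at least 2 samples per group")
  }
  missing <- setdiff(c(sn, sc), names(expr))
  if (length(missing) > 0) {
    abort_usage(sprintf("samples absent from expression table: %s",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  xn <- as.matrix(expr[, sn, drop = FALSE])
  xc <- as.matrix(expr[, sc, drop = FALSE])
  if (any(xn < 0) || any(xc < 0)) abort_usage("expression values must be >= 0")

  mean_n <- rowMeans(xn)
  mean_c <- rowMeans(xc)
  fc <- (mean_c + 1) / (mean_n + 1)

  ln <- log2(xn + 1)
  lc <- log2(xc + 1)
  n1 <- ncol(ln); n2 <- ncol(lc)
  m1 <- rowMeans(ln); m2 <- rowMeans(lc)
  v1 <- rowSums((ln - m1)^2) / (n1 - 1)
  v2 <- rowSums((lc - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate genes: zero variance in both groups
  degen <- se2 == 0
  p[degen & m1 == m2] <- 1
  p[degen & m1 != m2] <- 0
  p[is.na(p)] <- 1
  q <- stats::p.adjust(p, method = "BH")

  up <- fc > thresholds$fc_threshold & q < thresholds$q_threshold
  down <- fc < 1 / thresholds$fc_threshold & q < thresholds$q_threshold
  tibble::tibble(
    gene_id = expr$gene_id,
    mean_normal = mean_n, mean_cancer = mean_c,
    fold_change = fc, log2_fc = log2(fc),
    p_value = p, q_value = q,
    direction = ifelse(up, "up", ifelse(down, "down", "ns")),
    significant = up | down
  )
}

#' Identify enhancer target genes from loop evidence and expression
#'
#' A loop supports gene `g` when one anchor overlaps a specific enhancer
#' (>= 1 bp) and the other anchor overlaps the promoter window
#' `[tss_g - tss_window, tss_g + tss_window)`. A gene is reported as a
#' target when the summed interaction count over its supporting loops
#' reaches `count_threshold` and the gene is significantly upregulated.
#'
#' @param loops Loop tibble with a `count` column (from
#'   [read_intervals()] or [annotate_loops()]).
#' @param specific Interval tibble of specific enhancers.
#' @param tss TSS annotation (`gene_id`, `chrom`, `tss`).
#' @param de Differential expression table from
#'   [differential_expression()].
#' @param thresholds An [integration_thresholds()] object.
#' @return Tibble of target genes: `gene_id`, `n_loops`,
#'   `evidence_count`, `max_span`, `is_long_range` (any supporting loop
#'   with span at or above the long-range threshold), `fold_change`,
#'   `q_value`, and a list-column `supporting_loops`. Attribute
#'   `universe` holds the pre-filter table of all genes with at least
#'   one supporting loop, regardless of the count and expression
#'   filters.
#' @export
identify_target_genes <- function(loops, specific, tss, de,
                                  thresholds = integration_thresholds()) {
  validate_loops(loops)
  validate_intervals(specific, "specific")
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(tss)),
            "gene_id" %in% names(de))
  loops <- tibble::as_tibble(loops)
  if (!"count" %in% names(loops)) loops$count <- 1
  if (!"span" %in% names(loops)) loops$span <- loop_span(loops)

  w <- thresholds$tss_window
  prom <- tibble::tibble(gene_id = tss$gene_id, chrom = tss$chrom,
                         start = pmax(0, tss$tss - w), end = tss$tss + w)

  a1 <- loop_anchor(loops, 1)
  a2 <- loop_anchor(loops, 2)
  e1 <- overlaps_any(a1, specific)
  e2 <- overlaps_any(a2, specific)
  p1 <- overlap_pairs_tbl(a1, prom)   # anchor1 on promoter
  p2 <- overlap_pairs_tbl(a2, prom)

  # support: enhancer on one anchor, promoter on the other
  sup <- dplyr::bind_rows(
    tibble::tibble(loop = p2$query, gene = p2$subject)[e1[p2$query], ],
    tibble::tibble(loop = p1$query, gene = p1$subject)[e2[p1$query], ]
  ) |> dplyr::distinct()

  if (nrow(sup) == 0) {
    empty <- tibble::tibble(gene_id = character(0), n_loops = integer(0),
                            evidence_count = numeric(0), max_span = numeric(0),
                            is_long_range = logical(0), fold_change = numeric(0),
                            q_value = numeric(0), supporting_loops = list())
    attr(empty, "universe") <- empty
    return(empty)
  }

  sup$gene_id <- prom$gene_id[sup$gene]
  missing_de <- setdiff(unique(sup$gene_id), de$gene_id)
  if (length(missing_de) > 0) {
    rlang::warn(sprintf("%d gene(s) with loop support absent from the DE table; skipped: %s",
                        length(missing_de),
                        paste(utils::head(missing_de, 5), collapse = ", ")))
    sup <- sup[!sup$gene_id %in% missing_de, , drop = FALSE]
  }

  universe <- sup |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_loops = dplyr::n_distinct(.data$loop),
      evidence_count = sum(loops$count[.data$loop]),
      max_span = suppressWarnings(max(loops$span[.data$loop], na.rm = TRUE)),
      supporting_loops = list(loops[unique(.data$loop), , drop = FALSE]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      max_span = dplyr::if_else(is.finite(.data$max_span), .data$max_span, NA_real_),
      is_long_range = purrr::map_lgl(
        .data$supporting_loops,
        function(l) any(l$span >= thresholds$long_range_bp, na.rm = TRUE))
    ) |>
    dplyr::left_join(de[, c("gene_id", "fold_change", "q_value")],
                     by = "gene_id") |>
    dplyr::mutate(upregulated = .data$fold_change > thresholds$fc_threshold &
                    .data$q_value < thresholds$q_threshold)

  targets <- universe |>
    dplyr::filter(.data$evidence_count >= thresholds$count_threshold,
                  .data$upregulated) |>
    dplyr::select("gene_id", "n_loops", "evidence_count", "max_span",
                  "is_long_range", "fold_change", "q_value",
                  "supporting_loops") |>
    dplyr::arrange(dplyr::desc(.data$evidence_count), .data$gene_id)

  attr(targets, "universe") <- universe
  attr(targets, "thresholds") <- thresholds
  targets
}

#' Fraction of long-range enhancer-target interactions
#'
#' Over all supporting loops of all target genes, the fraction whose span
#' is at or above the long-range threshold (20 kb by default). Loops
#' supporting several genes are counted once per gene, mirroring the
#' per-interaction view of the target table.
#'
#' @param targets Result of [identify_target_genes()].
#' @param thresholds An [integration_thresholds()] object.
#' @return A single fraction in `[0, 1]`, or `NA` (with a warning) for an
#'   empty target set.
#' @export
long_range_fraction <- function(targets, thresholds = integration_thresholds()) {
  if (nrow(targets) == 0) {
    rlang::warn("empty target set: long-range fraction undefined")
    return(NA_real_)
  }
  spans <- unlist(purrr::map(targets$supporting_loops, "span"))
  spans <- spans[!is.na(spans)]
  mean(spans >= thresholds$long_range_bp)
}
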