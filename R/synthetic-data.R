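# Seeded generators for synthetic regulatory landscapes with planted
# ground truth: multi-sample peak sets, paired TAD segmentations, HiChIP
# style loops and expression tables. Every planted object is re-derivable
# by the corresponding pipeline stage under default thresholds.

#' Configuration for the synthetic-data generators
#'
#' One object drives all three generators; `seed` is mandatory and every
#' stage derives its own seed from it so stages can be regenerated
#' independently. Defaults encode the study conditions the pipeline is
#' tested under: a multi-sample design of 7 target (cancer) and 10
#' background (normal) H3K27ac sample sets, at least 500 peaks per
#' sample, log-normal peak signal with a planted heavy tail of super
#' enhancers, six planted TAD boundary-change categories, distance
#' decaying loop spans with a long-range (>= 20 kb) probability of 0.8,
#' negative-binomial interaction counts, and a TCGA-sized expression
#' cohort (349 normal, 275 cancer) with planted fold changes.
#'
#' @param seed Integer seed (mandatory).
#' @param n_chromosomes,chrom_length_bp Synthetic genome shape.
#' @param n_target_samples,n_background_samples Peak sample counts.
#' @param n_shared_enhancers,n_specific_enhancers,n_background_enhancers
#'   Planted enhancer counts by class (shared = active in every sample,
#'   specific = target-only, background = background-only).
#' @param n_decoy_tss_peaks Target-sample peaks planted inside the
#'   +/- 2.5 kb TSS window of a decoy gene (exercise the TSS filter).
#' @param peak_width_meanlog,peak_width_sdlog Log-normal peak widths.
#' @param signal_meanlog,signal_sdlog Log-normal peak signal.
#' @param super_fraction,super_scale Fraction of specific enhancers given
#'   heavy-tail signal (planted super enhancers) and their scale factor.
#' @param jitter_bp Per-sample boundary jitter (<= 200 bp by default) so
#'   the any-overlap logic, not exact matching, is exercised.
#' @param tss_exclusion_bp TSS window the landscape placement respects.
#' @param slot_pitch Spacing of the placement grid in bp.
#' @param tads_per_category,n_unchanged_tads Planted TAD events per
#'   category per chromosome.
#' @param tad_length_bp,tad_length_jitter,tad_shift_bp,tad_gap_bp,
#'   tad_inner_gap_bp TAD geometry; `tad_shift_bp` defaults to 120 kb,
#'   three times the classifier's 40 kb tolerance.
#' @param n_wired_pass Genes wired to a specific enhancer with planted
#'   evidence count >= 5 and fold change > 1.5 (true targets).
#' @param n_decoy_low_count,n_decoy_low_fc,n_decoy_unwired Decoy genes
#'   failing exactly one target filter each (interaction count < 5;
#'   fold change 1; upregulated but no loop).
#' @param n_nonspecific_loops,n_noise_loops Loops anchored on shared
#'   enhancers / on random non-enhancer positions.
#' @param span_min,span_max,long_range_prob Truncated power-law loop
#'   span distribution; the exponent is solved so that
#'   `P(span >= 20 kb) = long_range_prob`.
#' @param count_mu,count_size Negative-binomial interaction counts.
#' @param n_genes Total genes in the annotation and expression table.
#' @param n_bg_up,n_bg_down Unwired background genes with planted up /
#'   down regulation.
#' @param n_expr_normal,n_expr_cancer Expression cohort sizes.
#' @param expr_meanlog,expr_sdlog Log-normal baseline abundance.
#' @param noise_cv Per-sample multiplicative noise (coefficient of
#'   variation).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 4, chrom_length_bp = 1e8,
                       n_target_samples = 7, n_background_samples = 10,
                       n_shared_enhancers = 250, n_specific_enhancers = 150,
                       n_background_enhancers = 250, n_decoy_tss_peaks = 100,
                       peak_width_meanlog = log(1500), peak_width_sdlog = 0.3,
                       signal_meanlog = 1, signal_sdlog = 0.25,
                       super_fraction = 0.05, super_scale = 50,
                       jitter_bp = 200, tss_exclusion_bp = 2500,
                       slot_pitch = 30000,
                       tads_per_category = 10, n_unchanged_tads = 10,
                       tad_length_bp = 4e5, tad_length_jitter = 0.1,
                       tad_shift_bp = 120000, tad_gap_bp = 200000,
                       tad_inner_gap_bp = 50000,
                       n_wired_pass = 50, n_decoy_low_count = 17,
                       n_decoy_low_fc = 17, n_decoy_unwired = 16,
                       n_nonspecific_loops = 200, n_noise_loops = 500,
                       span_min = 10000, span_max = 2e6,
                       long_range_prob = 0.8,
                       count_mu = 8, count_size = 2,
                       n_genes = 1000, n_bg_up = 100, n_bg_down = 100,
                       n_expr_normal = 349, n_expr_cancer = 275,
                       expr_meanlog = log(50), expr_sdlog = 1,
                       noise_cv = 0.3) {
  if (missing(seed) || length(seed) != 1 || is.na(seed)) {
    abort_usage("`seed` is mandatory")
  }
  cfg <- as.list(environment())
  counts <- c(cfg$n_chromosomes, cfg$chrom_length_bp, cfg$n_target_samples,
              cfg$n_background_samples, cfg$n_genes)
  if (any(counts <= 0)) abort_usage("genome, sample and gene counts must be > 0")
  n_wired <- cfg$n_wired_pass + cfg$n_decoy_low_count + cfg$n_decoy_low_fc
  if (n_wired > cfg$n_specific_enhancers) {
    abort_usage("need at least as many specific enhancers as wired genes")
  }
  if (n_wired + cfg$n_decoy_unwired + cfg$n_decoy_tss_peaks +
      cfg$n_bg_up + cfg$n_bg_down > cfg$n_genes) {
    abort_usage("`n_genes` too small for the planted gene roles")
  }
  if (cfg$span_min <= 0 || cfg$span_max <= cfg$span_min) {
    abort_usage("need 0 < span_min < span_max")
  }
  if (cfg$long_range_prob <= 0 || cfg$long_range_prob >= 1) {
    abort_usage("`long_range_prob` must be in (0, 1)")
  }
  structure(cfg, class = "sim_config")
}

# Exponent of a truncated Pareto on [xmin, xmax] such that
# P(X >= threshold) = p.
span_pareto_exponent <- function(p, xmin, xmax, threshold = 20000) {
  r1 <- xmin / threshold
  r2 <- xmin / xmax
  f <- function(a) (r1^a - r2^a) / (1 - r2^a) - p
  stats::uniroot(f, c(1e-8, 50), tol = 1e-12)$root
}

rpareto_trunc <- function(n, alpha, xmin, xmax) {
  u <- stats::runif(n)
  r2a <- (xmin / xmax)^alpha
  xmin * (1 - u * (1 - r2a))^(-1 / alpha)
}

draw_spans <- function(n, config) {
  alpha <- span_pareto_exponent(config$long_range_prob, config$span_min,
                                config$span_max)
  round(rpareto_trunc(n, alpha, config$span_min, config$span_max))
}

split_across <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + as.integer(seq_len(k) <= extra)
}

#' Generate a multi-sample synthetic peak landscape with planted truth
#'
#' Emulates a multi-tissue H3K27ac design: shared enhancers appear (with
#' boundary jitter and resampled scores) in every sample, target-specific
#' enhancers only in target samples, background-only enhancers only in
#' background samples. A configured fraction of specific enhancers get
#' heavy-tail signal (planted super enhancers). Genes destined to be
#' wired to specific enhancers have their TSS placed at power-law
#' distributed distances from the partner enhancer; decoy genes carry a
#' planted target-sample peak inside their TSS window so the promoter
#' filter is exercised.
#'
#' @param config A [sim_config()] object.
#' @return A list with `peaks` (long tibble: `sample_id`,
#'   `tissue_label`, `chrom`, `start`, `end`, `score`), `tss` (gene
#'   annotation), `targets`/`backgrounds` (sample id vectors) and
#'   `truth` (planted enhancer sets, expected recovered intervals,
#'   planted supers, gene roles and enhancer-gene wiring).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  margin <- config$span_max + 1e6

  if (config$chrom_length_bp <= 2 * margin + 10 * config$slot_pitch) {
    rlang::abort("chromosomes too short for enhancer placement; increase chrom_length_bp",
                 class = "cregnet_generation_error")
  }

  # --- placement grid -------------------------------------------------
  slots <- purrr::map(chroms, function(ch) {
    centers <- seq(margin, config$chrom_length_bp - margin, by = config$slot_pitch)
    centers <- centers + round(stats::runif(length(centers), -5000, 5000))
    tibble::tibble(chrom = ch, center = centers[sample.int(length(centers))])
  }) |> dplyr::bind_rows()

  n_wired <- config$n_wired_pass + config$n_decoy_low_count + config$n_decoy_low_fc
  n_slot_genes <- config$n_genes - n_wired
  need <- config$n_shared_enhancers + config$n_specific_enhancers +
    config$n_background_enhancers + n_slot_genes
  if (need > nrow(slots)) {
    rlang::abort(sprintf(
      "placement infeasible: %d slots available for %d planted objects; increase chrom_length_bp or n_chromosomes",
      nrow(slots), need), class = "cregnet_generation_error")
  }
  # balance classes across chromosomes
  slots <- slots |> dplyr::group_by(.data$chrom) |>
    dplyr::mutate(.r = dplyr::row_number()) |> dplyr::ungroup() |>
    dplyr::arrange(.data$.r, .data$chrom)
  roles <- c(rep("specific", config$n_specific_enhancers),
             rep("shared", config$n_shared_enhancers),
             rep("background", config$n_background_enhancers),
             rep("slot_gene", n_slot_genes))
  slots <- slots[seq_along(roles), ]
  slots$role <- roles

  enhancer_interval <- function(centers) {
    w <- pmin(5000, pmax(600, round(stats::rlnorm(length(centers),
                                                  config$peak_width_meanlog,
                                                  config$peak_width_sdlog))))
    tibble::tibble(start = pmax(0, centers - w %/% 2),
                   end = centers - w %/% 2 + w)
  }

  mk_set <- function(role) {
    s <- slots[slots$role == role, ]
    dplyr::bind_cols(tibble::tibble(chrom = s$chrom), enhancer_interval(s$center)) |>
      sort_intervals()
  }
  specific <- mk_set("specific")
  shared <- mk_set("shared")
  background <- mk_set("background")
  specific$enhancer_id <- sprintf("spec_%03d", seq_len(nrow(specific)))
  n_super <- ceiling(config$super_fraction * nrow(specific))
  super_idx <- sort(sample.int(nrow(specific), n_super))
  specific$is_super <- seq_len(nrow(specific)) %in% super_idx

  # --- genes ----------------------------------------------------------
  gene_slots <- slots[slots$role == "slot_gene", ]
  slot_roles <- c(rep("decoy_tss", config$n_decoy_tss_peaks),
                  rep("decoy_unwired", config$n_decoy_unwired),
                  rep("bg_up", config$n_bg_up),
                  rep("bg_down", config$n_bg_down),
                  rep("background", n_slot_genes - config$n_decoy_tss_peaks -
                        config$n_decoy_unwired - config$n_bg_up - config$n_bg_down))
  slot_roles <- slot_roles[sample.int(length(slot_roles))]
  slot_genes <- tibble::tibble(chrom = gene_slots$chrom,
                               tss = gene_slots$center,
                               role = slot_roles)

  # wired genes: TSS at power-law distance from a distinct specific enhancer
  wired_roles <- c(rep("wired_pass", config$n_wired_pass),
                   rep("decoy_low_count", config$n_decoy_low_count),
                   rep("decoy_low_fc", config$n_decoy_low_fc))
  wired_enh <- sample.int(nrow(specific), length(wired_roles))
  enh_mid <- floor((specific$start + specific$end) / 2)
  # everything a wired TSS must keep clear of (any target-sample peak body)
  avoid <- dplyr::bind_rows(specific[interval_cols], shared[interval_cols])
  pad <- config$tss_exclusion_bp + config$jitter_bp + 100

  place_wired <- function(mids, chrom) {
    n <- length(mids)
    tss <- rep(NA_real_, n)
    span <- rep(NA_real_, n)
    todo <- seq_len(n)
    for (try in 1:60) {
      if (length(todo) == 0) break
      d <- draw_spans(length(todo), config)
      dir <- sample(c(-1, 1), length(todo), replace = TRUE)
      cand <- mids[todo] + dir * d
      ok <- cand > margin / 2 & cand < config$chrom_length_bp - margin / 2
      win <- tibble::tibble(chrom = chrom[todo],
                            start = pmax(0, cand - pad), end = cand + pad)
      ok[ok] <- !overlaps_any(win[ok, , drop = FALSE], avoid)
      tss[todo[ok]] <- cand[ok]
      span[todo[ok]] <- d[ok]
      todo <- todo[!ok]
    }
    if (length(todo) > 0) {
      rlang::abort("could not place wired gene TSS after 60 rounds; increase chrom_length_bp",
                   class = "cregnet_generation_error")
    }
    list(tss = tss, span = span)
  }
  wchrom <- specific$chrom[wired_enh]
  placed <- place_wired(enh_mid[wired_enh], wchrom)
  wired_genes <- tibble::tibble(chrom = wchrom, tss = placed$tss,
                                role = wired_roles,
                                enhancer_id = specific$enhancer_id[wired_enh],
                                planted_span = placed$span)

  genes <- dplyr::bind_rows(wired_genes, slot_genes) |>
    dplyr::mutate(
      gene_id = sprintf("gene_%04d", dplyr::row_number()),
      strand = sample(c("+", "-"), dplyr::n(), replace = TRUE)
    )
  tss <- genes[, c("gene_id", "chrom", "tss", "strand")]

  # decoy TSS-proximal peaks (target samples only)
  decoy_genes <- genes[genes$role == "decoy_tss", ]
  decoy_peaks <- tibble::tibble(
    chrom = decoy_genes$chrom,
    start = decoy_genes$tss + 500,
    end = decoy_genes$tss + 500 +
      pmax(600, round(stats::rlnorm(nrow(decoy_genes), log(1200), 0.2)))
  )

  # --- per-sample peak emission --------------------------------------
  targets <- sprintf("cancer_%02d", seq_len(config$n_target_samples))
  backgrounds <- sprintf("colon_%02d", seq_len(config$n_background_samples))

  emit <- function(core, sample_id, tissue_label, score_scale = 1) {
    n <- nrow(core)
    if (n == 0) return(NULL)
    j1 <- sample(-config$jitter_bp:config$jitter_bp, n, replace = TRUE)
    j2 <- sample(-config$jitter_bp:config$jitter_bp, n, replace = TRUE)
    tibble::tibble(
      sample_id = sample_id, tissue_label = tissue_label,
      chrom = core$chrom,
      start = pmax(0, core$start + j1), end = core$end + j2,
      score = stats::rlnorm(n, config$signal_meanlog, config$signal_sdlog) *
        score_scale,
      planted_id = core$planted_id
    )
  }

  spec_core <- dplyr::mutate(specific[interval_cols],
                             planted_id = specific$enhancer_id)
  spec_scale <- ifelse(specific$is_super, config$super_scale, 1)
  shared_core <- dplyr::mutate(shared[interval_cols],
                               planted_id = sprintf("shared_%03d", seq_len(nrow(shared))))
  bg_core <- dplyr::mutate(background[interval_cols],
                           planted_id = sprintf("bg_%03d", seq_len(nrow(background))))
  decoy_core <- dplyr::mutate(decoy_peaks,
                              planted_id = sprintf("decoy_%03d", seq_len(nrow(decoy_peaks))))

  target_peaks <- purrr::map(targets, function(s) {
    sp <- emit(spec_core, s, "colorectal_cancer")
    sp$score <- sp$score * spec_scale
    dplyr::bind_rows(sp,
                     emit(shared_core, s, "colorectal_cancer"),
                     emit(decoy_core, s, "colorectal_cancer"))
  })
  background_peaks <- purrr::map(backgrounds, function(s) {
    dplyr::bind_rows(emit(shared_core, s, "colon"),
                     emit(bg_core, s, "colon"))
  })
  peaks <- dplyr::bind_rows(target_peaks, background_peaks) |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$start, .data$end)

  # expected recovered specific intervals: union of the jittered copies
  tp <- dplyr::bind_rows(target_peaks)
  if (nrow(specific) == 0) {
    expected <- tibble::tibble(chrom = character(0), start = numeric(0),
                               end = numeric(0), enhancer_id = character(0))
  } else {
    expected <- tp[tp$planted_id %in% specific$enhancer_id, ] |>
      dplyr::group_by(.data$planted_id) |>
      dplyr::summarise(chrom = .data$chrom[1], start = min(.data$start),
                       end = max(.data$end), .groups = "drop") |>
      dplyr::rename(enhancer_id = "planted_id") |>
      dplyr::select("chrom", "start", "end", "enhancer_id") |>
      sort_intervals()
  }

  truth <- list(
    planted_specific = specific,
    expected_specific = expected,
    planted_supers = specific[specific$is_super, ],
    planted_shared = shared,
    planted_background = background,
    decoy_tss_peaks = decoy_peaks,
    genes = genes,
    wiring = wired_genes[, c("enhancer_id", "role", "chrom", "tss", "planted_span")] |>
      dplyr::mutate(gene_id = genes$gene_id[seq_len(nrow(wired_genes))], .before = 1)
  )
  list(peaks = peaks[, c("sample_id", "tissue_label", "chrom", "start", "end", "score")],
       tss = tss, targets = targets, backgrounds = backgrounds,
       truth = truth, config = config)
}

#' Generate a paired TAD segmentation with planted boundary changes
#'
#' Tiles each chromosome with domain blocks separated by gaps larger
#' than the classifier tolerance, then applies each planted change
#' category (`expand`, `narrow`, `fusion`, `split`, `appear`,
#' `disappear`, plus unchanged filler) the configured number of times
#' per chromosome, with boundary shifts of `tad_shift_bp` (default three
#' times the 40 kb tolerance). Ground-truth labels are recorded per
#' block.
#'
#' @param config A [sim_config()] object.
#' @return A list with `normal` and `cancer` TAD tibbles and `truth`
#'   (tibble of `event_id`, `chrom`, `category`, block bounds).
#' @export
generate_tad_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  cats <- c(rep(changed_categories, each = config$tads_per_category),
            rep("unchanged", config$n_unchanged_tads))

  normal <- list(); cancer <- list(); truth <- list()
  for (ch in chroms) {
    events <- cats[sample.int(length(cats))]
    cursor <- 1e5
    for (ev in events) {
      L <- round(config$tad_length_bp *
                   stats::runif(1, 1 - config$tad_length_jitter,
                                1 + config$tad_length_jitter))
      s <- config$tad_shift_bp
      g <- config$tad_inner_gap_bp
      a <- cursor
      nm <- cm <- NULL
      if (ev == "unchanged") {
        nm <- cm <- c(a, a + L); block <- L
      } else if (ev == "expand") {
        if (stats::runif(1) < 0.5) { nm <- c(a, a + L); cm <- c(a, a + L + s) }
        else { nm <- c(a + s, a + L + s); cm <- c(a, a + L + s) }
        block <- L + s
      } else if (ev == "narrow") {
        if (stats::runif(1) < 0.5) { nm <- c(a, a + L); cm <- c(a, a + L - s) }
        else { nm <- c(a, a + L); cm <- c(a + s, a + L) }
        block <- L
      } else if (ev == "fusion") {
        k <- if (stats::runif(1) < 0.25) 3 else 2
        Ls <- round(L * stats::runif(k, 0.8, 1.2))
        starts <- a + cumsum(c(0, utils::head(Ls, -1) + g))
        nm <- cbind(starts, starts + Ls)
        cm <- c(a, max(starts + Ls))
        block <- max(starts + Ls) - a
      } else if (ev == "split") {
        k <- if (stats::runif(1) < 0.25) 3 else 2
        Ls <- round(L * stats::runif(k, 0.8, 1.2))
        starts <- a + cumsum(c(0, utils::head(Ls, -1) + g))
        cm <- cbind(starts, starts + Ls)
        nm <- c(a, max(starts + Ls))
        block <- max(starts + Ls) - a
      } else if (ev == "appear") {
        cm <- c(a, a + L); block <- L
      } else if (ev == "disappear") {
        nm <- c(a, a + L); block <- L
      }
      if (cursor + block + 1e5 > config$chrom_length_bp) {
        rlang::abort("planted TAD events exceed chromosome length; increase chrom_length_bp",
                     class = "cregnet_generation_error")
      }
      to_tbl <- function(m) {
        if (is.null(m)) return(NULL)
        if (!is.matrix(m)) m <- matrix(m, ncol = 2)
        tibble::tibble(chrom = ch, start = m[, 1], end = m[, 2])
      }
      normal[[length(normal) + 1]] <- to_tbl(nm)
      cancer[[length(cancer) + 1]] <- to_tbl(cm)
      truth[[length(truth) + 1]] <- tibble::tibble(
        chrom = ch, category = ev, block_start = a, block_end = a + block)
      cursor <- cursor + block + config$tad_gap_bp
    }
  }
  truth <- dplyr::bind_rows(truth) |>
    dplyr::arrange(.data$chrom, .data$block_start)
  truth$event_id <- seq_len(nrow(truth))
  list(normal = sort_intervals(dplyr::bind_rows(normal)),
       cancer = sort_intervals(dplyr::bind_rows(cancer)),
       truth = dplyr::relocate(truth, "event_id"))
}

#' Generate loops and an expression table wired to the planted landscape
#'
#' Wired loops connect each wired gene's planted specific enhancer to the
#' gene's promoter; spans follow the configured power law by
#' construction (the landscape placed the TSS at the drawn distance) and
#' interaction counts are negative binomial, conditioned at >= 5 for
#' genes planted to pass the count filter and capped at < 5 for
#' low-count decoys. Additional loops anchor on shared (non-specific)
#' enhancers or on random non-enhancer positions. Expression is drawn
#' log-normal with multiplicative noise; planted fold changes are
#' applied to the cancer group of wired and background DE genes.
#'
#' @param config A [sim_config()] object.
#' @param landscape Result of [generate_landscape()].
#' @return A list with `loops` (tibble `chrom1..end2`, `count`),
#'   `expression` (tibble `gene_id` + sample columns), `groups`
#'   (`sample_id`, `group`) and `truth` (`loops` roles keyed by row,
#'   `planted_fc` per gene, wired totals per gene).
#' @export
generate_loops_and_expression <- function(config, landscape) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  truth <- landscape$truth
  specific <- truth$planted_specific
  shared <- truth$planted_shared
  wiring <- truth$wiring
  genes <- truth$genes

  if (!all(wiring$gene_id %in% landscape$tss$gene_id)) {
    abort_usage("wiring genes missing from the TSS annotation")
  }

  # --- wired loops ----------------------------------------------------
  ei <- match(wiring$enhancer_id, specific$enhancer_id)
  enh <- specific[ei, ]
  n_w <- nrow(wiring)
  counts <- integer(n_w)
  pass <- wiring$role %in% c("wired_pass", "decoy_low_fc")
  counts[pass] <- 5L + stats::rnbinom(sum(pass), size = config$count_size,
                                      mu = max(0.5, config$count_mu - 5))
  counts[!pass] <- sample(1:4, sum(!pass), replace = TRUE)

  wired <- tibble::tibble(
    chrom1 = enh$chrom, start1 = enh$start, end1 = enh$end,
    chrom2 = wiring$chrom, start2 = wiring$tss - 1000, end2 = wiring$tss + 1000,
    count = counts, role = paste0("wired_", wiring$role),
    gene_id = wiring$gene_id
  )
  flip <- wired$start2 < wired$start1
  wired[flip, c("chrom1", "start1", "end1", "chrom2", "start2", "end2")] <-
    wired[flip, c("chrom2", "start2", "end2", "chrom1", "start1", "end1")]

  # --- decoy loops ----------------------------------------------------
  avoid <- dplyr::mutate(specific[interval_cols],
                         start = pmax(0, .data$start - config$jitter_bp - 50),
                         end = .data$end + config$jitter_bp + 50)
  margin <- 1e5
  anchor_w <- 2000

  draw_second <- function(a1) {
    n <- nrow(a1)
    out_start <- rep(NA_real_, n)
    todo <- seq_len(n)
    for (try in 1:60) {
      if (length(todo) == 0) break
      d <- draw_spans(length(todo), config)
      dir <- sample(c(-1, 1), length(todo), replace = TRUE)
      mid <- floor((a1$start[todo] + a1$end[todo]) / 2) + dir * d
      st <- mid - anchor_w %/% 2
      ok <- st > margin & st + anchor_w < config$chrom_length_bp - margin
      cand <- tibble::tibble(chrom = a1$chrom[todo], start = pmax(0, st),
                             end = pmax(0, st) + anchor_w)
      ok[ok] <- !overlaps_any(cand[ok, , drop = FALSE], avoid)
      out_start[todo[ok]] <- st[ok]
      todo <- todo[!ok]
    }
    if (length(todo) > 0) {
      rlang::abort("could not place loop anchors; increase chrom_length_bp",
                   class = "cregnet_generation_error")
    }
    out_start
  }

  nonspec <- NULL
  if (config$n_nonspecific_loops > 0) {
    si <- sample.int(nrow(shared), config$n_nonspecific_loops, replace = TRUE)
    a1 <- shared[si, interval_cols]
    s2 <- draw_second(a1)
    nonspec <- tibble::tibble(
      chrom1 = a1$chrom, start1 = a1$start, end1 = a1$end,
      chrom2 = a1$chrom, start2 = s2, end2 = s2 + anchor_w,
      count = 1 + stats::rnbinom(nrow(a1), size = config$count_size,
                                 mu = config$count_mu / 4),
      role = "nonspecific", gene_id = NA_character_
    )
  }

  noise <- NULL
  if (config$n_noise_loops > 0) {
    n <- config$n_noise_loops
    ch <- sample(paste0("chr", seq_len(config$n_chromosomes)), n, replace = TRUE)
    a1 <- tibble::tibble(chrom = ch, start = NA_real_, end = NA_real_)
    todo <- seq_len(n)
    for (try in 1:60) {
      if (length(todo) == 0) break
      st <- round(stats::runif(length(todo), margin,
                               config$chrom_length_bp - margin - anchor_w))
      cand <- tibble::tibble(chrom = ch[todo], start = st, end = st + anchor_w)
      ok <- !overlaps_any(cand, avoid)
      a1$start[todo[ok]] <- st[ok]
      a1$end[todo[ok]] <- st[ok] + anchor_w
      todo <- todo[!ok]
    }
    if (length(todo) > 0) {
      rlang::abort("could not place noise loop anchors", class = "cregnet_generation_error")
    }
    s2 <- draw_second(a1)
    noise <- tibble::tibble(
      chrom1 = a1$chrom, start1 = a1$start, end1 = a1$end,
      chrom2 = ch, start2 = s2, end2 = s2 + anchor_w,
      count = 1 + stats::rnbinom(n, size = config$count_size,
                                 mu = config$count_mu / 4),
      role = "noise", gene_id = NA_character_
    )
  }

  all_loops <- dplyr::bind_rows(wired, nonspec, noise)
  flip <- all_loops$start2 < all_loops$start1
  all_loops[flip, c("chrom1", "start1", "end1", "chrom2", "start2", "end2")] <-
    all_loops[flip, c("chrom2", "start2", "end2", "chrom1", "start1", "end1")]
  all_loops$loop_id <- seq_len(nrow(all_loops))
  loops <- all_loops[, c("chrom1", "start1", "end1", "chrom2", "start2",
                         "end2", "count")]

  # --- expression -----------------------------------------------------
  n_genes <- nrow(genes)
  base <- stats::rlnorm(n_genes, config$expr_meanlog, config$expr_sdlog)
  fc <- rep(1, n_genes)
  up_roles <- c("wired_pass", "decoy_low_count", "decoy_unwired")
  fc[genes$role %in% up_roles] <- stats::runif(sum(genes$role %in% up_roles), 2, 6)
  fc[genes$role == "bg_up"] <- stats::runif(sum(genes$role == "bg_up"), 2, 4)
  fc[genes$role == "bg_down"] <- 1 / stats::runif(sum(genes$role == "bg_down"), 2, 4)
  # keep planted-effect genes at detectable abundance so the pseudocount
  # fold change reflects the planted effect
  base[fc != 1] <- pmax(5, base[fc != 1])

  s <- sqrt(log(1 + config$noise_cv^2))
  n_n <- config$n_expr_normal
  n_c <- config$n_expr_cancer
  noise_mat <- function(ncol) {
    matrix(stats::rlnorm(n_genes * ncol, -s^2 / 2, s), nrow = n_genes)
  }
  xn <- base * noise_mat(n_n)
  xc <- (base * fc) * noise_mat(n_c)
  sample_ids <- c(sprintf("N%03d", seq_len(n_n)), sprintf("C%03d", seq_len(n_c)))
  expr <- dplyr::bind_cols(
    tibble::tibble(gene_id = genes$gene_id),
    tibble::as_tibble(`colnames<-`(cbind(xn, xc), sample_ids))
  )
  groups <- tibble::tibble(sample_id = sample_ids,
                           group = rep(c("normal", "cancer"), c(n_n, n_c)))

  wired_totals <- wired |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(total_count = sum(.data$count), .groups = "drop")

  list(
    loops = loops,
    expression = expr,
    groups = groups,
    truth = list(
      loop_roles = all_loops[, c("loop_id", "role", "gene_id")],
      planted_fc = tibble::tibble(gene_id = genes$gene_id, role = genes$role,
                                  fold_change = fc),
      wired_totals = wired_totals,
      planted_spans = wiring$planted_span
    )
  )
}
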