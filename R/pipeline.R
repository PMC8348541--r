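#' Pipeline configuration
#'
#' Builds a validated run configuration for [run_pipeline()]. In
#' `simulate` mode a [sim_config()] drives seeded data generation; in
#' `files` mode all inputs are read from disk and every referenced path
#' must exist (validated before any stage runs).
#'
#' @param mode `"simulate"` or `"files"`.
#' @param sim A [sim_config()] (simulate mode).
#' @param paths Named list of input paths (files mode): `targets` and
#'   `backgrounds` (character vectors of broadPeak/BED files), `tss`
#'   (BED with gene id in the name column), `loops` (BEDPE),
#'   `tad_normal`, `tad_cancer` (BED), `expression` (TSV, genes x
#'   samples), `groups` (TSV: sample_id, group).
#' @param thresholds An [integration_thresholds()] object.
#' @param vel_n Number of variant enhancer loci to retain (`NULL` keeps
#'   all loci).
#' @param boundary_tol,min_overlap_frac TAD classifier parameters.
#' @param stitch_gap Super-enhancer stitching distance (bp).
#' @param n_random_loops Size of the random loop reference class.
#' @param out_dir Output directory for stage artifacts (`NULL` for none).
#' @param seed Seed for the pipeline's own randomness (the random loop
#'   reference); defaults to the simulation seed in simulate mode.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "files"), sim = NULL,
                       paths = list(), thresholds = integration_thresholds(),
                       vel_n = NULL, boundary_tol = 40000,
                       min_overlap_frac = 0.1, stitch_gap = 12500,
                       n_random_loops = 1000, out_dir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "simulate") {
    if (!inherits(sim, "sim_config")) {
      abort_usage("simulate mode needs a sim_config() in `sim`")
    }
    if (is.null(seed)) seed <- sim$seed
  } else {
    need <- c("targets", "backgrounds", "tss", "loops", "tad_normal",
              "tad_cancer", "expression", "groups")
    missing <- setdiff(need, names(paths))
    if (length(missing) > 0) {
      abort_usage(sprintf("files mode config lacks path(s): %s",
                          paste(missing, collapse = ", ")))
    }
    flat <- unlist(paths[need], use.names = FALSE)
    absent <- flat[!file.exists(flat)]
    if (length(absent) > 0) {
      abort_usage(sprintf("input file(s) not found: %s",
                          paste(absent, collapse = ", ")))
    }
    if (is.null(seed)) seed <- 1L
  }
  structure(list(mode = mode, sim = sim, paths = paths,
                 thresholds = thresholds, vel_n = vel_n,
                 boundary_tol = boundary_tol,
                 min_overlap_frac = min_overlap_frac,
                 stitch_gap = stitch_gap, n_random_loops = n_random_loops,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Read a TSS annotation from a BED-like file
#'
#' Expects at least four columns (`chrom`, `start`, `end`, `gene_id`);
#' a sixth column, when present, is the strand. The TSS coordinate is
#' the interval start for `+`/unstranded genes and `end - 1` for `-`
#' genes.
#'
#' @param path Path to the BED file.
#' @return Tibble `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                       progress = FALSE)
  if (ncol(x) < 4) abort_parse("TSS BED needs >= 4 columns (chrom, start, end, gene_id)")
  strand <- if (ncol(x) >= 6) as.character(x[[6]]) else rep("+", nrow(x))
  tibble::tibble(
    gene_id = as.character(x[[4]]),
    chrom = as.character(x[[1]]),
    tss = ifelse(strand == "-", as.numeric(x[[3]]) - 1, as.numeric(x[[2]])),
    strand = strand
  )
}

#' Run the full enhancer regulatory-network pipeline
#'
#' Executes the stages in order — specific-enhancer calling, super
#' enhancers, density-matrix profiles, loop annotation and span
#' comparison, TAD change classification, differential expression and
#' target-gene integration — and aggregates per-stage summaries into a
#' report. Reruns with an identical configuration reproduce identical
#' results. If a stage fails the error names the stage.
#'
#' @param config A [run_config()] object.
#' @return A list of class `cregnet_report` carrying per-stage result
#'   objects and summary counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)), parent = e)
    })
  }

  # ---- inputs --------------------------------------------------------
  inputs <- stage("inputs", {
    if (config$mode == "simulate") {
      land <- generate_landscape(config$sim)
      tads <- generate_tad_pair(config$sim)
      le <- generate_loops_and_expression(config$sim, land)
      list(peaks = land$peaks, tss = land$tss, targets = land$targets,
           backgrounds = land$backgrounds, loops = le$loops,
           expression = le$expression, groups = le$groups,
           tad_normal = tads$normal, tad_cancer = tads$cancer,
           truth = list(landscape = land$truth, tads = tads$truth,
                        loops = le$truth))
    } else {
      p <- config$paths
      read_class <- function(files, tissue) {
        purrr::imap(files, function(f, i) {
          fmt <- if (grepl("\\.broadPeak$", f, ignore.case = TRUE)) "broadpeak" else "bed"
          x <- read_intervals(f, fmt)
          nm <- if (is.character(i) && nzchar(i)) i else
            sub("\\.[^.]+$", "", basename(f))
          dplyr::mutate(x, sample_id = nm, tissue_label = tissue)
        }) |> dplyr::bind_rows()
      }
      tpk <- read_class(p$targets, "target")
      bpk <- read_class(p$backgrounds, "background")
      expr <- readr::read_tsv(p$expression, col_types = readr::cols(),
                              progress = FALSE)
      names(expr)[1] <- "gene_id"
      groups <- readr::read_tsv(p$groups, col_types = readr::cols(),
                                progress = FALSE)
      names(groups)[1:2] <- c("sample_id", "group")
      list(peaks = dplyr::bind_rows(tpk, bpk), tss = read_tss(p$tss),
           targets = unique(tpk$sample_id),
           backgrounds = unique(bpk$sample_id),
           loops = read_intervals(p$loops, "bedpe"),
           expression = expr, groups = groups,
           tad_normal = read_intervals(p$tad_normal, "bed")[interval_cols],
           tad_cancer = read_intervals(p$tad_cancer, "bed")[interval_cols],
           truth = NULL)
    }
  })

  # ---- enhancers -----------------------------------------------------
  enh <- stage("enhancers", {
    specific <- call_specific_enhancers(inputs$peaks, inputs$targets,
                                        inputs$backgrounds, inputs$tss,
                                        tss_window = th$tss_window,
                                        tissue_label = "target_specific")
    background_specific <- call_specific_enhancers(inputs$peaks,
                                                   inputs$backgrounds,
                                                   inputs$targets, inputs$tss,
                                                   tss_window = th$tss_window,
                                                   tissue_label = "background_specific")
    supers <- if (nrow(specific) >= 2) {
      stitch_and_rank_super_enhancers(specific, stitch_gap = config$stitch_gap)
    } else NULL
    list(specific = specific, background_specific = background_specific,
         supers = supers)
  })

  # ---- profiles ------------------------------------------------------
  prof <- stage("profiles", {
    if (nrow(enh$specific) < 2) return(NULL)
    dmat <- build_density_matrix(inputs$peaks, enh$specific[interval_cols])
    n_vel <- min(config$vel_n %||% nrow(dmat), nrow(dmat))
    vels <- select_variant_enhancer_loci(dmat, n_vel)
    pearson_d <- correlation_distance_matrix(vels, "pearson")
    spearman_d <- correlation_distance_matrix(vels, "spearman")
    list(density = dmat, vels = vels, pearson_dist = pearson_d,
         spearman_dist = spearman_d, hclust = cluster_samples(pearson_d))
  })

  # ---- loops ---------------------------------------------------------
  loops <- stage("loops", {
    merged_target <- inputs$peaks[inputs$peaks$sample_id %in% inputs$targets, ] |>
      exclude_tss_proximal(inputs$tss, th$tss_window) |>
      merge_intervals(gap = 0)
    nonspecific <- subtract_overlapping(merged_target, enh$specific[interval_cols])
    ann <- annotate_loops(inputs$loops, enh$specific[interval_cols], nonspecific)
    spans <- compare_span_distributions(
      ann, n_random = min(config$n_random_loops, nrow(ann)),
      seed = config$seed)
    list(annotated = ann, nonspecific = nonspecific, span_comparison = spans)
  })

  # ---- tads ----------------------------------------------------------
  tads <- stage("tads", {
    changes <- classify_tad_changes(inputs$tad_normal, inputs$tad_cancer,
                                    boundary_tol = config$boundary_tol,
                                    min_overlap_frac = config$min_overlap_frac)
    summary <- summarize_tad_changes(changes, enh$specific[interval_cols])
    list(changes = changes, summary = summary)
  })

  # ---- targets -------------------------------------------------------
  targets <- stage("targets", {
    de <- differential_expression(inputs$expression, inputs$groups, th)
    tg <- identify_target_genes(loops$annotated, enh$specific[interval_cols],
                                inputs$tss, de, th)
    lrf <- if (nrow(tg) > 0) long_range_fraction(tg, th) else NA_real_
    list(de = de, target_genes = tg, long_range_fraction = lrf)
  })

  report <- structure(list(
    config = config,
    inputs = inputs,
    enhancers = enh,
    profiles = prof,
    loops = loops,
    tads = tads,
    targets = targets,
    counts = list(
      n_specific_enhancers = nrow(enh$specific),
      n_background_specific = nrow(enh$background_specific),
      n_super_enhancers = if (is.null(enh$supers)) 0L else sum(enh$supers$is_super),
      loop_classes = table(loops$annotated$class_label),
      tad_category_counts = stats::setNames(tads$summary$n,
                                            as.character(tads$summary$category)),
      n_de_up = sum(targets$de$direction == "up"),
      n_de_down = sum(targets$de$direction == "down"),
      n_target_genes = nrow(targets$target_genes),
      long_range_fraction = targets$long_range_fraction
    ),
    version = as.character(utils::packageVersion("cregnet"))
  ), class = "cregnet_report")

  if (!is.null(config$out_dir)) write_report_artifacts(report, config$out_dir)
  report
}

#' @export
print.cregnet_report <- function(x, ...) {
  ct <- x$counts
  cat("cregnet pipeline report\n")
  cat(sprintf("  specific enhancers:            %d (background-specific: %d)\n",
              ct$n_specific_enhancers, ct$n_background_specific))
  cat(sprintf("  super enhancers:               %d\n", ct$n_super_enhancers))
  cat(sprintf("  loops (specific/nonspec/other): %s\n",
              paste(ct$loop_classes, collapse = "/")))
  tc <- ct$tad_category_counts
  cat(sprintf("  TAD changes:                   %s\n",
              paste(sprintf("%s=%d", names(tc), tc), collapse = " ")))
  cat(sprintf("  DE genes up/down:              %d/%d\n", ct$n_de_up, ct$n_de_down))
  cat(sprintf("  target genes:                  %d (long-range fraction %.3f)\n",
              ct$n_target_genes, ct$long_range_fraction))
  invisible(x)
}

write_report_artifacts <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  enh <- report$enhancers
  write_intervals(enh$specific, p("specific_enhancers.bed"), "bed")
  write_intervals(enh$background_specific, p("background_specific_enhancers.bed"), "bed")
  if (!is.null(enh$supers)) {
    readr::write_tsv(tibble::as_tibble(enh$supers), p("super_enhancers.tsv"))
  }
  if (!is.null(report$profiles)) {
    write_density_matrix(report$profiles$density, p("density_matrix.tsv"))
    if (requireNamespace("ape", quietly = TRUE)) {
      write_dendrogram_newick(report$profiles$hclust, p("sample_dendrogram.nwk"))
    }
  }
  write_annotated_bedpe(report$loops$annotated, p("annotated_loops.bedpe"))
  readr::write_tsv(report$loops$span_comparison$proportions, p("span_distribution.tsv"))
  write_tad_changes_bed(report$tads$changes, p("tad_changes.bed"))
  readr::write_tsv(report$tads$summary, p("tad_summary.tsv"))
  readr::write_tsv(report$targets$de, p("differential_expression.tsv"))
  if (nrow(report$targets$target_genes) > 0) {
    readr::write_tsv(dplyr::select(report$targets$target_genes,
                                   -"supporting_loops"),
                     p("target_genes.tsv"))
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    ct <- report$counts
    jsonlite::write_json(
      list(version = report$version,
           counts = list(
             n_specific_enhancers = ct$n_specific_enhancers,
             n_background_specific = ct$n_background_specific,
             n_super_enhancers = ct$n_super_enhancers,
             loop_classes = as.list(ct$loop_classes),
             tad_category_counts = as.list(ct$tad_category_counts),
             n_de_up = ct$n_de_up, n_de_down = ct$n_de_down,
             n_target_genes = ct$n_target_genes,
             long_range_fraction = ct$long_range_fraction)),
      p("report.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}
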