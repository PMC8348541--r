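validate_tads <- function(x, arg = "tads", tol = 0) {
  validate_intervals(x, arg)
  x <- sort_intervals(tibble::as_tibble(x[interval_cols]))
  if (nrow(x) > 1) {
    same <- x$chrom[-1] == x$chrom[-nrow(x)]
    ov <- x$end[-nrow(x)] - x$start[-1]
    bad <- which(same & ov > tol)
    if (length(bad) > 0) {
      i <- bad[1]
      abort_usage(sprintf(
        "`%s`: overlapping domains %s:%s-%s and %s:%s-%s (overlap %s bp beyond tolerance)",
        arg, x$chrom[i], x$start[i], x$end[i],
        x$chrom[i + 1], x$start[i + 1], x$end[i + 1], ov[i]))
    }
  }
  x
}

tad_categories <- c("unchanged", "expand", "narrow", "fusion", "split",
                    "appear", "disappear", "complex")
changed_categories <- c("expand", "narrow", "fusion", "split", "appear",
                        "disappear")

#' Classify TAD boundary changes between two conditions
#'
#' Matches the domains of two TAD segmentations (e.g. normal colon vs
#' colorectal cancer) and classifies every matched group into one of six
#' boundary-change categories plus `unchanged` and `complex`:
#'
#' * `expand` / `narrow` — a one-to-one match whose boundaries moved by
#'   more than `boundary_tol`, with the condition-2 domain respectively
#'   at least as long / shorter than its condition-1 partner;
#' * `fusion` — two or more condition-1 domains matched to a single
#'   condition-2 domain;
#' * `split` — one condition-1 domain matched to two or more condition-2
#'   domains;
#' * `appear` / `disappear` — a domain present only in condition 2 /
#'   only in condition 1;
#' * `unchanged` — one-to-one with both boundary displacements within
#'   `boundary_tol`;
#' * `complex` — many-to-many components, reported separately and
#'   excluded from the six-category fractions.
#'
#' Matching builds, per chromosome, a bipartite graph joining domains of
#' the two conditions whose overlap is at least `min_overlap_frac` times
#' the length of the shorter of the two; connected components partition
#' all domains.
#'
#' @param normal TAD tibble (`chrom`, `start`, `end`) for condition 1.
#' @param cancer TAD tibble for condition 2.
#' @param boundary_tol Boundary-displacement tolerance in bp (default
#'   40000, about one Hi-C bin).
#' @param min_overlap_frac Minimum overlap, as a fraction of the shorter
#'   domain, for a match edge (default 0.1).
#' @return An object of class `tad_changes`: a tibble with one row per
#'   component: `change_id`, `chrom`, `category`, `n_normal`, `n_cancer`,
#'   footprint bounds (`start`, `end`) and list-columns `normal_members`,
#'   `cancer_members` holding the member domains.
#' @export
classify_tad_changes <- function(normal, cancer, boundary_tol = 40000,
                                 min_overlap_frac = 0.1) {
  normal <- validate_tads(normal, "normal")
  cancer <- validate_tads(cancer, "cancer")
  if (boundary_tol < 0) abort_usage("`boundary_tol` must be >= 0")
  if (min_overlap_frac <= 0 || min_overlap_frac > 1) {
    abort_usage("`min_overlap_frac` must be in (0, 1]")
  }

  pairs <- overlap_pairs_tbl(normal, cancer)
  if (nrow(pairs) > 0) {
    len_n <- normal$end[pairs$query] - normal$start[pairs$query]
    len_c <- cancer$end[pairs$subject] - cancer$start[pairs$subject]
    keep <- pairs$overlap_bp >= pmax(1, min_overlap_frac * pmin(len_n, len_c))
    pairs <- pairs[keep, , drop = FALSE]
  }

  vn <- paste0("n", seq_len(nrow(normal)))
  vc <- paste0("c", seq_len(nrow(cancer)))
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c(vn, vc))
  if (nrow(pairs) > 0) {
    g <- igraph::add_edges(g, rbind(vn[pairs$query], vc[pairs$subject]))
  }
  comp <- igraph::components(g)$membership

  members <- split(names(comp), comp)
  rows <- purrr::imap(members, function(vs, id) {
    ni <- as.integer(sub("^n", "", vs[startsWith(vs, "n")]))
    ci <- as.integer(sub("^c", "", vs[startsWith(vs, "c")]))
    nm <- normal[ni, , drop = FALSE]
    cm <- cancer[ci, , drop = FALSE]
    k <- nrow(nm); m <- nrow(cm)
    category <- if (k == 0 && m == 1) "appear"
    else if (k == 1 && m == 0) "disappear"
    else if (k >= 2 && m == 1) "fusion"
    else if (k == 1 && m >= 2) "split"
    else if (k == 1 && m == 1) {
      disp <- max(abs(nm$start - cm$start), abs(nm$end - cm$end))
      if (disp <= boundary_tol) "unchanged"
      else if ((cm$end - cm$start) >= (nm$end - nm$start)) "expand"
      else "narrow"
    } else "complex"
    all_m <- dplyr::bind_rows(nm, cm)
    tibble::tibble(
      chrom = all_m$chrom[1],
      category = category,
      n_normal = k, n_cancer = m,
      start = min(all_m$start), end = max(all_m$end),
      normal_members = list(nm), cancer_members = list(cm)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$end)
  out$change_id <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "change_id")
  out$category <- factor(out$category, levels = tad_categories)
  attr(out, "boundary_tol") <- boundary_tol
  attr(out, "min_overlap_frac") <- min_overlap_frac
  class(out) <- c("tad_changes", class(out))
  out
}

change_footprint <- function(changes) {
  # footprint used for enhancer containment: cancer members; for
  # disappeared domains the normal members (the cancer side is empty)
  purrr::map2(changes$cancer_members, changes$normal_members, function(cm, nm) {
    if (nrow(cm) > 0) cm else nm
  })
}

#' Summarize TAD changes and enhancer-containing fractions
#'
#' Counts changes per category, the fraction each of the six change
#' categories represents among all changed domains (`unchanged` and
#' `complex` excluded from the denominator), and the fraction of each
#' category's changes whose footprint contains (overlaps by >= 1 bp) at
#' least one specific enhancer. The footprint of a change is the union
#' of its cancer-side domains (normal-side for disappearances).
#'
#' @param changes Result of [classify_tad_changes()].
#' @param specific_enhancers Interval tibble of specific enhancers.
#' @return A tibble (`category`, `n`, `fraction_of_changed`,
#'   `enhancer_fraction`), with `fraction_of_changed` defined only for
#'   the six change categories (`NA` elsewhere, and `NA` throughout when
#'   no domain changed). Attributes: `n_changed`, `n_total`,
#'   `domain_changed_fraction` (changed plus complex over all
#'   components) and `boundary_turnover` (fraction of condition-1
#'   boundary positions not reproduced within the classifier tolerance).
#' @export
summarize_tad_changes <- function(changes, specific_enhancers) {
  validate_intervals(specific_enhancers, "specific_enhancers")
  cat_chr <- as.character(changes$category)
  changed <- cat_chr %in% changed_categories
  n_changed <- sum(changed)
  if (n_changed == 0) {
    rlang::warn("no changed domains: fractions undefined")
  }

  feet <- change_footprint(changes)
  has_enh <- vapply(feet, function(f) {
    nrow(f) > 0 && any(overlaps_any(f, specific_enhancers))
  }, logical(1))

  out <- tibble::tibble(category = factor(tad_categories, levels = tad_categories)) |>
    dplyr::mutate(
      n = vapply(tad_categories, function(ct) sum(cat_chr == ct), integer(1),
                 USE.NAMES = FALSE),
      fraction_of_changed = dplyr::if_else(
        .data$category %in% changed_categories & n_changed > 0,
        .data$n / n_changed, NA_real_),
      enhancer_fraction = vapply(tad_categories, function(ct) {
        idx <- cat_chr == ct
        if (!any(idx)) return(NA_real_)
        mean(has_enh[idx])
      }, numeric(1), USE.NAMES = FALSE)
    )

  tol <- attr(changes, "boundary_tol") %||% 40000
  nb <- unique(unlist(purrr::map(changes$normal_members, function(nm) {
    if (nrow(nm) == 0) return(NULL)
    paste(nm$chrom, c(nm$start, nm$end))
  })))
  cbp <- dplyr::bind_rows(changes$cancer_members)
  boundary_turnover <- if (length(nb) == 0) NA_real_ else {
    parts <- strsplit(nb, " ", fixed = TRUE)
    reproduced <- vapply(parts, function(p) {
      pos <- as.numeric(p[2])
      cb <- cbp[cbp$chrom == p[1], , drop = FALSE]
      any(abs(c(cb$start, cb$end) - pos) <= tol)
    }, logical(1))
    mean(!reproduced)
  }

  attr(out, "n_changed") <- n_changed
  attr(out, "n_total") <- nrow(changes)
  attr(out, "domain_changed_fraction") <-
    if (nrow(changes) == 0) NA_real_ else
      sum(cat_chr != "unchanged") / nrow(changes)
  attr(out, "boundary_turnover") <- boundary_turnover
  out
}

#' Write per-domain TAD change classifications as BED
#'
#' One record per member domain, name column carrying
#' `category|condition|change_id`.
#'
#' @param changes Result of [classify_tad_changes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tad_changes_bed <- function(changes, path) {
  rows <- purrr::pmap(list(changes$change_id, as.character(changes$category),
                           changes$normal_members, changes$cancer_members),
                      function(id, ct, nm, cm) {
    dplyr::bind_rows(
      if (nrow(nm) > 0) dplyr::mutate(nm, name = sprintf("%s|normal|%d", ct, id)),
      if (nrow(cm) > 0) dplyr::mutate(cm, name = sprintf("%s|cancer|%d", ct, id))
    )
  }) |> dplyr::bind_rows() |> sort_intervals()
  write_intervals(rows, path, format = "bed")
  invisible(path)
}
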