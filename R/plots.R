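#' Hockey-stick plot of the super-enhancer rank curve
#'
#' Scaled rank against scaled signal with the inflection cutoff marked;
#' regions above the cutoff (super enhancers) are highlighted.
#'
#' @param object A `super_enhancers` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.super_enhancers <- function(object, ...) {
  cutoff <- attr(object, "cutoff_index")
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scaled_rank,
                                   y = .data$scaled_score,
                                   colour = .data$is_super)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = df$scaled_rank[df$rank == cutoff],
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "scaled rank (ascending signal)",
                  y = "scaled stitched signal",
                  colour = "super enhancer",
                  title = sprintf("%d super enhancers of %d stitched regions",
                                  sum(df$is_super), nrow(df))) +
    ggplot2::theme_minimal()
}

#' Barplot of binned loop-span proportions per class
#'
#' @param object A `span_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.span_comparison <- function(object, ...) {
  df <- object$proportions
  df$bin <- factor(sprintf("%s-%s kb", df$bin_lo / 1000, df$bin_hi / 1000),
                   levels = unique(sprintf("%s-%s kb", df$bin_lo / 1000,
                                           df$bin_hi / 1000)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$proportion,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "loop span", y = "proportion of loops",
                  fill = "loop class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Barplot of TAD change categories
#'
#' @param object A `tad_changes` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tad_changes <- function(object, ...) {
  df <- dplyr::count(tidy(object), .data$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "boundary-change category", y = "domains") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' @param de Result of [differential_expression()].
#' @param thresholds The [integration_thresholds()] used (drawn as guide
#'   lines).
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, thresholds = integration_thresholds()) {
  df <- dplyr::mutate(de, neglog_q = -log10(pmax(.data$q_value, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc, y = .data$neglog_q,
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(thresholds$fc_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(thresholds$q_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "navy", ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (cancer / normal)",
                  y = "-log10 q-value", colour = NULL) +
    ggplot2::theme_minimal()
}
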