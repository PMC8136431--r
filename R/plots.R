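# ggplot2 figures for assembled panels and study results.

#' Plot reliability deviations of a study
#'
#' The deviation figure of the evaluation suite: observed-minus-target
#' attribute reliability `D_ik` per attribute, one line per primary pathway,
#' faceted by condition. Points near zero mean the assembled pathways hit
#' the reliability target.
#'
#' @param x A `cdmst_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cdmst_study
#' @export
autoplot.cdmst_study <- function(x, ...) {
  d <- dplyr::summarise(
    dplyr::group_by(x$deviations, .data$condition, .data$pathway,
                    .data$attribute),
    deviation = mean(.data$deviation), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$attribute, y = .data$deviation,
                                  colour = .data$pathway,
                                  group = .data$pathway)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "Attribute", y = "Observed - target reliability",
                  colour = "Pathway") +
    ggplot2::theme_minimal()
}

#' Plot the difficulty profile of assembled panels
#'
#' Item difficulties of every assembled item by pathway and stage, with the
#' bank's difficulty-bin boundaries when available. Shows the intended
#' ordering easy > medium > hard of the primary pathways.
#'
#' @param x A `cdmst_panels`.
#' @param bank The item bank the panels were assembled from.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cdmst_panels
#' @export
autoplot.cdmst_panels <- function(x, bank, ...) {
  d <- dplyr::left_join(tidy(x), bank[c("item_id", "diff")], by = "item_id")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pathway, y = .data$diff,
                                       colour = .data$pathway)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::facet_wrap(~panel, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Module", y = "CD item difficulty") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
  cuts <- attr(bank, "cut_points")
  if (!is.null(cuts)) {
    p <- p + ggplot2::geom_hline(yintercept = cuts[2:3], linetype = 3,
                                 colour = "grey40")
  }
  p
}

#' @rdname autoplot.cdmst_study
#' @param study A `cdmst_study`.
#' @export
plot_reliability_deviation <- function(study, ...) {
  autoplot.cdmst_study(study, ...)
}
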