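#' Volcano plot of a differential-expression table
#'
#' @param de A [differential_expression()] table, optionally already passed
#'   through [classify_volcano()].
#' @param log2fc_cut,p_cut Thresholds used for coloring (defaults 0.38,
#'   0.05); ignored when `de` already has a `regulation` column.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, log2fc_cut = 0.38, p_cut = 0.05) {
  if (!"regulation" %in% names(de)) {
    de <- classify_volcano(de, log2fc_cut = log2fc_cut, p_cut = p_cut)
  }
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                                   colour = .data$regulation)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(up = "#d73027", down = "#4575b4",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (React-30 - NR)",
                  y = expression(-log[10](p)), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Cross-species concordance scatter of integration records
#'
#' Standardized human correlation axis against standardized mouse
#' fold-change axis, colored by direction consistency.
#'
#' @param records Integration records (e.g. a [select_overlap()] result).
#' @return A ggplot object.
#' @export
plot_concordance <- function(records) {
  rec <- records[is.finite(records$human_r) & is.finite(records$mouse_log2fc), ]
  rec$zh <- zscore(rec$human_r, "human axis")
  rec$zm <- zscore(rec$mouse_log2fc, "mouse axis")
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$zh, y = .data$zm,
                                    colour = .data$consistent)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#4575b4",
                                            `FALSE` = "#fdae61")) +
    ggplot2::labs(x = "standardized human correlation",
                  y = "standardized mouse fold change",
                  colour = "consistent") +
    ggplot2::theme_minimal()
}

#' Bootstrap distribution of the mediation indirect effect
#'
#' @param object A [mediation_analysis()] fit.
#' @param ... Unused.
#' @return A ggplot object showing the standardized path estimates with
#'   normal-theory error bars.
#' @export
autoplot.crossmed_mediation <- function(object, ...) {
  pt <- tidy(object, scale = "all")
  ggplot2::ggplot(pt, ggplot2::aes(x = .data$term, y = .data$estimate,
                                   colour = .data$scale)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$estimate - 1.96 * .data$se,
                                          ymax = .data$estimate + 1.96 * .data$se),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "path estimate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
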