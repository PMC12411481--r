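#' Diagnostic plots for the sensitivity analyses
#'
#' Thin ggplot2 wrappers used by the analysis scripts: a tornado diagram
#' for the one-way analysis, the cost-effectiveness plane scatter, and the
#' acceptability curve. ggplot2 is only suggested; the functions error
#' politely when it is unavailable.
#'
#' @param tornado An [owsa()] tibble.
#' @param base_icer Vertical reference line (base-case ICER).
#' @param top_n Number of widest bars to show.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, base_icer = attr(tornado, "base_icer"),
                         top_n = 12) {
  need_ggplot2()
  tor <- utils::head(tornado[tornado$ok, ], top_n)
  tor$id <- factor(tor$id, levels = rev(tor$id))
  ggplot2::ggplot(tor) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$icer_low, xend = .data$icer_high,
      y = .data$id, yend = .data$id), linewidth = 5, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::labs(x = "ICER ($/QALY)", y = NULL,
                  title = "One-way sensitivity analysis")
}

#' @rdname plot_tornado
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay threshold drawn as a line.
#' @export
plot_ce_plane <- function(psa, wtp = psa$wtp) {
  need_ggplot2()
  it <- psa$iterations[stats::complete.cases(psa$iterations), ]
  ggplot2::ggplot(it, ggplot2::aes(.data$delta_qaly, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0) + ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost ($)",
                  title = "Cost-effectiveness plane")
}

#' @rdname plot_tornado
#' @param curve A [ceac()] tibble.
#' @export
plot_ceac <- function(curve, wtp = NULL) {
  need_ggplot2()
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$wtp, .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay ($/QALY)",
                  y = "P(cost-effective)",
                  title = "Cost-effectiveness acceptability curve")
  if (!is.null(wtp)) p <- p + ggplot2::geom_vline(xintercept = wtp, linetype = 2)
  p
}

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}
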