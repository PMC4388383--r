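# Optional ggplot2 figures for the three standard artifacts: CE-plane
# scatter, acceptability curve, and tornado diagram. ggplot2 is a suggested
# dependency; each function errors informatively if it is unavailable.

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  }
}

#' Cost-effectiveness plane scatter plot
#'
#' Incremental HbA1c reduction (x) against incremental cost (y), one point
#' per PSA draw. Positive x favours the intervention's effectiveness;
#' positive y means the intervention costs more.
#'
#' @param psa A [run_psa()] result.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa) {
  .need_ggplot()
  ggplot2::ggplot(psa$draws,
                  ggplot2::aes(x = .data$delta_effect, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Incremental HbA1c reduction (% points)",
                  y = "Incremental cost (USD)",
                  title = sprintf("Cost-effectiveness plane (%d runs)",
                                  psa$n_runs)) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param ceac A data frame from [ceac_curve()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac) {
  .need_ggplot()
  ggplot2::ggplot(ceac, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD per 1% HbA1c reduction)",
                  y = "P(intervention cost-effective)",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' Horizontal bars from the outcome at each input's low bound to the outcome
#' at its high bound, widest first.
#'
#' @param tornado A [one_way_sweep()] result.
#' @param top_k Number of inputs to display (default 10).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top_k = 10) {
  .need_ggplot()
  tw <- utils::head(as.data.frame(tornado), top_k)
  tw$input <- factor(tw$input, levels = rev(tw$input))
  base <- attr(tornado, "base_value")
  ggplot2::ggplot(tw, ggplot2::aes(y = .data$input)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$outcome_at_low,
                                       xend = .data$outcome_at_high,
                                       yend = .data$input),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = attr(tornado, "outcome"), y = NULL,
                  title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}
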