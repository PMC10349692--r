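#' Distribution of the diet indices across a cohort
#'
#' Histograms of the raw or energy-adjusted PDI, hPDI and uPDI.
#'
#' @param scores Output of [score_diet()].
#' @param which `"adj"` (default) or `"raw"`.
#' @return A ggplot object.
#' @export
plot_index_distribution <- function(scores, which = c("adj", "raw")) {
  which <- match.arg(which)
  long <- scores |>
    dplyr::select("participant_id", dplyr::ends_with(paste0("_", which))) |>
    tidyr::pivot_longer(-"participant_id", names_to = "index",
                        values_to = "value") |>
    dplyr::mutate(index = toupper(sub(paste0("_", which, "$"), "",
                                      .data$index)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~index, scales = "free_x") +
    ggplot2::labs(
      x = if (which == "adj") "Energy-adjusted index" else "Raw index",
      y = "Participants"
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of association results
#'
#' Point estimates with 95% confidence intervals for a tidy result table,
#' faceted by outcome and coloured by model tier.
#'
#' @param results Result tibble from [run_cross_sectional()],
#'   [run_longitudinal()] or [stratified_analysis()].
#' @return A ggplot object.
#' @export
plot_associations <- function(results) {
  results <- dplyr::mutate(
    results,
    label = ifelse(is.na(.data$stratum),
                   paste(.data$index, .data$exposure_form),
                   paste(.data$index, .data$stratum))
  )
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$beta, y = .data$label,
                               colour = .data$model)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = "Difference in composite Z-score (95% CI)", y = NULL,
                  colour = "Model") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a single fitted model
#'
#' @param object A `pdi_fit` object.
#' @param ... Unused.
#' @return A ggplot object showing the exposure contrasts with 95% CIs.
#' @method autoplot pdi_fit
#' @export
autoplot.pdi_fit <- function(object, ...) {
  plot_associations(tidy(object)) +
    ggplot2::ggtitle(paste0(object$index, " → ", object$outcome,
                            " (", object$model, ")"))
}
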