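#' Plot a patient's medicine-coverage timeline
#'
#' Covered intervals as horizontal segments over the observation window, with
#' gaps visible as breaks.
#'
#' @param timeline A [build_coverage_timeline()] result.
#' @return A ggplot.
#' @export
plot_coverage_timeline <- function(timeline) {
  stopifnot(inherits(timeline, "coverage_timeline"))
  iv <- timeline$intervals
  ggplot2::ggplot(iv) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_day, xend = .data$end_day, y = 1, yend = 1),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::xlim(0, timeline$window_end_day) +
    ggplot2::scale_y_continuous(breaks = NULL, limits = c(0.5, 1.5)) +
    ggplot2::labs(
      x = "days since ART initiation", y = NULL,
      title = sprintf("%.1f%% of days covered; longest gap %d days",
                      pct_days_covered(timeline), longest_gap(timeline))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the adjusted monthly weight-gain trajectory
#'
#' Population-averaged adjusted weight gain by month since initiation, from a
#' fitted weight model (the month-bin coefficients standardized over the
#' observed covariate distribution).
#'
#' @param model An `adherence_model` of kind `gee_weight` fit with the
#'   month time coding.
#' @param conf.level Confidence level for the ribbons.
#' @return A ggplot.
#' @export
plot_monthly_gain <- function(model, conf.level = 0.95) {
  stopifnot(inherits(model, "adherence_model"), model$kind == "gee_weight")
  months <- sort(unique(as.integer(as.character(model$fit$model$month))))
  rows <- lapply(months, function(m) {
    pr <- adjusted_prediction(model, horizon_day = m * 30L,
                              mode = "population", conf.level = conf.level)
    # average over the indicator's observed distribution: take the
    # population-mode row for each level weighted by its frequency
    x <- model$fit$model[[model$indicator_var]]
    wts <- as.numeric(table(factor(x))[pr$level])
    wts <- wts / sum(wts)
    tibble::tibble(month = m,
                   estimate = sum(pr$estimate * wts),
                   conf.low = sum(pr$conf.low * wts),
                   conf.high = sum(pr$conf.high * wts))
  })
  df <- dplyr::bind_rows(rows)
  ggplot2::ggplot(df, ggplot2::aes(.data$month, .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high), alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = months) +
    ggplot2::labs(x = "month since ART initiation",
                  y = "adjusted weight gain (kg)") +
    ggplot2::theme_minimal()
}

#' Plot adjusted outcome change by adherence level
#'
#' Adjusted (typical-patient or population-averaged) outcome change for each
#' level of the model's adherence indicator, with confidence intervals.
#'
#' @param model An `adherence_model`.
#' @inheritParams adjusted_prediction
#' @return A ggplot.
#' @export
plot_adjusted_gain <- function(model, profile = NULL, horizon_day = 270L,
                               mode = "population") {
  pr <- adjusted_prediction(model, profile = profile,
                            horizon_day = horizon_day, mode = mode)
  pr$level <- factor(pr$level, levels = pr$level)
  ggplot2::ggplot(pr, ggplot2::aes(.data$level, .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                        ymax = .data$conf.high), width = 0.2) +
    ggplot2::labs(
      x = model$indicator,
      y = if (model$kind == "gee_weight") "adjusted weight gain (kg)" else
        "adjusted CD4 gain (cells/mm3)"
    ) +
    ggplot2::theme_minimal()
}
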