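# ggplot2 displays for the diagnostic objects

#' Predicted-versus-observed plot for a fitted model
#'
#' @param object a `gc_fit` object.
#' @param cohort the cohort the model was fitted to.
#' @param type plot population (`PRED`) or individual (`IPRED`)
#'   predictions.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gc_fit <- function(object, cohort, type = c("PRED", "IPRED"), ...) {
  type <- match.arg(type)
  d <- augment(object, cohort)
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[type]], y = .data$DV)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phase), alpha = 0.7) +
    ggplot2::labs(x = paste0(type, " (mg/L)"), y = "Observed (mg/L)",
                  colour = "Phase") +
    ggplot2::theme_bw()
}

#' NPDE diagnostic panels
#'
#' Histogram of the NPDE with the standard-normal density, or NPDE against
#' time after dose / postnatal age.
#'
#' @param object a `gc_npde` object.
#' @param type `"hist"`, `"qq"` or `"time"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gc_npde <- function(object, type = c("hist", "qq", "time"), ...) {
  type <- match.arg(type)
  d <- object$table
  if (type == "hist") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$npde)) +
      ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                              bins = 30, fill = "steelblue",
                              colour = "white") +
      ggplot2::stat_function(fun = dnorm, colour = "black",
                             linetype = 2) +
      ggplot2::labs(x = "NPDE", y = "Density") +
      ggplot2::theme_bw()
  } else if (type == "qq") {
    ggplot2::ggplot(d, ggplot2::aes(sample = .data$npde)) +
      ggplot2::stat_qq(alpha = 0.6) +
      ggplot2::stat_qq_line(linetype = 2) +
      ggplot2::labs(x = "N(0,1) quantiles", y = "NPDE quantiles") +
      ggplot2::theme_bw()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$TIME, y = .data$npde)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$phase), alpha = 0.7) +
      ggplot2::labs(x = "Postnatal age (h)", y = "NPDE", colour = "Phase") +
      ggplot2::theme_bw()
  }
}

#' pcVPC ribbons
#'
#' Observed 5th/50th/95th percentile curves over the simulation-derived
#' 95% confidence bands, with the prediction-corrected observations.
#'
#' @param object a `gc_pcvpc` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gc_pcvpc <- function(object, ...) {
  b <- object$bins
  b$percentile <- factor(b$percentile, levels = c(5, 50, 95))
  xlab <- if (object$bin_on == "time_after_dose")
    "Time after dose (h)" else "Postnatal age (h)"
  ggplot2::ggplot(b, ggplot2::aes(x = .data$bin_mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_low,
                                      ymax = .data$sim_high,
                                      fill = .data$percentile),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    group = .data$percentile,
                                    linetype = .data$percentile)) +
    ggplot2::geom_point(data = object$data,
                        ggplot2::aes(x = .data$x, y = .data$dv),
                        alpha = 0.3, shape = 1) +
    ggplot2::labs(x = xlab, y = "Prediction-corrected concentration (mg/L)",
                  fill = "Percentile", linetype = "Percentile") +
    ggplot2::theme_bw()
}

#' Bias and precision by stratum
#'
#' Point estimates with 95% confidence intervals for MPE and RMSE across
#' the phase-by-level strata.
#'
#' @param object a `gc_pe_table`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gc_pe_table <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("mpe", "rmse"), names_to = "metric", values_to = "estimate")
  d$lo <- ifelse(d$metric == "mpe", d$mpe_low, d$rmse_low)
  d$hi <- ifelse(d$metric == "mpe", d$mpe_high, d$rmse_high)
  d$metric <- toupper(d$metric)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$estimate,
                                  colour = .data$phase)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                             position = ggplot2::position_dodge(0.5)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Concentration stratum", y = "mg/L",
                  colour = "Phase") +
    ggplot2::theme_bw()
}
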