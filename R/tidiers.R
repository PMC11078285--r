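# broom-style tidiers for the fitted objects

#' Tidy a population fit
#'
#' @param x a `gc_fit` object.
#' @param ... unused.
#' @return A tibble with one row per parameter: `parameter`, `estimate`,
#'   `fixed`, and (when available) `se` and `cv_pct`.
#' @export
tidy.gc_fit <- function(x, ...) {
  x$parameters
}

#' @rdname tidy.gc_fit
#' @export
glance.gc_fit <- function(x, ...) {
  tibble::tibble(
    ofv = x$ofv,
    converged = x$converged,
    n_subjects = nrow(x$ebes),
    n_function_evals = x$n_function_evals,
    n_free = sum(!x$parameters$fixed)
  )
}

#' Per-observation predictions for a fitted model
#'
#' Appends population (`PRED`) and individual (`IPRED`) predictions, and
#' their residuals, to the observation records used in the fit.
#'
#' @param x a `gc_fit` object.
#' @param cohort the cohort the model was fitted to.
#' @param ... unused.
#' @export
augment.gc_fit <- function(x, cohort, ...) {
  ph <- gc_posthoc(cohort, x$estimates)
  dplyr::mutate(ph$predictions,
                resid = .data$DV - .data$PRED,
                iresid = .data$DV - .data$IPRED)
}

#' Tidy a bootstrap result
#'
#' @param x a `gc_bootstrap` object.
#' @param ... unused.
#' @return The per-parameter summary: median estimate and percentile
#'   2.5/97.5% interval.
#' @export
tidy.gc_bootstrap <- function(x, ...) {
  x$summary
}

#' @rdname tidy.gc_bootstrap
#' @export
glance.gc_bootstrap <- function(x, ...) {
  tibble::tibble(n_success = x$n_success, n_failed = x$n_failed)
}

#' Tidy an NPDE result
#'
#' @param x a `gc_npde` object.
#' @param ... unused.
#' @return The per-observation NPDE table.
#' @export
tidy.gc_npde <- function(x, ...) {
  x$table
}

#' @rdname tidy.gc_npde
#' @export
glance.gc_npde <- function(x, ...) {
  tibble::tibble(mean = x$mean, variance = x$variance,
                 wilcoxon_p = x$wilcoxon_p, variance_p = x$variance_p,
                 n_obs = nrow(x$table), n_sim = x$n_sim)
}

#' Tidy a pcVPC result
#'
#' @param x a `gc_pcvpc` object.
#' @param ... unused.
#' @return The per-bin percentile table.
#' @export
tidy.gc_pcvpc <- function(x, ...) {
  x$bins
}

#' @rdname tidy.gc_pcvpc
#' @export
glance.gc_pcvpc <- function(x, ...) {
  tibble::tibble(coverage = x$coverage,
                 n_bins = length(unique(x$bins$bin)), n_sim = x$n_sim)
}
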