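#' Draw interindividual random effects
#'
#' Independent normal draws on the log scale: `eta_cl ~ N(0, omega2_cl)`,
#' `eta_vc ~ N(0, omega2_vc)`, `eta_vp ~ N(0, omega2_vp)` and `eta_eps ~
#' N(0, omega2_eps)` (no correlation terms are modelled).
#'
#' @param params a [gc_parameters()] object.
#' @param n number of individuals to draw.
#' @param seed optional integer; when supplied the caller's RNG stream is
#'   left untouched.
#' @return A tibble with columns `eta_cl`, `eta_vc`, `eta_vp`, `eta_eps`.
#' @export
draw_random_effects <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "gc_parameters"), n >= 1)
  with_local_seed(seed, {
    tibble::tibble(
      eta_cl = rnorm(n, 0, sqrt(params$omega2_cl)),
      eta_vc = rnorm(n, 0, sqrt(params$omega2_vc)),
      eta_vp = rnorm(n, 0, sqrt(params$omega2_vp)),
      eta_eps = rnorm(n, 0, sqrt(params$omega2_eps))
    )
  })
}

#' Apply residual error to predicted concentrations
#'
#' The residual model is additive with an individual log-normal scale
#' factor: `DV = pred + sigma_add * exp(eta_eps) * epsilon`,
#' `epsilon ~ N(0, 1)`, so the individual residual SD is
#' `sigma_add * exp(eta_eps)`.
#'
#' @param conc_pred predicted concentrations, mg/L.
#' @param params a [gc_parameters()] object.
#' @param eta_eps individual residual-scale deviation (log scale).
#' @param seed optional integer seed.
#' @return Simulated observed concentrations, mg/L (possibly negative; see
#'   [truncate_negative()]).
#' @export
apply_residual_error <- function(conc_pred, params, eta_eps = 0,
                                 seed = NULL) {
  if (any(conc_pred < 0)) stop("`conc_pred` must be >= 0", call. = FALSE)
  with_local_seed(seed, {
    conc_pred + params$sigma_add * exp(eta_eps) * rnorm(length(conc_pred))
  })
}

#' Truncation policy for negative simulated concentrations
#'
#' Simulated observations below zero are kept by default: the rank-based
#' distribution-error diagnostics need the untruncated residual
#' distribution.  Truncation at zero is available for display and
#' dosing-evaluation purposes.
#'
#' @param conc simulated concentrations, mg/L.
#' @param truncate logical; truncate negative values to 0?
#' @return `conc`, truncated when requested.
#' @export
truncate_negative <- function(conc, truncate = TRUE) {
  if (truncate) pmax(conc, 0) else conc
}

#' Simulation settings
#'
#' @param n_replicates number of Monte-Carlo replicates (the validation
#'   diagnostics use 1000).
#' @param seed master integer seed; per-subject streams are derived from it
#'   so that subject order does not affect the draws.
#' @param include_residual simulate residual error on top of the
#'   interindividual variability?
#' @param truncate_negative truncate negative simulated concentrations to 0?
#' @return A list of class `gc_sim_spec`.
#' @export
gc_sim_spec <- function(n_replicates = 1000, seed = NULL,
                        include_residual = TRUE,
                        truncate_negative = FALSE) {
  stopifnot(n_replicates >= 1)
  structure(list(n_replicates = as.integer(n_replicates), seed = seed,
                 include_residual = include_residual,
                 truncate_negative = truncate_negative),
            class = "gc_sim_spec")
}

# internal: replicate matrix (n_replicates x n_obs) for one subject list
# as produced by cohort_subjects(); fresh etas and residuals per replicate
simulate_subject_core <- function(s, params, spec) {
  n_rep <- spec$n_replicates
  n_obs <- length(s$times)
  if (n_obs < 1) stop("subject has no observation times", call. = FALSE)
  if (length(s$dose_start) == 0)
    warning("subject ", s$id, " has no doses; predictions are all zero",
            call. = FALSE)
  seed_i <- if (is.null(spec$seed)) NULL else subject_seed(spec$seed, s$id)
  with_local_seed(seed_i, {
    eta <- draw_random_effects(params, n_rep)
    tv <- subject_tv_row(params, s)
    conc <- cpp_conc_batch(s$times, s$dose_start, s$dose_amt, s$dose_dur,
                           tv$cl * exp(eta$eta_cl),
                           tv$vc * exp(eta$eta_vc),
                           tv$q,
                           tv$vp * exp(eta$eta_vp),
                           params$theta_sd5, DAY5_CUTOFF_H)
    if (spec$include_residual) {
      sd_i <- params$sigma_add * exp(eta$eta_eps)
      conc <- conc + matrix(rnorm(n_rep * n_obs), n_rep, n_obs) * sd_i
    }
    if (spec$truncate_negative) conc[conc < 0] <- 0
    conc
  })
}

#' Simulate replicate observation vectors for one subject
#'
#' Each replicate draws fresh random effects and (optionally) residual
#' errors and evaluates the subject's own design: same doses, covariates
#' and observation times.
#'
#' @param subject one element of the list returned by the internal cohort
#'   splitter, or a list with fields `id`, `bw`, `ga`, `times`,
#'   `dose_start`, `dose_amt`, `dose_dur`.
#' @param params a [gc_parameters()] object.
#' @param spec a [gc_sim_spec()].
#' @return A matrix of simulated concentrations, `n_replicates` rows by
#'   `length(subject$times)` columns.
#' @export
simulate_subject <- function(subject, params, spec = gc_sim_spec()) {
  simulate_subject_core(subject, params, spec)
}

# internal: list of per-subject replicate matrices for a cohort
simulate_cohort_matrices <- function(cohort, params, spec) {
  subs <- cohort_subjects(cohort)
  out <- lapply(subs, simulate_subject_core, params = params, spec = spec)
  names(out) <- vapply(subs, function(s) as.character(s$id), character(1))
  out
}

#' Simulate a cohort under the model
#'
#' Monte-Carlo simulation of every subject's design.  Returns a long tibble
#' suitable for plotting or summarising; the validation diagnostics use the
#' same engine internally.
#'
#' @param cohort an event-record cohort.
#' @param params a [gc_parameters()] object.
#' @param spec a [gc_sim_spec()].
#' @return A tibble with columns `ID`, `TIME`, `replicate`, `sim` (mg/L).
#' @export
gc_simulate <- function(cohort, params, spec = gc_sim_spec()) {
  subs <- cohort_subjects(cohort)
  mats <- lapply(subs, simulate_subject_core, params = params, spec = spec)
  purrr::map2_dfr(subs, mats, function(s, m) {
    tibble::tibble(
      ID = s$id,
      TIME = rep(s$times, each = nrow(m)),
      replicate = rep(seq_len(nrow(m)), times = length(s$times)),
      sim = as.vector(m)
    )
  })
}
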