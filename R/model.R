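#' Typical (population) structural parameters from covariates
#'
#' Evaluates the covariate model: allometric scaling of all four structural
#' parameters to body weight (exponent 0.75 on clearances, 1 on volumes),
#' a gestational-age power term on clearance, and the multiplicative day-5
#' clearance factor applied when `sd5 = 1`.
#'
#' @param params a [gc_parameters()] object.
#' @param bw body weight, kg (vectorised).
#' @param ga gestational age, completed weeks (vectorised).
#' @param sd5 0/1 indicator for study day 5, i.e. postnatal age > 96 h at
#'   the prediction time (vectorised).
#' @return A tibble with columns `cl`, `vc`, `q`, `vp` (absolute units:
#'   L/h and L).
#' @examples
#' typical_values(gc_parameters(), bw = 3.5, ga = 40, sd5 = 0)
#' @export
typical_values <- function(params, bw, ga, sd5 = 0) {
  stopifnot(inherits(params, "gc_parameters"))
  n <- max(length(bw), length(ga), length(sd5))
  bw <- rep_len(bw, n); ga <- rep_len(ga, n); sd5 <- rep_len(sd5, n)
  if (any(!is.finite(bw)) || any(bw <= 0))
    stop("`bw` must be finite and > 0", call. = FALSE)
  if (any(!is.finite(ga)) || any(ga <= 0))
    stop("`ga` must be finite and > 0", call. = FALSE)
  if (!all(sd5 %in% c(0, 1)))
    stop("`sd5` must be 0 or 1", call. = FALSE)
  fsize <- bw / KG_REF
  cl <- params$cl_pop * fsize^0.75 * params$theta_sd5^sd5 *
    (ga / params$ga_median)^params$theta_cl_ga
  out <- tibble::tibble(
    cl = cl,
    vc = params$vc_pop * fsize,
    q = params$q_pop * fsize^0.75,
    vp = params$vp_pop * fsize
  )
  if (any(!is.finite(unlist(out))))
    stop("non-finite typical value; check covariates", call. = FALSE)
  out
}

#' Individual structural parameters from random effects
#'
#' Applies log-normal interindividual variability to the typical values:
#' `cl_i = cl * exp(eta_cl)` and likewise for `vc` and `vp`.  The
#' intercompartmental clearance `q` carries no random effect.
#'
#' @param tv a data frame with columns `cl`, `vc`, `q`, `vp` (typical
#'   values, as returned by [typical_values()]).
#' @param eta_cl,eta_vc,eta_vp random-effect deviations on the log scale.
#' @return A tibble with the same columns, individualised.
#' @export
individual_parameters <- function(tv, eta_cl = 0, eta_vc = 0, eta_vp = 0) {
  stopifnot(all(c("cl", "vc", "q", "vp") %in% names(tv)))
  if (any(!is.finite(c(eta_cl, eta_vc, eta_vp))))
    stop("random effects must be finite", call. = FALSE)
  tibble::tibble(
    cl = tv$cl * exp(eta_cl),
    vc = tv$vc * exp(eta_vc),
    q = tv$q,
    vp = tv$vp * exp(eta_vp)
  )
}

#' Predict gentamicin concentrations for a multi-infusion schedule
#'
#' Analytic solution of the linear two-compartment model with zero-order
#' infusion input, evaluated by exact state propagation between input
#' breakpoints (so overlapping infusions and the piecewise day-5 clearance
#' step are handled by timeline segmentation with amount carry-over, not by
#' superposition tricks).  A degenerate repeated eigenvalue (alpha = beta)
#' is handled by the exact limiting form of the matrix exponential, so no
#' ODE fallback is needed.
#'
#' @param structural a one-row data frame (or list) with `cl`, `vc`, `q`,
#'   `vp` in L/h and L — individual or typical values at `sd5 = 0`.
#' @param doses a data frame with columns `start_time` (h postnatal age),
#'   `amount` (mg) and `duration` (h).
#' @param times observation times, h postnatal age, sorted ascending.
#' @param cl_day5_factor multiplicative clearance factor applied for
#'   `t > day5_time`; use `params$theta_sd5` for the published model or 1
#'   for a time-constant clearance.
#' @param day5_time postnatal age (h) of the clearance step; the boundary
#'   itself belongs to the pre-step period.
#' @return Numeric vector of concentrations, mg/L.
#' @examples
#' tv <- typical_values(gc_parameters(), bw = 3.4, ga = 40)
#' doses <- data.frame(start_time = 6, amount = 13.6, duration = 0.5)
#' predict_concentration(tv, doses, times = c(6.5, 12, 24))
#' @export
predict_concentration <- function(structural, doses, times,
                                  cl_day5_factor = 1,
                                  day5_time = DAY5_CUTOFF_H) {
  check_doses(doses)
  if (is.unsorted(times)) stop("`times` must be sorted ascending", call. = FALSE)
  if (any(times < 0)) stop("`times` must be >= 0", call. = FALSE)
  cpp_conc(as.numeric(times),
           as.numeric(doses$start_time), as.numeric(doses$amount),
           as.numeric(doses$duration),
           structural$cl[[1]], structural$vc[[1]],
           structural$q[[1]], structural$vp[[1]],
           cl_day5_factor, day5_time)
}

check_doses <- function(doses) {
  stopifnot(is.data.frame(doses),
            all(c("start_time", "amount", "duration") %in% names(doses)))
  if (nrow(doses) > 0 &&
      (any(doses$amount <= 0) || any(doses$duration <= 0) ||
       any(doses$start_time < 0)))
    stop("doses need amount > 0, duration > 0, start_time >= 0",
         call. = FALSE)
  invisible(doses)
}

#' Typical clearance as a function of postnatal age
#'
#' Clearance is constant throughout hypothermia and rewarming and steps up
#' by the day-5 factor once normothermia is re-established (postnatal age
#' > 96 h; the 96 h boundary itself belongs to the pre-step period).
#'
#' @param params a [gc_parameters()] object.
#' @param bw body weight, kg.
#' @param ga gestational age, weeks.
#' @param times postnatal ages, h.
#' @return A tibble with columns `time` and `cl` (L/h).
#' @export
clearance_time_profile <- function(params, bw, ga, times) {
  if (any(times < 0)) stop("`times` must be >= 0", call. = FALSE)
  sd5 <- as.integer(times > DAY5_CUTOFF_H)
  tv <- typical_values(params, bw = bw, ga = ga, sd5 = sd5)
  tibble::tibble(time = times, cl = tv$cl)
}

#' Phase of controlled therapeutic hypothermia at a postnatal age
#'
#' 0–72 h is the hypothermic phase (the 72 h boundary included), 72–96 h
#' rewarming, beyond 96 h normothermia.
#'
#' @param time_h postnatal age, hours (vectorised).
#' @return Factor with levels `hypothermia`, `rewarming`, `normothermia`.
#' @examples
#' phase_of(c(50, 80, 120))
#' @export
phase_of <- function(time_h) {
  if (any(!is.finite(time_h)) || any(time_h < 0))
    stop("`time_h` must be finite and >= 0", call. = FALSE)
  cut(time_h, breaks = c(-Inf, 72, 96, Inf),
      labels = c("hypothermia", "rewarming", "normothermia"),
      right = TRUE)
}

#' Population predictions for every observation in a cohort
#'
#' Computes PRED — the model prediction with all random effects at zero —
#' for each observation record, under locked population parameters (the
#' estimation-free prediction mode).
#'
#' @param cohort an event-record cohort (see [generate_cohort()] or
#'   [read_pk_dataset()]).
#' @param params a [gc_parameters()] object.
#' @return The observation rows of `cohort` with a `PRED` column appended.
#' @export
gc_predict <- function(cohort, params) {
  subs <- cohort_subjects(cohort)
  obs <- dplyr::filter(cohort, .data$EVID == 0)
  pred <- purrr::map(subs, function(s) {
    tv <- subject_tv_row(params, s)
    cpp_conc(s$times, s$dose_start, s$dose_amt, s$dose_dur,
             tv$cl, tv$vc, tv$q, tv$vp, params$theta_sd5, DAY5_CUTOFF_H)
  })
  obs$PRED <- unlist(pred, use.names = FALSE)
  obs
}
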