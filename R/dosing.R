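#' Recommended empiric gentamicin regimen by gestational age
#'
#' The model-derived empiric algorithm for cooled neonates: 5 mg/kg every
#' 36 h for gestational ages 36-41 weeks and 5 mg/kg every 24 h at 42
#' weeks, as 30-minute infusions.  Outside 36-42 weeks the model was not
#' validated and an error is raised.
#'
#' @param ga gestational age, completed weeks.
#' @return A one-row tibble of class `gc_regimen`: `dose_per_kg`,
#'   `interval`, `infusion_duration` (h).
#' @examples
#' recommend_regimen(38)   # q36h
#' recommend_regimen(42)   # q24h
#' @export
recommend_regimen <- function(ga) {
  stopifnot_scalar_num(ga, "ga")
  if (ga < 36 || ga > 42)
    stop("regimen recommendation covers GA 36-42 weeks only", call. = FALSE)
  out <- tibble::tibble(
    dose_per_kg = 5,
    interval = if (ga <= 41) 36 else 24,
    infusion_duration = 0.5
  )
  class(out) <- c("gc_regimen", class(out))
  out
}

#' Build a custom regimen
#'
#' @param dose_per_kg dose, mg/kg.
#' @param interval dosing interval, h.
#' @param infusion_duration infusion length, h.
#' @param n_doses number of doses to simulate.
#' @return A one-row tibble of class `gc_regimen`.
#' @export
gc_regimen <- function(dose_per_kg, interval, infusion_duration = 0.5,
                       n_doses = NULL) {
  stopifnot(dose_per_kg > 0, interval > 0, infusion_duration > 0)
  out <- tibble::tibble(dose_per_kg = dose_per_kg, interval = interval,
                        infusion_duration = infusion_duration)
  if (!is.null(n_doses)) out$n_doses <- n_doses
  class(out) <- c("gc_regimen", class(out))
  out
}

#' Peak/trough targets for regimen evaluation
#'
#' Default targets (peak 8-12 mg/L at end of infusion, trough below
#' 1 mg/L) reflect routine gentamicin therapeutic drug monitoring
#' practice; they are configuration, not model estimates.
#'
#' @param peak_range acceptable peak window, mg/L.
#' @param trough_limit upper trough limit, mg/L.
#' @return A list of class `gc_targets`.
#' @export
gc_targets <- function(peak_range = c(8, 12), trough_limit = 1) {
  stopifnot(length(peak_range) == 2, peak_range[1] < peak_range[2],
            trough_limit > 0)
  structure(list(peak_range = peak_range, trough_limit = trough_limit),
            class = "gc_targets")
}

#' Evaluate a dosing regimen by simulation
#'
#' Simulates virtual cooled neonates on the given regimen (covariates
#' drawn from the cohort design; interindividual variability and,
#' optionally, residual error included), and reports per-interval peak and
#' trough statistics with target-attainment fractions and Monte-Carlo
#' standard errors.  Peaks are reported both at the end of the infusion
#' and 0.5 h later (post-distribution sampling conventions differ);
#' troughs are taken immediately before the next dose.  Negative simulated
#' concentrations are truncated at zero for these displays.
#'
#' @param regimen a [gc_regimen()] or [recommend_regimen()] row.
#' @param params a [gc_parameters()] object.
#' @param design a [gc_design()] supplying the covariate distributions.
#' @param targets a [gc_targets()].
#' @param n_subjects number of virtual subjects.
#' @param n_doses number of doses simulated (default covers the day-5
#'   clearance step plus one interval).
#' @param include_residual add residual error to the sampled peaks and
#'   troughs?
#' @param seed integer seed.
#' @return A list of class `gc_dosing`: `summary` (per-interval tibble)
#'   and `subjects` (per-subject per-interval peaks and troughs).
#' @export
evaluate_regimen <- function(regimen, params, design = gc_design("external"),
                             targets = gc_targets(), n_subjects = 500,
                             n_doses = NULL, include_residual = FALSE,
                             seed = NULL) {
  stopifnot(inherits(regimen, "gc_regimen"))
  n_doses <- n_doses %||%
    (if ("n_doses" %in% names(regimen)) regimen$n_doses else NULL) %||%
    (ceiling((DAY5_CUTOFF_H + regimen$interval) / regimen$interval) + 1)
  with_local_seed(seed, {
    ga_lv <- seq(design$ga_range[1], design$ga_range[2])
    ga <- sample(ga_lv, n_subjects, replace = TRUE,
                 prob = dnorm(ga_lv, params$ga_median, 1.4))
    bw <- rtruncnorm1(n_subjects, design$bw_mean, design$bw_sd,
                      design$bw_range[1], design$bw_range[2])
    eta <- draw_random_effects(params, n_subjects)
    t0 <- runif(n_subjects, design$first_dose_pna[1],
                design$first_dose_pna[2])
    per_subj <- purrr::map_dfr(seq_len(n_subjects), function(i) {
      starts <- t0[i] + regimen$interval * (0:(n_doses - 1))
      peak_t <- starts + regimen$infusion_duration
      peak2_t <- peak_t + 0.5
      trough_t <- starts + regimen$interval
      tt <- sort(unique(c(peak_t, peak2_t, trough_t)))
      tv <- typical_values(params, bw = bw[i], ga = ga[i], sd5 = 0)
      ind <- individual_parameters(tv, eta$eta_cl[i], eta$eta_vc[i],
                                   eta$eta_vp[i])
      conc <- predict_concentration(
        ind, tibble::tibble(start_time = starts,
                            amount = regimen$dose_per_kg * bw[i],
                            duration = regimen$infusion_duration),
        tt, cl_day5_factor = params$theta_sd5)
      if (include_residual)
        conc <- apply_residual_error(conc, params, eta$eta_eps[i])
      conc <- truncate_negative(conc)
      tibble::tibble(
        ID = i, interval = seq_len(n_doses),
        trough_time = trough_t,
        phase = phase_of(trough_t),
        peak = conc[match(peak_t, tt)],
        peak_post = conc[match(peak2_t, tt)],
        trough = conc[match(trough_t, tt)]
      )
    })
    summary <- per_subj |>
      dplyr::group_by(.data$interval, .data$phase) |>
      dplyr::summarise(
        n = dplyr::n(),
        peak_median = median(.data$peak),
        peak_post_median = median(.data$peak_post),
        trough_median = median(.data$trough),
        peak_in_range = mean(.data$peak >= targets$peak_range[1] &
                               .data$peak <= targets$peak_range[2]),
        trough_below = mean(.data$trough < targets$trough_limit),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        peak_in_range_se = sqrt(.data$peak_in_range *
                                  (1 - .data$peak_in_range) / .data$n),
        trough_below_se = sqrt(.data$trough_below *
                                 (1 - .data$trough_below) / .data$n)
      )
    structure(list(summary = summary, subjects = per_subj,
                   regimen = regimen, targets = targets),
              class = "gc_dosing")
  })
}

#' @export
print.gc_dosing <- function(x, ...) {
  cat(sprintf("<gc_dosing> %g mg/kg q%gh, %d virtual subjects\n",
              x$regimen$dose_per_kg, x$regimen$interval,
              length(unique(x$subjects$ID))))
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}
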