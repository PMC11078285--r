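#' Design of a synthetic neonatal gentamicin cohort
#'
#' Describes the trial design the generator emulates: (near) term neonates
#' under controlled therapeutic hypothermia receiving 4 mg/kg gentamicin as
#' 30-minute infusions every 24 h, with sparse arterial sampling
#' concentrated in the hypothermic phase (days 2–3) and thinning out over
#' rewarming (day 4) and normothermia (day 5).  Two sampling profiles are
#' provided: `"external"` (about 80% of samples during hypothermia, median
#' 8 samples per subject, 39 subjects) and `"model_building"` (about 63%
#' during hypothermia, median 14 samples, 47 subjects).
#'
#' @param profile sampling profile, `"external"` or `"model_building"`.
#' @param n_subjects number of neonates (profile default: 39 or 47).
#' @param ga_range completed gestational weeks, inclusive.
#' @param bw_mean,bw_sd,bw_range truncated-normal birth-weight model, kg.
#' @param dose_per_kg maintenance dose, mg/kg.
#' @param dose_interval dosing interval, h.
#' @param infusion_duration infusion length, h.
#' @param first_dose_pna range (h postnatal age) of the uniformly drawn
#'   first dose time.
#' @param treatment_days support of the treatment-duration draw, days
#'   (0 days = a single dose).
#' @param treatment_days_prob probabilities for `treatment_days`.
#' @param sampling_hypo,sampling_late nominal sampling grids (h postnatal
#'   age) for the hypothermic (0–72 h) and later (>72 h) windows.
#' @param hypo_fraction target fraction of samples in the hypothermic
#'   phase.
#' @param samples_range per-subject sample-count range.
#' @param samples_mode centre of the per-subject sample-count draw.
#' @param truncate_dv truncate negative simulated observations to 0?  The
#'   default keeps them: the generated values are model realisations, and
#'   the rank-based validation diagnostics assume the untruncated residual
#'   distribution.  Set `TRUE` for display-realistic datasets (a real assay
#'   would report such samples as below the quantification limit).
#' @return A list of class `gc_design`.
#' @export
gc_design <- function(profile = c("external", "model_building"),
                      n_subjects = NULL,
                      ga_range = c(36, 42),
                      bw_mean = 3.3, bw_sd = 0.5, bw_range = c(2.09, 5.07),
                      dose_per_kg = 4.0, dose_interval = 24,
                      infusion_duration = 0.5,
                      first_dose_pna = c(2, 12),
                      treatment_days = NULL, treatment_days_prob = NULL,
                      sampling_hypo = c(24, 30, 36, 42, 48, 54, 60, 66, 72),
                      sampling_late = c(78, 84, 96, 102, 108, 120),
                      hypo_fraction = NULL,
                      samples_range = NULL, samples_mode = NULL,
                      truncate_dv = FALSE) {
  profile <- match.arg(profile)
  ext <- profile == "external"
  d <- list(
    profile = profile,
    n_subjects = n_subjects %||% (if (ext) 39L else 47L),
    ga_range = ga_range,
    bw_mean = bw_mean, bw_sd = bw_sd, bw_range = bw_range,
    dose_per_kg = dose_per_kg, dose_interval = dose_interval,
    infusion_duration = infusion_duration,
    first_dose_pna = first_dose_pna,
    treatment_days = treatment_days %||% (if (ext) 0:4 else 0:5),
    treatment_days_prob = treatment_days_prob %||%
      (if (ext) c(0.20, 0.30, 0.25, 0.15, 0.10)
       else c(0.12, 0.20, 0.30, 0.20, 0.12, 0.06)),
    sampling_hypo = sampling_hypo,
    sampling_late = sampling_late,
    hypo_fraction = hypo_fraction %||% (if (ext) 0.80 else 0.63),
    samples_range = samples_range %||% (if (ext) c(2, 15) else c(4, 16)),
    samples_mode = samples_mode %||% (if (ext) 8 else 14),
    truncate_dv = truncate_dv
  )
  stopifnot(d$n_subjects >= 1, d$dose_per_kg > 0, d$dose_interval > 0,
            d$infusion_duration > 0,
            length(d$treatment_days) == length(d$treatment_days_prob))
  if (length(c(d$sampling_hypo, d$sampling_late)) == 0)
    stop("empty sampling grid", call. = FALSE)
  if (any(c(d$sampling_hypo, d$sampling_late) < 0) ||
      any(c(d$sampling_hypo, d$sampling_late) > 150))
    stop("sampling times must lie within 0-150 h", call. = FALSE)
  structure(d, class = "gc_design")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic cohort of cooled neonates
#'
#' Draws covariates (integer gestational age with mode at the reference
#' 40 weeks, truncated-normal birth weight), a q24h 4 mg/kg dosing history
#' of randomly drawn duration, per-subject sampling times from the design
#' grids, and observed concentrations simulated under the full model
#' (interindividual variability plus residual error, truncated at zero as
#' a measured concentration cannot be negative).  Nuisance clinical
#' covariates (serum creatinine, urine output, sex) are carried along with
#' no effect on the kinetics, for covariate-search testing.
#'
#' @param design a [gc_design()].
#' @param params a [gc_parameters()] object (the generating truth).
#' @param seed integer master seed.
#' @return An event-record tibble of class `gc_cohort` with columns
#'   `ID`, `TIME`, `EVID`, `AMT`, `RATE`, `DV`, `MDV`, `BW`, `GA`, `SD5`,
#'   `SCR`, `URINE`, `MALE`, sorted by (ID, TIME, dose-before-observation).
#' @examples
#' coh <- generate_cohort(gc_design("external"), gc_parameters(), seed = 1)
#' dplyr::count(coh, EVID)
#' @export
generate_cohort <- function(design, params, seed) {
  stopifnot(inherits(design, "gc_design"), inherits(params, "gc_parameters"))
  with_local_seed(seed, {
    n <- design$n_subjects
    ga_lv <- seq(design$ga_range[1], design$ga_range[2])
    ga_w <- dnorm(ga_lv, params$ga_median, 1.4)
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      ga <- sample(ga_lv, 1, prob = ga_w)
      bw <- round(rtruncnorm1(1, design$bw_mean, design$bw_sd,
                              design$bw_range[1], design$bw_range[2]), 3)
      t0 <- round(runif(1, design$first_dose_pna[1],
                        design$first_dose_pna[2]), 2)
      days <- sample(design$treatment_days, 1,
                     prob = design$treatment_days_prob)
      dose_times <- t0 + design$dose_interval * (0:days)
      amt <- design$dose_per_kg * bw

      n_hypo_max <- length(design$sampling_hypo)
      n_late_max <- length(design$sampling_late)
      n_i <- min(sample_count(design), n_hypo_max + n_late_max)
      n_hypo <- stats::rbinom(1, n_i, design$hypo_fraction)
      n_hypo <- min(max(n_hypo, n_i - n_late_max), n_hypo_max)
      obs_t <- sort(c(sample(design$sampling_hypo, n_hypo),
                      sample(design$sampling_late, n_i - n_hypo)))

      eta <- draw_random_effects(params, 1)
      tv <- typical_values(params, bw = bw, ga = ga, sd5 = 0)
      ind <- individual_parameters(tv, eta$eta_cl, eta$eta_vc, eta$eta_vp)
      doses <- tibble::tibble(start_time = dose_times, amount = amt,
                              duration = design$infusion_duration)
      conc <- predict_concentration(ind, doses, obs_t,
                                    cl_day5_factor = params$theta_sd5)
      dv <- apply_residual_error(conc, params, eta$eta_eps)
      dv <- signif(truncate_negative(dv, design$truncate_dv), 6)

      scr <- round(exp(rnorm(1, log(49), 0.35)))
      urine <- round(max(0.1, rnorm(1, 2.8, 1.2)), 2)
      male <- stats::rbinom(1, 1, 0.57)

      dose_rec <- tibble::tibble(
        ID = i, TIME = dose_times, EVID = 1L, AMT = amt,
        RATE = amt / design$infusion_duration, DV = NA_real_, MDV = 1L)
      obs_rec <- tibble::tibble(
        ID = i, TIME = obs_t, EVID = 0L, AMT = NA_real_, RATE = NA_real_,
        DV = dv, MDV = 0L)
      rec <- dplyr::bind_rows(dose_rec, obs_rec)
      rec$BW <- bw; rec$GA <- ga
      rec$SD5 <- as.integer(rec$TIME > DAY5_CUTOFF_H)
      rec$SCR <- scr; rec$URINE <- urine; rec$MALE <- male
      recs[[i]] <- rec
    }
    out <- dplyr::bind_rows(recs)
    out <- dplyr::arrange(out, .data$ID, .data$TIME, dplyr::desc(.data$EVID))
    structure(out, class = c("gc_cohort", class(tibble::tibble())),
              design = design)
  })
}

# per-subject sample count: discrete draw centred on the profile's median,
# bounded by the observed per-subject range
sample_count <- function(design) {
  lv <- seq(design$samples_range[1], design$samples_range[2])
  sample(lv, 1, prob = dnorm(lv, design$samples_mode, 3))
}
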