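#' Population pharmacokinetic parameters for gentamicin under therapeutic
#' hypothermia
#'
#' Container for the fixed effects, interindividual variability (IIV)
#' variances and residual-error parameters of the allometrically scaled
#' two-compartment gentamicin model for cooled (near) term neonates.  The
#' defaults are the published model-building estimates; the merged-data
#' refit is available via `profile = "merged_refit"`.
#'
#' The typical-value model is
#' \deqn{TVCL = CL \cdot (BW/70)^{0.75} \cdot \theta_{SD5}^{SD5} \cdot
#'   (GA/GA_{med})^{\theta_{CLGA}}}
#' \deqn{TVV_c = V_c \cdot (BW/70), \quad TVQ = Q \cdot (BW/70)^{0.75},
#'   \quad TVV_p = V_p \cdot (BW/70)}
#' with log-normal IIV on CL, Vc and Vp, an additive residual error with
#' SD `sigma_add`, and log-normal IIV on that residual SD (its variance is
#' `omega2_eps`).  `SD5` is 1 when postnatal age exceeds 96 h (study day 5,
#' normothermia re-established) and 0 before.
#'
#' @param cl_pop clearance for a 70 kg reference individual, L/h.
#' @param vc_pop central volume of distribution per 70 kg, L.
#' @param q_pop intercompartmental clearance per 70 kg, L/h.
#' @param vp_pop peripheral volume of distribution per 70 kg, L.
#' @param theta_cl_ga exponent on `(GA/ga_median)` for clearance.
#' @param theta_sd5 multiplicative clearance factor on study day 5
#'   (postnatal age > 96 h).
#' @param omega2_cl,omega2_vc,omega2_vp variances of the log-normal IIV on
#'   CL, Vc and Vp.
#' @param omega2_eps variance of the log-normal IIV on the additive
#'   residual SD.
#' @param sigma_add additive residual SD, mg/L.
#' @param ga_median reference gestational age, weeks.
#' @param profile which published estimate column the unspecified arguments
#'   default to: `"model_building"` (default) or `"merged_refit"`.
#'
#' @return An object of class `gc_parameters` (a named list).
#' @examples
#' p <- gc_parameters()
#' p$cl_pop        # 1.89 L/h/70 kg
#' iiv_cv(p)       # IIV reported as CV%
#' @export
gc_parameters <- function(cl_pop = NULL, vc_pop = NULL, q_pop = NULL,
                          vp_pop = NULL, theta_cl_ga = NULL,
                          theta_sd5 = NULL,
                          omega2_cl = NULL, omega2_vc = NULL,
                          omega2_vp = NULL, omega2_eps = NULL,
                          sigma_add = NULL, ga_median = 40,
                          profile = c("model_building", "merged_refit")) {
  profile <- match.arg(profile)
  # published columns; IIV printed as 100 * omega, stored as omega^2
  def <- if (profile == "model_building") {
    list(cl_pop = 1.89, vc_pop = 32.5, q_pop = 2.01, vp_pop = 30.3,
         theta_cl_ga = 3.0, theta_sd5 = 1.29,
         omega2_cl = 0.266^2, omega2_vc = 0.408^2, omega2_vp = 0.533^2,
         omega2_eps = 0.502^2, sigma_add = 0.15)
  } else {
    list(cl_pop = 1.88, vc_pop = 33.2, q_pop = 1.81, vp_pop = 32.2,
         theta_cl_ga = 2.76, theta_sd5 = 1.36,
         omega2_cl = 0.245^2, omega2_vc = 0.301^2, omega2_vp = 0.564^2,
         omega2_eps = 0.523^2, sigma_add = 0.16)
  }
  p <- list(
    cl_pop = cl_pop %||% def$cl_pop,
    vc_pop = vc_pop %||% def$vc_pop,
    q_pop = q_pop %||% def$q_pop,
    vp_pop = vp_pop %||% def$vp_pop,
    theta_cl_ga = theta_cl_ga %||% def$theta_cl_ga,
    theta_sd5 = theta_sd5 %||% def$theta_sd5,
    omega2_cl = omega2_cl %||% def$omega2_cl,
    omega2_vc = omega2_vc %||% def$omega2_vc,
    omega2_vp = omega2_vp %||% def$omega2_vp,
    omega2_eps = omega2_eps %||% def$omega2_eps,
    sigma_add = sigma_add %||% def$sigma_add,
    ga_median = ga_median
  )
  validate_gc_parameters(p)
  structure(p, class = "gc_parameters")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

validate_gc_parameters <- function(p) {
  for (nm in c("cl_pop", "vc_pop", "q_pop", "vp_pop", "theta_sd5",
               "sigma_add", "ga_median"))
    stopifnot_scalar_num(p[[nm]], nm, positive = TRUE)
  for (nm in c("omega2_cl", "omega2_vc", "omega2_vp", "omega2_eps"))
    stopifnot_scalar_num(p[[nm]], nm, nonneg = TRUE)
  stopifnot_scalar_num(p$theta_cl_ga, "theta_cl_ga")
  invisible(p)
}

#' @export
print.gc_parameters <- function(x, ...) {
  cat("<gc_parameters> two-compartment gentamicin population model\n")
  cat(sprintf("  CL %.3g L/h/70kg  Vc %.3g L/70kg  Q %.3g L/h/70kg  Vp %.3g L/70kg\n",
              x$cl_pop, x$vc_pop, x$q_pop, x$vp_pop))
  cat(sprintf("  GA exponent %.3g (GA median %g wk)   day-5 CL factor %.3g\n",
              x$theta_cl_ga, x$ga_median, x$theta_sd5))
  cat(sprintf("  IIV CV%%: CL %.1f  Vc %.1f  Vp %.1f  residual %.1f\n",
              100 * sqrt(x$omega2_cl), 100 * sqrt(x$omega2_vc),
              100 * sqrt(x$omega2_vp), 100 * sqrt(x$omega2_eps)))
  cat(sprintf("  additive residual SD %.3g mg/L\n", x$sigma_add))
  invisible(x)
}

#' Report interindividual variability as coefficients of variation
#'
#' Two reporting conventions coexist for log-normal random effects: the
#' dominant approximation `100 * omega` and the exact log-normal CV
#' `100 * sqrt(exp(omega^2) - 1)`.  Both are returned.
#'
#' @param params a [gc_parameters()] object.
#' @return A tibble with one row per variability term.
#' @export
iiv_cv <- function(params) {
  stopifnot(inherits(params, "gc_parameters"))
  om2 <- c(cl = params$omega2_cl, vc = params$omega2_vc,
           vp = params$omega2_vp, eps = params$omega2_eps)
  tibble::tibble(
    parameter = names(om2),
    omega2 = unname(om2),
    cv_pct = 100 * sqrt(unname(om2)),
    cv_pct_lognormal = 100 * sqrt(exp(unname(om2)) - 1)
  )
}

# parameter vector <-> gc_parameters plumbing used by the estimation module
FIXED_EFFECT_NAMES <- c("cl_pop", "vc_pop", "q_pop", "vp_pop",
                        "theta_cl_ga", "theta_sd5")
ALL_PARAM_NAMES <- c(FIXED_EFFECT_NAMES,
                     "omega2_cl", "omega2_vc", "omega2_vp", "omega2_eps",
                     "sigma_add")
# identity-scale parameters; everything else is estimated on the log scale
IDENTITY_SCALE <- "theta_cl_ga"
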