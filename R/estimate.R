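# Nonlinear mixed-effects machinery: Laplacian conditional-mode (FOCE-I
# style) marginal likelihood, maximum-likelihood fitting, empirical-Bayes
# individual estimates, stepwise covariate search and bootstrap.

# --- parameter plumbing -----------------------------------------------------

# covariate-extension spec: named list, each element
#   list(type = "continuous", col = "SCR")   -> (cov/median)^theta on CL
#   list(type = "categorical", col = "MALE") -> theta^indicator on CL
#   list(type = "day5")                      -> frees theta_sd5
par_spec <- function(start, extras, fixed) {
  nm <- ALL_PARAM_NAMES
  val <- unlist(start[nm])
  scale <- ifelse(nm %in% IDENTITY_SCALE, "id", "log")
  if (length(extras)) {
    ex <- names(extras)[vapply(extras, function(e) e$type != "day5",
                               logical(1))]
    for (e in ex) {
      nm <- c(nm, paste0("theta_", e))
      if (extras[[e]]$type == "continuous") {
        val <- c(val, 0); scale <- c(scale, "id")
      } else {
        val <- c(val, 1); scale <- c(scale, "log")
      }
    }
  }
  names(val) <- nm
  names(scale) <- nm
  free <- setdiff(nm, fixed)
  list(names = nm, values = val, scale = scale, free = free)
}

to_trans <- function(values, scale) {
  ifelse(scale == "log", log(values), values)
}
from_trans <- function(tpar, scale) {
  ifelse(scale == "log", exp(tpar), tpar)
}

# per-subject clearance multiplier from the active covariate extensions
extras_cl_multiplier <- function(subs, extras, theta) {
  out <- rep(1, length(subs))
  for (e in names(extras)) {
    if (extras[[e]]$type == "day5") next
    col <- extras[[e]]$col
    v <- vapply(subs, function(s) {
      x <- s$extras[[col]]
      if (is.null(x)) stop("covariate column `", col, "` not in cohort",
                           call. = FALSE)
      as.numeric(x)
    }, numeric(1))
    th <- theta[[paste0("theta_", e)]]
    if (extras[[e]]$type == "continuous") {
      out <- out * (v / median(v))^th
    } else {
      out <- out * th^v
    }
  }
  out
}

params_from_values <- function(values, ga_median) {
  p <- as.list(values[ALL_PARAM_NAMES])
  p$ga_median <- ga_median
  structure(p, class = "gc_parameters")
}

# --- marginal objective function value --------------------------------------

#' Approximate marginal objective function value (-2 log-likelihood)
#'
#' Per-subject Laplacian approximation at the conditional mode of the
#' random effects, with the residual variance evaluated at the conditional
#' estimates (the interaction term of FOCE-I); subject contributions sum.
#' With all IIV variances equal to zero the value is the exact Gaussian
#' residual -2 log-likelihood.
#'
#' @param cohort an event-record cohort.
#' @param params a [gc_parameters()] object.
#' @return The objective function value (numeric scalar).
#' @export
gc_ofv <- function(cohort, params) {
  subs <- cohort_subjects(cohort)
  scpp <- subjects_for_cpp(subs)
  tv <- subject_tv_matrix(params, subs)
  warm <- matrix(0, length(subs), 4)
  res <- cpp_cohort_ofv(scpp, tv, params$theta_sd5, DAY5_CUTOFF_H,
                        omega2_vector(params), params$sigma_add, warm)
  if (!all(res$ok))
    warning(sum(!res$ok), " subject(s) with ill-conditioned conditional ",
            "curvature", call. = FALSE)
  res$ofv
}

# --- maximum-likelihood fit -------------------------------------------------

#' Fit the population model by approximate maximum likelihood
#'
#' Maximises the Laplacian marginal likelihood over the unfixed parameters.
#' Positive parameters and variances are estimated on the log scale, the
#' gestational-age exponent on the identity scale.  Multiple jittered
#' starts guard against local optima; convergence requires a relative
#' objective-function change below 1e-7 in the quasi-Newton optimiser.
#' Standard errors come from the observed-information (inverse Hessian)
#' sandwich on the transformed scale; when the information matrix is
#' ill-conditioned they are reported as `NA` (use [gc_bootstrap()]).
#'
#' @param cohort an event-record cohort.
#' @param start a [gc_parameters()] object of starting values (also
#'   supplies the values of fixed parameters).
#' @param fixed character vector of parameter names to hold fixed, e.g.
#'   `c("q_pop", "omega2_vp")`.  Fixing all parameters evaluates the
#'   objective once and returns the empirical-Bayes estimates without any
#'   optimisation (the estimation-free mode).
#' @param extras covariate-extension list (see [gc_stepwise()]); `NULL`
#'   for the base model.
#' @param n_starts number of optimisation starts (first from `start`,
#'   others jittered on the transformed scale).
#' @param jitter_sd SD of the start jitter on the transformed scale.
#' @param seed seed for the start jitter.
#' @param se compute observed-information standard errors?
#' @param verbose report the objective reached from each start?
#' @param control passed to [stats::nlminb()].
#' @return An object of class `gc_fit`: estimates, objective function
#'   value, parameter table with CV%, per-subject empirical-Bayes random
#'   effects, convergence flag and evaluation count.
#' @export
gc_fit <- function(cohort, start = gc_parameters(), fixed = character(),
                   extras = NULL, n_starts = 3, jitter_sd = 0.1,
                   seed = NULL, se = TRUE, verbose = FALSE,
                   control = list(rel.tol = 1e-7, eval.max = 2000,
                                  iter.max = 500)) {
  stopifnot(inherits(start, "gc_parameters"))
  extras <- extras %||% list()
  if (any(vapply(extras, function(e) e$type == "day5", logical(1))))
    fixed <- setdiff(fixed, "theta_sd5")
  subs <- cohort_subjects(cohort)
  if (any(vapply(subs, function(s) length(s$y), integer(1)) < 1))
    stop("every subject needs at least one observation", call. = FALSE)
  scpp <- subjects_for_cpp(subs)
  spec <- par_spec(start, extras, fixed)
  bad <- setdiff(fixed, spec$names)
  if (length(bad)) stop("unknown parameter(s) in `fixed`: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  n <- length(subs)
  n_evals <- 0L
  zero_etas <- matrix(0, n, 4)   # fixed inner start keeps the OFV
                                 # deterministic in the parameters

  eval_ofv <- function(values) {
    params <- params_from_values(values, start$ga_median)
    clx <- extras_cl_multiplier(subs, extras, as.list(values))
    tv <- subject_tv_matrix(params, subs, clx)
    n_evals <<- n_evals + 1L
    cpp_cohort_ofv(scpp, tv, values[["theta_sd5"]], DAY5_CUTOFF_H,
                   omega2_vector(params), params$sigma_add, zero_etas)
  }

  full_values <- function(tfree) {
    v <- spec$values
    v[spec$free] <- from_trans(tfree, spec$scale[spec$free])
    v
  }

  if (length(spec$free) == 0) {
    res <- eval_ofv(spec$values)
    return(new_gc_fit(spec, spec$values, res, subs, start, fixed, extras,
                      converged = TRUE, n_evals = n_evals, se_tab = NULL))
  }

  obj <- function(tp) eval_ofv(full_values(tp))$ofv
  grad <- function(tp) {
    vapply(seq_along(tp), function(i) {
      e <- numeric(length(tp)); e[i] <- 1e-5
      (obj(tp + e) - obj(tp - e)) / 2e-5
    }, numeric(1))
  }

  t0 <- to_trans(spec$values[spec$free], spec$scale[spec$free])
  starts <- list(t0)
  if (n_starts > 1) {
    jit <- with_local_seed(seed, {
      lapply(seq_len(n_starts - 1), function(k)
        t0 + rnorm(length(t0), 0, jitter_sd))
    })
    starts <- c(starts, jit)
  }

  lower <- rep(-25, length(t0)); upper <- rep(25, length(t0))
  # each start alternates quasi-Newton descent with a derivative-free
  # Nelder-Mead polish (which tolerates the ~1e-6 numerical roughness of
  # the Laplacian objective) until a full round no longer improves the
  # objective function value materially
  run_start <- function(st) {
    cur <- st; curval <- obj(st); converged <- FALSE
    for (round in 1:8) {
      opt <- tryCatch(
        nlminb(cur, obj, gradient = grad, lower = lower, upper = upper,
               control = control),
        error = function(e) NULL)
      if (!is.null(opt)) {
        # on abnormal termination nlminb's reported objective can refer to
        # a different iterate than $par; trust only a re-evaluation
        val <- obj(opt$par)
        if (val < curval) { cur <- opt$par; curval <- val }
      }
      pol <- optim(cur, obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-10, maxit = 2000))
      polval <- obj(pol$par)
      imp <- curval - polval
      if (polval < curval) { cur <- pol$par; curval <- polval }
      if (imp < 1e-3) { converged <- TRUE; break }
    }
    list(par = cur, objective = curval, converged = converged)
  }
  best <- NULL
  for (si in seq_along(starts)) {
    cand <- tryCatch(run_start(starts[[si]]), error = function(e) NULL)
    if (is.null(cand)) next
    if (verbose)
      message(sprintf("start %d: OFV %.4f%s", si, cand$objective,
                      if (cand$converged) "" else " (not converged)"))
    if (is.null(best) || cand$objective < best$objective) best <- cand
  }
  if (is.null(best)) stop("all optimisation starts failed", call. = FALSE)
  values <- full_values(best$par)
  res <- eval_ofv(values)   # EBEs at the optimum

  se_tab <- NULL
  if (se) se_tab <- fit_se(obj, best$par, spec)

  new_gc_fit(spec, values, res, subs, start, fixed, extras,
             converged = best$converged, n_evals = n_evals,
             se_tab = se_tab)
}

# observed-information standard errors on the transformed scale, mapped to
# the natural scale by the delta method
fit_se <- function(obj, tpar, spec) {
  p <- length(tpar)
  h <- pmax(1e-4, 1e-4 * abs(tpar))
  H <- matrix(NA_real_, p, p)
  f0 <- obj(tpar)
  fp <- fm <- numeric(p)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    fp[i] <- obj(tpar + ei); fm[i] <- obj(tpar - ei)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  if (p > 1) {
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      ei <- numeric(p); ei[i] <- h[i]
      ej <- numeric(p); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (obj(tpar + ei + ej) - obj(tpar + ei - ej) -
           obj(tpar - ei + ej) + obj(tpar - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  se_t <- tryCatch({
    cv <- 2 * solve(H)           # covariance of the transformed estimates
    sqrt(pmax(diag(cv), 0))
  }, error = function(e) rep(NA_real_, p))
  est <- from_trans(tpar, spec$scale[spec$free])
  se_nat <- ifelse(spec$scale[spec$free] == "log", est * se_t, se_t)
  tibble::tibble(parameter = spec$free, se = se_nat,
                 cv_pct = 100 * se_nat / abs(est))
}

new_gc_fit <- function(spec, values, res, subs, start, fixed, extras,
                       converged, n_evals, se_tab) {
  est <- params_from_values(values, start$ga_median)
  tab <- tibble::tibble(
    parameter = spec$names,
    estimate = unname(values[spec$names]),
    fixed = spec$names %in% setdiff(spec$names, spec$free)
  )
  if (!is.null(se_tab)) tab <- dplyr::left_join(tab, se_tab, by = "parameter")
  etam <- res$etas
  colnames(etam) <- c("eta_cl", "eta_vc", "eta_vp", "eta_eps")
  ebes <- dplyr::bind_cols(
    tibble::tibble(ID = vapply(subs, function(s) s$id, numeric(1))),
    tibble::as_tibble(etam))
  structure(list(
    estimates = est,
    extra_thetas = values[setdiff(spec$names, ALL_PARAM_NAMES)],
    ofv = res$ofv,
    parameters = tab,
    ebes = ebes,
    converged = converged,
    n_function_evals = n_evals,
    subject_ok = res$ok,
    fixed = fixed,
    extras = extras,
    start = start
  ), class = "gc_fit")
}

#' @export
print.gc_fit <- function(x, ...) {
  cat(sprintf("<gc_fit> OFV %.3f  (%s, %d evaluations)\n", x$ofv,
              if (x$converged) "converged" else "NOT converged",
              x$n_function_evals))
  print(x$parameters, n = nrow(x$parameters))
  invisible(x)
}

# --- empirical-Bayes (posthoc) estimation -----------------------------------

#' Empirical-Bayes random effects and predictions under locked parameters
#'
#' The estimation-free mode: population parameters stay locked while each
#' subject's random effects are set to the mode of their conditional
#' (posterior) density.  Returns both population predictions (`PRED`,
#' random effects at zero — the quantity the prediction-error metrics use)
#' and individual predictions (`IPRED`, random effects at the conditional
#' mode).  A subject without observations keeps the prior mode, eta = 0.
#'
#' @param cohort an event-record cohort.
#' @param params locked [gc_parameters()].
#' @return A list of class `gc_posthoc` with elements `etas` (tibble, one
#'   row per subject) and `predictions` (tibble, one row per observation
#'   with `DV`, `PRED`, `IPRED`, `phase`).
#' @export
gc_posthoc <- function(cohort, params) {
  subs <- cohort_subjects(cohort)
  scpp <- subjects_for_cpp(subs)
  tv <- subject_tv_matrix(params, subs)
  warm <- matrix(0, length(subs), 4)
  res <- cpp_cohort_ofv(scpp, tv, params$theta_sd5, DAY5_CUTOFF_H,
                        omega2_vector(params), params$sigma_add, warm)
  etam <- res$etas
  colnames(etam) <- c("eta_cl", "eta_vc", "eta_vp", "eta_eps")
  etas <- dplyr::bind_cols(
    tibble::tibble(ID = vapply(subs, function(s) s$id, numeric(1))),
    tibble::as_tibble(etam))
  preds <- purrr::imap_dfr(subs, function(s, i) {
    if (length(s$times) == 0) return(NULL)
    pred <- cpp_conc(s$times, s$dose_start, s$dose_amt, s$dose_dur,
                     tv[i, 1], tv[i, 2], tv[i, 3], tv[i, 4],
                     params$theta_sd5, DAY5_CUTOFF_H)
    e <- res$etas[i, ]
    ipred <- cpp_conc(s$times, s$dose_start, s$dose_amt, s$dose_dur,
                      tv[i, 1] * exp(e[1]), tv[i, 2] * exp(e[2]),
                      tv[i, 3], tv[i, 4] * exp(e[3]),
                      params$theta_sd5, DAY5_CUTOFF_H)
    tibble::tibble(ID = s$id, TIME = s$times, DV = s$y,
                   PRED = pred, IPRED = ipred,
                   phase = phase_of(s$times))
  })
  structure(list(etas = etas, predictions = preds, ofv = res$ofv),
            class = "gc_posthoc")
}

# --- stepwise covariate search ----------------------------------------------

#' Stepwise covariate selection on clearance
#'
#' Forward inclusion followed by backward elimination on nested models.
#' Continuous candidates enter clearance as `(cov/median)^theta`,
#' categorical candidates as `theta^indicator`; the special candidate
#' `list(type = "day5")` frees the day-5 clearance factor.  A candidate is
#' included when it lowers the objective function value by at least
#' `forward_dofv` (3.84 is the 5% chi-square point for one parameter; the
#' published search used 3.8) and survives elimination only when its
#' removal raises the value by at least `backward_dofv` (10.83, P < 0.001).
#'
#' @param cohort an event-record cohort.
#' @param start starting [gc_parameters()] for the base model (set
#'   `theta_sd5 = 1` and fix it when the day-5 effect is itself a
#'   candidate).
#' @param candidates named list of candidate specs (see above).
#' @param fixed parameters fixed in every model.
#' @param forward_dofv,backward_dofv selection thresholds on the
#'   objective-function drop.
#' @param ... further arguments to [gc_fit()] (e.g. `n_starts`).
#' @return A list of class `gc_stepwise`: `fit` (final model),
#'   `included` (candidate names retained), `trace` (tibble of every
#'   comparison).
#' @export
gc_stepwise <- function(cohort, start = gc_parameters(), candidates,
                        fixed = character(),
                        forward_dofv = 3.8, backward_dofv = 10.83, ...) {
  stopifnot(is.list(candidates))
  if (length(candidates) &&
      (is.null(names(candidates)) || any(names(candidates) == "")))
    stop("`candidates` must be a named list", call. = FALSE)
  included <- character()
  trace <- list()
  base_fit <- gc_fit(cohort, start, fixed = fixed, extras = NULL, ...)
  current <- base_fit
  step <- 0L
  repeat {                                   # forward inclusion
    remaining <- setdiff(names(candidates), included)
    if (!length(remaining)) break
    step <- step + 1L
    fits <- lapply(remaining, function(cn) {
      ex <- candidates[c(included, cn)]
      tryCatch(gc_fit(cohort, start, fixed = fixed, extras = ex, ...),
               error = function(e) NULL)
    })
    dofv <- vapply(fits, function(f)
      if (is.null(f)) -Inf else current$ofv - f$ofv, numeric(1))
    trace <- c(trace, list(tibble::tibble(
      step = step, phase = "forward", candidate = remaining,
      ofv = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$ofv,
                   numeric(1)),
      dofv = dofv)))
    k <- which.max(dofv)
    if (dofv[k] >= forward_dofv) {
      included <- c(included, remaining[k])
      current <- fits[[k]]
    } else break
  }
  repeat {                                   # backward elimination
    if (!length(included)) break
    step <- step + 1L
    fits <- lapply(included, function(cn) {
      ex <- candidates[setdiff(included, cn)]
      if (!length(ex)) ex <- NULL
      tryCatch(gc_fit(cohort, start, fixed = fixed, extras = ex, ...),
               error = function(e) NULL)
    })
    rise <- vapply(fits, function(f)
      if (is.null(f)) Inf else f$ofv - current$ofv, numeric(1))
    trace <- c(trace, list(tibble::tibble(
      step = step, phase = "backward", candidate = included,
      ofv = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$ofv,
                   numeric(1)),
      dofv = rise)))
    k <- which.min(rise)
    if (rise[k] < backward_dofv) {
      current <- fits[[k]]
      included <- setdiff(included, included[k])
    } else break
  }
  structure(list(fit = current, included = included,
                 base_ofv = base_fit$ofv,
                 trace = dplyr::bind_rows(trace)),
            class = "gc_stepwise")
}

#' @export
print.gc_stepwise <- function(x, ...) {
  cat("<gc_stepwise> retained: ",
      if (length(x$included)) paste(x$included, collapse = ", ") else "none",
      "\n", sep = "")
  print(x$trace, n = nrow(x$trace))
  invisible(x)
}

# --- bootstrap ---------------------------------------------------------------

#' Nonparametric bootstrap of the population fit
#'
#' Subject-level resampling with replacement; each resample is refit from
#' `start` and percentile 2.5/97.5% intervals are taken over the
#' successful fits.  Failed fits are excluded and counted; a warning is
#' raised when more than 10% fail.
#'
#' @param cohort an event-record cohort.
#' @param start starting [gc_parameters()].
#' @param n_resamples number of bootstrap resamples (1000 in routine use).
#' @param seed integer seed for the resampling.
#' @param indices optional list of subject-index vectors overriding the
#'   random resampling (for reproducing a specific resample set).
#' @param ... further arguments to [gc_fit()]; bootstrap refits default to
#'   a single start and no standard errors.
#' @return A list of class `gc_bootstrap`: `draws` (tibble of per-resample
#'   estimates), `summary` (median and percentile CI per parameter),
#'   `n_success`, `n_failed`.
#' @export
gc_bootstrap <- function(cohort, start = gc_parameters(), n_resamples = 1000,
                         seed = NULL, indices = NULL, ...) {
  stopifnot(n_resamples >= 1)
  ids <- unique(cohort$ID)
  n <- length(ids)
  if (is.null(indices)) {
    indices <- with_local_seed(seed, {
      lapply(seq_len(n_resamples), function(k) sample.int(n, n, replace = TRUE))
    })
  }
  dots <- list(...)
  if (is.null(dots$n_starts)) dots$n_starts <- 1
  if (is.null(dots$se)) dots$se <- FALSE
  by_id <- split(seq_len(nrow(cohort)), factor(cohort$ID, levels = ids))
  draws <- purrr::imap_dfr(indices, function(idx, k) {
    rows <- unlist(lapply(seq_along(idx), function(j) by_id[[idx[j]]]),
                   use.names = FALSE)
    boot <- cohort[rows, ]
    # renumber so duplicated subjects stay distinct
    reps <- vapply(idx, function(i) length(by_id[[i]]), integer(1))
    boot$ID <- rep(seq_along(idx), reps)
    f <- tryCatch(do.call(gc_fit, c(list(boot, start), dots)),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) return(NULL)
    sel <- !f$parameters$fixed
    out <- tibble::as_tibble(as.list(setNames(
      f$parameters$estimate[sel], f$parameters$parameter[sel])))
    dplyr::bind_cols(tibble::tibble(resample = k, ofv = f$ofv), out)
  })
  n_success <- nrow(draws) %||% 0L
  n_failed <- length(indices) - n_success
  if (n_failed > 0.10 * length(indices))
    warning(sprintf("%d of %d bootstrap fits failed", n_failed,
                    length(indices)), call. = FALSE)
  par_cols <- setdiff(names(draws), c("resample", "ofv"))
  summ <- purrr::map_dfr(par_cols, function(pc) {
    x <- draws[[pc]]
    tibble::tibble(parameter = pc, estimate = median(x),
                   conf_low = unname(quantile(x, 0.025)),
                   conf_high = unname(quantile(x, 0.975)))
  })
  structure(list(draws = draws, summary = summ,
                 n_success = n_success, n_failed = n_failed),
            class = "gc_bootstrap")
}

#' @export
print.gc_bootstrap <- function(x, ...) {
  cat(sprintf("<gc_bootstrap> %d successful / %d failed resamples\n",
              x$n_success, x$n_failed))
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}
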