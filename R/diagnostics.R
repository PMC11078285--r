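# Model-validation battery: prediction-error metrics with stratification
# and bootstrap CIs, normalized prediction distribution errors (NPDE) and
# the prediction-corrected visual predictive check (pcVPC).

#' Prediction errors
#'
#' `PE = predicted - observed`: over-prediction is positive.
#'
#' @param predicted,observed paired concentration vectors, mg/L.
#' @return Numeric vector of prediction errors.
#' @export
prediction_errors <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("`predicted` and `observed` must have equal length", call. = FALSE)
  predicted - observed
}

boot_ci <- function(pe, statistic, B, seed) {
  if (length(pe) == 1) return(c(statistic(pe), statistic(pe)))
  reps <- with_local_seed(seed, {
    vapply(seq_len(B), function(b)
      statistic(pe[sample.int(length(pe), replace = TRUE)]), numeric(1))
  })
  unname(quantile(reps, c(0.025, 0.975)))
}

#' Mean prediction error (bias) with 95% confidence interval
#'
#' Arithmetic mean of the prediction errors; the interval is a
#' nonparametric percentile bootstrap (default) or a t-based interval.
#'
#' @param pe vector of prediction errors, mg/L.
#' @param conf compute a confidence interval?
#' @param method `"bootstrap"` (percentile, `B` resamples) or `"t"`.
#' @param B bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @return One-row tibble: `n`, `estimate`, `conf_low`, `conf_high`.
#' @export
mpe <- function(pe, conf = TRUE, method = c("bootstrap", "t"), B = 1000,
                seed = NULL) {
  if (!length(pe)) stop("empty prediction-error vector", call. = FALSE)
  method <- match.arg(method)
  est <- mean(pe)
  ci <- c(NA_real_, NA_real_)
  if (conf) {
    ci <- if (method == "bootstrap") boot_ci(pe, mean, B, seed)
    else est + c(-1, 1) * stats::qt(0.975, max(length(pe) - 1, 1)) *
      sd(pe) / sqrt(length(pe))
  }
  tibble::tibble(n = length(pe), estimate = est,
                 conf_low = ci[1], conf_high = ci[2])
}

#' Root mean squared prediction error (precision) with 95% CI
#'
#' @inheritParams mpe
#' @return One-row tibble: `n`, `estimate`, `conf_low`, `conf_high`.
#' @export
rmse <- function(pe, conf = TRUE, method = c("bootstrap", "t"), B = 1000,
                 seed = NULL) {
  if (!length(pe)) stop("empty prediction-error vector", call. = FALSE)
  method <- match.arg(method)
  f <- function(x) sqrt(mean(x^2))
  est <- f(pe)
  ci <- c(NA_real_, NA_real_)
  if (conf) {
    ci <- if (method == "bootstrap") boot_ci(pe, f, B, seed)
    else {  # delta-method interval on the mean square
      ms <- mean(pe^2)
      half <- stats::qt(0.975, max(length(pe) - 1, 1)) *
        sd(pe^2) / sqrt(length(pe))
      sqrt(pmax(c(ms - half, ms + half), 0))
    }
  }
  tibble::tibble(n = length(pe), estimate = est,
                 conf_low = ci[1], conf_high = ci[2])
}

#' Stratify observations by phase and concentration level
#'
#' Low levels are observed concentrations at or below 1.5 mg/L (the
#' trough-like stratum); high levels are samples drawn within 2 hours
#' after the start of the preceding infusion (boundary inclusive).  The
#' two strata are not mutually exclusive and a sample can be neither.
#'
#' @param cohort an event-record cohort.
#' @param low_cutoff concentration cutoff for the low stratum, mg/L.
#' @param high_window width of the post-dose window for the high stratum, h.
#' @return Observation rows with `phase`, `tad` (time after most recent
#'   dose start, `NA` before the first dose), `low`, `high`.
#' @export
gc_stratify <- function(cohort, low_cutoff = 1.5, high_window = 2) {
  obs <- dplyr::filter(cohort, .data$EVID == 0)
  subs <- cohort_subjects(cohort)
  tad <- unlist(lapply(subs, function(s) {
    vapply(s$times, function(t) {
      prior <- s$dose_start[s$dose_start <= t]
      if (!length(prior)) NA_real_ else t - max(prior)
    }, numeric(1))
  }), use.names = FALSE)
  if (any(is.na(tad)))
    warning("observation(s) before any dose: not eligible for the high ",
            "stratum", call. = FALSE)
  obs$phase <- phase_of(obs$TIME)
  obs$tad <- tad
  obs$low <- obs$DV <= low_cutoff
  obs$high <- !is.na(tad) & tad > 0 & tad <= high_window
  obs
}

#' Stratified bias and precision table
#'
#' Population-predicted concentrations under locked parameters are
#' compared with the observations; MPE and RMSE (with 95% CIs) are
#' reported for all samples and for the low and high strata, across all
#' phases and within the hypothermic and normothermic phases.
#'
#' @param cohort an event-record cohort.
#' @param params locked [gc_parameters()].
#' @inheritParams mpe
#' @return A tibble of class `gc_pe_table`, one row per stratum.
#' @export
gc_pe_table <- function(cohort, params, method = c("bootstrap", "t"),
                        B = 1000, seed = NULL) {
  method <- match.arg(method)
  strat <- gc_stratify(cohort)
  ph <- gc_posthoc(cohort, params)
  pe_all <- prediction_errors(ph$predictions$PRED, ph$predictions$DV)
  rows <- list()
  phases <- list(all = rep(TRUE, nrow(strat)),
                 hypothermia = strat$phase == "hypothermia",
                 normothermia = strat$phase == "normothermia")
  levels_ <- list(all = rep(TRUE, nrow(strat)),
                  low = strat$low, high = strat$high)
  for (pn in names(phases)) for (ln in names(levels_)) {
    sel <- phases[[pn]] & levels_[[ln]]
    if (!any(sel)) {
      rows[[paste(pn, ln)]] <- tibble::tibble(
        phase = pn, level = ln, n = 0L,
        mpe = NA_real_, mpe_low = NA_real_, mpe_high = NA_real_,
        rmse = NA_real_, rmse_low = NA_real_, rmse_high = NA_real_)
      next
    }
    m <- mpe(pe_all[sel], method = method, B = B, seed = seed)
    r <- rmse(pe_all[sel], method = method, B = B, seed = seed)
    rows[[paste(pn, ln)]] <- tibble::tibble(
      phase = pn, level = ln, n = m$n,
      mpe = m$estimate, mpe_low = m$conf_low, mpe_high = m$conf_high,
      rmse = r$estimate, rmse_low = r$conf_low, rmse_high = r$conf_high)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gc_pe_table", class(out))
  out
}

# stack per-subject simulation matrices into one n_rep x N_obs matrix in
# cohort observation order
stack_sims <- function(mats) {
  do.call(cbind, mats)
}

#' Normalized prediction distribution errors
#'
#' For each subject, `n_sim` replicate observation vectors are simulated
#' under the locked model; observed and simulated vectors are decorrelated
#' with the empirical simulation mean and covariance (inverse lower
#' Cholesky factor), and each decorrelated observation is ranked within
#' its decorrelated simulated distribution.  The rank is mapped through
#' `(count + 0.5) / (n_sim + 1)` (which also keeps boundary ranks off 0
#' and 1) and then through the standard-normal quantile function; under a
#' correct model the NPDE are N(0, 1).  A singular simulation covariance
#' is ridge-regularised (1e-8 on the diagonal) with a warning.
#'
#' Significance tests: Wilcoxon signed-rank for location 0 and the
#' variance test against 1 (reported as the "Fisher variance test" for
#' continuity with the model-validation literature; implemented as the
#' one-sample chi-square variance test).
#'
#' @param cohort an event-record cohort.
#' @param params locked [gc_parameters()].
#' @param n_sim simulation replicates (at least 100; routine use 1000).
#' @param seed master seed; per-subject streams are derived from it, so
#'   the result is invariant under subject reordering.
#' @return A list of class `gc_npde`: `table` (per-observation tibble with
#'   `npde`), `mean`, `variance`, `wilcoxon_p`, `variance_p`, `n_sim`.
#' @export
gc_npde <- function(cohort, params, n_sim = 1000, seed = NULL) {
  if (n_sim < 100) stop("`n_sim` must be at least 100", call. = FALSE)
  spec <- gc_sim_spec(n_replicates = n_sim, seed = seed,
                      include_residual = TRUE, truncate_negative = FALSE)
  subs <- cohort_subjects(cohort)
  mats <- lapply(subs, simulate_subject_core, params = params, spec = spec)
  npde_list <- purrr::map2(subs, mats, function(s, m) {
    y <- s$y
    nj <- length(y)
    mu <- colMeans(m)
    vc <- cov(m)
    L <- tryCatch(t(chol(vc)), error = function(e) {
      warning("singular simulation covariance for subject ", s$id,
              "; ridge-regularised", call. = FALSE)
      t(chol(vc + diag(1e-8, nj)))
    })
    ystar <- forwardsolve(L, y - mu)
    sstar <- forwardsolve(L, t(m) - mu)   # nj x n_sim
    cnt <- rowSums(sstar < ystar)
    qnorm((cnt + 0.5) / (n_sim + 1))
  })
  tab <- purrr::map2_dfr(subs, npde_list, function(s, v)
    tibble::tibble(ID = s$id, TIME = s$times, DV = s$y,
                   phase = phase_of(s$times), npde = v))
  x <- tab$npde
  n <- length(x)
  chi2 <- (n - 1) * var(x)
  var_p <- 2 * min(pchisq(chi2, n - 1), 1 - pchisq(chi2, n - 1))
  structure(list(
    table = tab,
    mean = mean(x),
    variance = var(x),
    wilcoxon_p = suppressWarnings(wilcox.test(x, mu = 0)$p.value),
    variance_p = var_p,
    n_sim = n_sim
  ), class = "gc_npde")
}

#' @export
print.gc_npde <- function(x, ...) {
  cat(sprintf(
    "<gc_npde> %d observations, %d simulations\n  mean %.4f (Wilcoxon p = %.3g)  variance %.4f (variance-test p = %.3g)\n",
    nrow(x$table), x$n_sim, x$mean, x$wilcoxon_p, x$variance, x$variance_p))
  invisible(x)
}

# merge bins with fewer than `min_n` observations into their left
# neighbour (first bin merges right); returns new integer bin ids
merge_small_bins <- function(bin, n_bins, min_n = 5) {
  repeat {
    counts <- tabulate(bin, n_bins)
    present <- which(counts > 0)
    small <- present[counts[present] < min_n]
    if (!length(small) || length(present) <= 1) break
    b <- small[1]
    left <- present[present < b]
    target <- if (length(left)) max(left) else min(present[present > b])
    bin[bin == b] <- target
  }
  bin
}

#' Prediction-corrected visual predictive check
#'
#' Observations and `n_sim` simulated replicates are normalised by the
#' bin-median population prediction (`pcY = Y * median(PRED in bin) /
#' PRED`), binned on time after the start of the most recent dose (or on
#' postnatal age), and compared: per bin the observed 5th/50th/95th
#' percentiles against the simulation-derived 95% confidence intervals of
#' the same percentiles.  Bins with fewer than 5 observations are merged
#' with a neighbour.
#'
#' @param cohort an event-record cohort.
#' @param params locked [gc_parameters()].
#' @param n_sim simulation replicates.
#' @param bins bin edges (h); right-open intervals, last bin extended to
#'   cover all observations.
#' @param bin_on `"time_after_dose"` (default) or `"time"` (postnatal age).
#' @param seed master seed.
#' @return A list of class `gc_pcvpc`: `bins` (per-bin tibble with
#'   observed percentiles and simulated CIs), `coverage` (fraction of
#'   observed bin-percentiles inside their CI), `data` (per-observation
#'   corrected values).
#' @export
gc_pcvpc <- function(cohort, params, n_sim = 1000,
                     bins = c(0, 1, 2, 4, 8, 12, 18, 24, 36),
                     bin_on = c("time_after_dose", "time"), seed = NULL) {
  bin_on <- match.arg(bin_on)
  strat <- gc_stratify(cohort)
  ph <- gc_posthoc(cohort, params)
  pred <- ph$predictions$PRED
  keep <- pred > 0 & (bin_on == "time" | !is.na(strat$tad))
  if (any(!keep))
    warning(sum(!keep), " observation(s) excluded from the prediction ",
            "correction (zero prediction or pre-dose sample)",
            call. = FALSE)
  xvar <- if (bin_on == "time_after_dose") strat$tad else strat$TIME
  spec <- gc_sim_spec(n_replicates = n_sim, seed = seed,
                      include_residual = TRUE, truncate_negative = FALSE)
  sims <- stack_sims(simulate_cohort_matrices(cohort, params, spec))
  y <- strat$DV[keep]; x <- xvar[keep]; p <- pred[keep]
  sims <- sims[, keep, drop = FALSE]
  edges <- sort(unique(c(bins, max(x))))
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  bin[bin == 0] <- 1L
  bin <- merge_small_bins(bin, length(edges))
  qs <- c(0.05, 0.5, 0.95)
  per_bin <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    med_pred <- median(p[sel])
    pcy <- y[sel] * med_pred / p[sel]
    pcsim <- sweep(sims[, sel, drop = FALSE], 2, med_pred / p[sel], `*`)
    obs_q <- quantile(pcy, qs, names = FALSE)
    sim_q <- apply(pcsim, 1, quantile, probs = qs)   # 3 x n_sim
    ci <- apply(sim_q, 1, quantile, probs = c(0.025, 0.975))
    tibble::tibble(
      bin = b, bin_low = min(x[sel]), bin_high = max(x[sel]),
      bin_mid = median(x[sel]), n = sum(sel),
      percentile = c(5, 50, 95),
      observed = obs_q,
      sim_low = ci[1, ], sim_high = ci[2, ])
  })
  bins_tab <- dplyr::bind_rows(per_bin)
  coverage <- mean(bins_tab$observed >= bins_tab$sim_low &
                     bins_tab$observed <= bins_tab$sim_high)
  structure(list(
    bins = bins_tab, coverage = coverage,
    data = tibble::tibble(x = x, dv = y, pred = p, bin = bin),
    bin_on = bin_on, n_sim = n_sim
  ), class = "gc_pcvpc")
}

#' @export
print.gc_pcvpc <- function(x, ...) {
  cat(sprintf(
    "<gc_pcvpc> %d bins, %d simulations; %.0f%% of observed bin-percentiles inside their 95%% CI\n",
    length(unique(x$bins$bin)), x$n_sim, 100 * x$coverage))
  print(x$bins, n = nrow(x$bins))
  invisible(x)
}
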