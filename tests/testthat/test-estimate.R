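# joint -2 log density of one subject, written independently in R for the
# quadrature cross-checks
h_r <- function(eta, s, p) {
  om <- c(p$omega2_cl, p$omega2_vc, p$omega2_vp, p$omega2_eps)
  tv <- typical_values(p, bw = s$bw, ga = s$ga, sd5 = 0)
  ind <- list(cl = tv$cl * exp(eta[1]), vc = tv$vc * exp(eta[2]),
              q = tv$q, vp = tv$vp * exp(eta[3]))
  f <- predict_concentration(
    ind, tibble::tibble(start_time = s$dose_start, amount = s$dose_amt,
                        duration = s$dose_dur),
    s$times, cl_day5_factor = p$theta_sd5)
  sig <- p$sigma_add * exp(eta[4])
  act <- which(om > 0)
  sum(log(2 * pi * sig^2) + (s$y - f)^2 / sig^2) +
    sum(log(2 * pi * om[act]) + eta[act]^2 / om[act])
}

subject_laplace_value <- function(s, p) {
  om <- c(p$omega2_cl, p$omega2_vc, p$omega2_vp, p$omega2_eps)
  tv <- typical_values(p, bw = s$bw, ga = s$ga, sd5 = 0)
  gentacool:::cpp_subject_laplace(
    rep(0, 4), s$y, s$times, s$dose_start, s$dose_amt, s$dose_dur,
    tv$cl, tv$vc, tv$q, tv$vp, p$theta_sd5, 96, om, p$sigma_add)$value
}

test_that("with no random effects the OFV is the exact Gaussian value", {
  p0 <- gc_parameters(omega2_cl = 0, omega2_vc = 0, omega2_vp = 0,
                      omega2_eps = 0)
  coh <- small_cohort(n = 6, seed = 51, params = p0)
  pred <- gc_predict(coh, p0)
  r <- pred$DV - pred$PRED
  exact <- sum(log(2 * pi * p0$sigma_add^2) + r^2 / p0$sigma_add^2)
  expect_equal(gc_ofv(coh, p0), exact, tolerance = 1e-10)
})

test_that("Laplace agrees with adaptive Gauss-Hermite quadrature", {
  # single random effect: tight agreement
  p1 <- gc_parameters(omega2_vc = 0, omega2_vp = 0, omega2_eps = 0)
  coh1 <- small_cohort(n = 3, seed = 52, params = p1)
  subs <- gentacool:::cohort_subjects(coh1)
  d1 <- vapply(subs, function(s) {
    lap <- subject_laplace_value(s, p1)
    agq <- agq_neg2ll(function(eta) h_r(eta, s, p1), active = 1,
                      n_nodes = 41)
    lap - agq
  }, numeric(1))
  expect_lt(sum(abs(d1)), 0.1)

  # three structural random effects (no residual-scale IIV, whose heavy
  # tails are the dominant Laplace error source): cohort |delta OFV| < 1
  p3 <- gc_parameters(omega2_eps = 0)
  coh3 <- small_cohort(n = 4, seed = 53, params = p3)
  d3 <- vapply(gentacool:::cohort_subjects(coh3), function(s) {
    lap <- subject_laplace_value(s, p3)
    agq <- agq_neg2ll(function(eta) h_r(eta, s, p3), active = 1:3,
                      n_nodes = 11)
    lap - agq
  }, numeric(1))
  expect_lt(sum(abs(d3)), 1)

  # full four-effect model: the log-normal residual-scale mixture makes
  # the eta_eps integrand markedly non-Gaussian; the per-subject Laplace
  # error stays below 1 (and is systematically positive)
  p4 <- gc_parameters()
  coh4 <- small_cohort(n = 4, seed = 53, params = p4)
  d4 <- vapply(gentacool:::cohort_subjects(coh4), function(s) {
    lap <- subject_laplace_value(s, p4)
    agq <- agq_neg2ll(function(eta) h_r(eta, s, p4), active = 1:4,
                      n_nodes = 9)
    lap - agq
  }, numeric(1))
  expect_lt(max(abs(d4)), 1)
})

test_that("OFV is invariant to subject relabeling and doubles on
           duplication", {
  p <- gc_parameters()
  coh <- small_cohort(n = 6, seed = 54)
  o <- gc_ofv(coh, p)
  relab <- coh; relab$ID <- relab$ID + 500
  expect_equal(gc_ofv(relab, p), o, tolerance = 1e-9)
  ids <- unique(coh$ID)
  perm <- coh[order(match(coh$ID, rev(ids)), coh$TIME, -coh$EVID), ]
  expect_equal(gc_ofv(perm, p), o, tolerance = 1e-9)
  dup <- dplyr::bind_rows(coh, relab)
  dup <- dup[order(match(dup$ID, unique(dup$ID)), dup$TIME, -dup$EVID), ]
  expect_equal(gc_ofv(dup, p), 2 * o, tolerance = 1e-8)
})

test_that("an all-fixed fit is the estimation-free mode", {
  p <- gc_parameters()
  coh <- small_cohort(n = 5, seed = 55)
  f <- gc_fit(coh, start = p, fixed = gentacool:::ALL_PARAM_NAMES)
  expect_true(f$converged)
  expect_equal(f$ofv, gc_ofv(coh, p), tolerance = 1e-9)
  expect_equal(unlist(f$estimates[gentacool:::ALL_PARAM_NAMES]),
               unlist(p[gentacool:::ALL_PARAM_NAMES]))
  expect_equal(nrow(f$ebes), 5)
})

test_that("empirical-Bayes estimates behave at the limits", {
  p <- gc_parameters()
  coh <- small_cohort(n = 4, seed = 56)
  # a dose-only subject keeps the prior mode
  extra <- dplyr::filter(coh, ID == 1, EVID == 1)
  extra$ID <- 999
  coh2 <- dplyr::bind_rows(coh, extra)
  ph <- gc_posthoc(coh2, p)
  expect_equal(unlist(ph$etas[ph$etas$ID == 999, -1]),
               c(eta_cl = 0, eta_vc = 0, eta_vp = 0, eta_eps = 0))
  # vanishing IIV shrinks all etas to zero
  ptight <- gc_parameters(omega2_cl = 1e-10, omega2_vc = 1e-10,
                          omega2_vp = 1e-10, omega2_eps = 1e-10)
  ph2 <- gc_posthoc(coh, ptight)
  expect_lt(max(abs(unlist(ph2$etas[-1]))), 1e-3)
})

test_that("rich low-noise data recover a subject's random effect", {
  p <- gc_parameters(sigma_add = 0.01, omega2_eps = 1e-8)
  s <- manual_subject(times = c(6.5, 8, 12, 18, 24, 30.5, 32, 36, 48,
                                54.5, 60, 72))
  eta_true <- c(0.3, -0.2, 0.1)
  tv <- typical_values(p, bw = s$bw, ga = s$ga, sd5 = 0)
  ind <- individual_parameters(tv, eta_true[1], eta_true[2], eta_true[3])
  conc <- predict_concentration(ind, manual_doses(s), s$times,
                                cl_day5_factor = p$theta_sd5)
  dv <- apply_residual_error(conc, p, seed = 57)
  coh <- validate_cohort(tibble::tibble(
    ID = 1,
    TIME = c(s$dose_start, s$times),
    EVID = rep(c(1L, 0L), c(length(s$dose_start), length(s$times))),
    AMT = c(s$dose_amt, rep(NA, length(s$times))),
    RATE = c(s$dose_amt / s$dose_dur, rep(NA, length(s$times))),
    DV = c(rep(NA, length(s$dose_start)), dv),
    MDV = rep(c(1L, 0L), c(length(s$dose_start), length(s$times))),
    BW = s$bw, GA = s$ga
  )[order(c(s$dose_start, s$times), -rep(c(1, 0), c(5, 12))), ])
  ph <- gc_posthoc(coh, p)
  expect_lt(abs(ph$etas$eta_cl[1] - eta_true[1]), 0.05)
  expect_lt(abs(ph$etas$eta_vc[1] - eta_true[2]), 0.05)
})

test_that("a constrained fit recovers generating values and lowers the
           OFV from a perturbed start", {
  p <- gc_parameters()
  coh <- small_cohort(n = 16, seed = 58)
  fixed <- setdiff(gentacool:::ALL_PARAM_NAMES,
                   c("cl_pop", "vc_pop", "omega2_cl", "sigma_add"))
  start <- gc_parameters(cl_pop = 1.3, vc_pop = 45)
  f <- gc_fit(coh, start = start, fixed = fixed, n_starts = 1, se = TRUE)
  expect_true(f$converged)
  expect_lt(f$ofv, gc_ofv(coh, start) + 1e-6)
  expect_lte(f$ofv, gc_ofv(coh, p) + 1e-6)   # no worse than the truth
  expect_lt(abs(f$estimates$cl_pop - p$cl_pop) / p$cl_pop, 0.15)
  expect_lt(abs(f$estimates$vc_pop - p$vc_pop) / p$vc_pop, 0.25)
  tab <- tidy(f)
  expect_true(all(is.finite(tab$cv_pct[!tab$fixed])))
  g <- glance(f)
  expect_equal(g$n_subjects, 16)
  expect_true(g$converged)
})

test_that("bootstrap respects seeds and collapses for a single resample", {
  p <- gc_parameters()
  coh <- small_cohort(n = 8, seed = 59)
  fixed <- setdiff(gentacool:::ALL_PARAM_NAMES, c("cl_pop", "sigma_add"))
  # identity resample equals a direct refit
  b1 <- gc_bootstrap(coh, start = p, n_resamples = 1,
                     indices = list(1:8), fixed = fixed)
  f <- gc_fit(coh, start = p, fixed = fixed, n_starts = 1, se = FALSE)
  expect_equal(b1$summary$estimate[b1$summary$parameter == "cl_pop"],
               f$estimates$cl_pop, tolerance = 1e-6)
  expect_equal(b1$summary$conf_low, b1$summary$conf_high)
  # seed reproducibility of the resampling
  b2 <- gc_bootstrap(coh, start = p, n_resamples = 3, seed = 60,
                     fixed = fixed)
  b3 <- gc_bootstrap(coh, start = p, n_resamples = 3, seed = 60,
                     fixed = fixed)
  expect_identical(b2$draws, b3$draws)
  s <- tidy(b2)
  expect_true(all(s$conf_low <= s$estimate & s$estimate <= s$conf_high))
})

test_that("stepwise search with no candidates returns the base model", {
  p <- gc_parameters()
  coh <- small_cohort(n = 5, seed = 61)
  sw <- gc_stepwise(coh, start = p, candidates = list(),
                    fixed = gentacool:::ALL_PARAM_NAMES)
  expect_length(sw$included, 0)
  expect_equal(sw$fit$ofv, gc_ofv(coh, p), tolerance = 1e-9)
})
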