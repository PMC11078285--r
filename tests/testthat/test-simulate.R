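test_that("random-effect draws have the right scale and reproduce", {
  p <- gc_parameters()
  e1 <- draw_random_effects(p, 500, seed = 1)
  e2 <- draw_random_effects(p, 500, seed = 1)
  expect_identical(e1, e2)
  p0 <- gc_parameters(omega2_cl = 0, omega2_vc = 0, omega2_vp = 0,
                      omega2_eps = 0)
  e0 <- draw_random_effects(p0, 10, seed = 2)
  expect_true(all(unlist(e0) == 0))
  big <- draw_random_effects(p, 1e5, seed = 3)
  expect_lt(abs(sd(big$eta_cl) - 0.266) / 0.266, 0.01)
  expect_lt(abs(sd(big$eta_eps) - 0.502) / 0.502, 0.01)
})

test_that("residual error is additive with exp(eta) scaling", {
  p <- gc_parameters()
  pred <- rep(2, 1e5)
  expect_equal(apply_residual_error(pred, gc_parameters(sigma_add = 1e-12),
                                    seed = 4),
               pred, tolerance = 1e-9)
  dv <- apply_residual_error(pred, p, eta_eps = 0, seed = 5)
  expect_lt(abs(sd(dv) - 0.15) / 0.15, 0.01)
  dv2 <- apply_residual_error(pred, p, eta_eps = log(2), seed = 5)
  expect_equal(sd(dv2) / sd(dv), 2, tolerance = 1e-6)
  expect_error(apply_residual_error(-1, p), ">= 0")
})

test_that("negative-value policy truncates only when asked", {
  x <- c(-0.1, 0, 0.5)
  expect_equal(truncate_negative(x, TRUE), c(0, 0, 0.5))
  expect_equal(truncate_negative(x, FALSE), x)
})

test_that("subject simulation reduces to the prediction when noise is off", {
  p0 <- gc_parameters(omega2_cl = 0, omega2_vc = 0, omega2_vp = 0,
                      omega2_eps = 0)
  s <- manual_subject()
  m <- simulate_subject(s, p0, gc_sim_spec(n_replicates = 20, seed = 6,
                                           include_residual = FALSE))
  expect_equal(dim(m), c(20, length(s$times)))
  tv <- typical_values(p0, bw = s$bw, ga = s$ga, sd5 = 0)
  pred <- predict_concentration(tv, manual_doses(s), s$times,
                                cl_day5_factor = p0$theta_sd5)
  for (k in 1:20) expect_equal(unname(m[k, ]), pred)
})

test_that("simulation is reproducible and replicate medians track the
           population prediction", {
  p <- gc_parameters()
  s <- manual_subject()
  spec <- gc_sim_spec(n_replicates = 4000, seed = 7)
  m1 <- simulate_subject(s, p, spec)
  m2 <- simulate_subject(s, p, spec)
  expect_identical(m1, m2)
  tv <- typical_values(p, bw = s$bw, ga = s$ga, sd5 = 0)
  pred <- predict_concentration(tv, manual_doses(s), s$times,
                                cl_day5_factor = p$theta_sd5)
  med <- apply(m1, 2, median)
  expect_lt(max(abs(med - pred) / pred), 0.08)
})

test_that("a subject without doses simulates pure noise with a warning", {
  p <- gc_parameters()
  s <- manual_subject(dose_times = numeric(0))
  s$dose_amt <- numeric(0); s$dose_dur <- numeric(0)
  expect_warning(
    m <- simulate_subject(s, p, gc_sim_spec(n_replicates = 50, seed = 8)),
    "no doses")
  expect_lt(max(abs(colMeans(m))), 0.2)
})

test_that("cohort simulation is invariant to subject order", {
  p <- gc_parameters()
  coh <- small_cohort(n = 6, seed = 9)
  sims <- gc_simulate(coh, p, gc_sim_spec(n_replicates = 50, seed = 10))
  ids <- unique(coh$ID)
  perm <- coh[order(match(coh$ID, rev(ids)), coh$TIME, -coh$EVID), ]
  sims2 <- gc_simulate(perm, p, gc_sim_spec(n_replicates = 50, seed = 10))
  for (id in ids) {
    expect_equal(sims$sim[sims$ID == id], sims2$sim[sims2$ID == id])
  }
})
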