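test_that("prediction-error formulas are exact", {
  expect_equal(prediction_errors(2.0, 1.5), 0.5)
  expect_equal(prediction_errors(c(1, 3), c(2, 1)), c(-1, 2))
  expect_equal(prediction_errors(c(1, 2), c(1, 2)), c(0, 0))
  expect_error(prediction_errors(1:3, 1:2), "equal length")

  expect_equal(mpe(c(0.5, -0.5), conf = FALSE)$estimate, 0)
  m <- mpe(c(1, 1, 1), B = 50, seed = 1)
  expect_equal(m$estimate, 1)
  expect_equal(m$conf_low, 1)
  expect_equal(m$conf_high, 1)
  expect_equal(rmse(c(0.5, -0.5), conf = FALSE)$estimate, 0.5)
  expect_equal(rmse(c(0, 0), conf = FALSE)$estimate, 0)
  expect_equal(rmse(c(3, 4), conf = FALSE)$estimate, sqrt(12.5))
  expect_error(mpe(numeric()), "empty")
})

test_that("RMSE^2 decomposes exactly into bias and variance", {
  set.seed(2)
  for (n in c(2, 7, 40)) {
    pe <- rnorm(n, 0.3, 1.2)
    lhs <- rmse(pe, conf = FALSE)$estimate^2
    rhs <- mpe(pe, conf = FALSE)$estimate^2 + var(pe) * (n - 1) / n
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("bootstrap and t confidence intervals bracket the estimate", {
  set.seed(3)
  pe <- rnorm(60, 0.2, 0.8)
  for (method in c("bootstrap", "t")) {
    m <- mpe(pe, method = method, B = 400, seed = 4)
    r <- rmse(pe, method = method, B = 400, seed = 4)
    expect_lt(m$conf_low, m$estimate); expect_gt(m$conf_high, m$estimate)
    expect_lt(r$conf_low, r$estimate); expect_gt(r$conf_high, r$estimate)
  }
})

test_that("stratification follows the cutoff and post-dose window rules", {
  coh <- small_cohort(n = 6, seed = 71)
  st <- gc_stratify(coh)
  expect_equal(st$low, st$DV <= 1.5)           # boundary inclusive
  expect_equal(st$high, !is.na(st$tad) & st$tad > 0 & st$tad <= 2)
  expect_equal(as.character(st$phase), as.character(phase_of(st$TIME)))
  # counts partition within each phase
  for (ph in unique(st$phase)) {
    sel <- st$phase == ph
    expect_equal(sum(st$low[sel]) + sum(!st$low[sel]), sum(sel))
  }
  # an observation before any dose warns and is not "high"
  pre <- coh[coh$ID == 1 & coh$EVID == 0, ][1, ]
  pre$TIME <- 0.5
  coh2 <- suppressWarnings(
    validate_cohort(dplyr::arrange(dplyr::bind_rows(coh, pre),
                                   match(ID, unique(ID)), TIME,
                                   dplyr::desc(EVID))))
  expect_warning(st2 <- gc_stratify(coh2), "before any dose")
  expect_false(any(st2$high[is.na(st2$tad)]))
})

test_that("the stratified table reports all phase-by-level cells", {
  p <- gc_parameters()
  coh <- small_cohort(n = 10, seed = 72)
  pt <- gc_pe_table(coh, p, B = 100, seed = 73)
  expect_equal(nrow(pt), 9)
  filled <- pt[pt$n > 0, ]
  expect_true(all(filled$rmse >= abs(filled$mpe) - 1e-12))
  expect_true(all(filled$mpe_low <= filled$mpe &
                    filled$mpe <= filled$mpe_high))
  all_row <- pt[pt$phase == "all" & pt$level == "all", ]
  st <- gc_stratify(coh)
  expect_equal(all_row$n, nrow(st))
})

test_that("npde is seed-stable and invariant to subject reordering", {
  p <- gc_parameters()
  coh <- small_cohort(n = 8, seed = 74)
  n1 <- gc_npde(coh, p, n_sim = 300, seed = 75)
  ids <- unique(coh$ID)
  perm <- coh[order(match(coh$ID, rev(ids)), coh$TIME, -coh$EVID), ]
  n2 <- gc_npde(perm, p, n_sim = 300, seed = 75)
  for (id in ids)
    expect_equal(n1$table$npde[n1$table$ID == id],
                 n2$table$npde[n2$table$ID == id])
  expect_equal(n1$mean, n2$mean)
})

test_that("npde is near-null under the true model and detects a 50%
           clearance misspecification", {
  p <- gc_parameters()
  coh <- generate_cohort(gc_design("external"), p, seed = 76)
  nd <- gc_npde(coh, p, n_sim = 600, seed = 77)
  expect_lt(abs(nd$mean), 3 / sqrt(nrow(nd$table)))
  expect_gt(nd$variance, 0.7); expect_lt(nd$variance, 1.35)
  expect_true(all(is.finite(nd$table$npde)))
  wrong <- gc_parameters(cl_pop = 1.5 * p$cl_pop)
  ndw <- gc_npde(coh, wrong, n_sim = 600, seed = 77)
  expect_lt(ndw$wilcoxon_p, 0.01)
})

test_that("pooled npde passes a normality screen on most null replicates", {
  p <- gc_parameters()
  pass <- vapply(1:8, function(k) {
    coh <- generate_cohort(small_design(n = 15), p, seed = 780 + k)
    nd <- gc_npde(coh, p, n_sim = 400, seed = 790 + k)
    suppressWarnings(ks.test(nd$table$npde, "pnorm")$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(pass), 7)
})

test_that("prediction correction is linear and bins stay populated", {
  p <- gc_parameters()
  coh <- generate_cohort(small_design(n = 20), p, seed = 81)
  pc <- gc_pcvpc(coh, p, n_sim = 200, seed = 82)
  expect_true(all(pc$bins$n >= 5))
  # percentile ordering within every bin
  wide <- tidyr::pivot_wider(pc$bins[, c("bin", "percentile", "observed")],
                             names_from = "percentile",
                             values_from = "observed")
  expect_true(all(wide$`5` <= wide$`50` & wide$`50` <= wide$`95`))
  # doubling the observations doubles the observed percentile curves
  coh2 <- coh
  coh2$DV[coh2$EVID == 0] <- 2 * coh2$DV[coh2$EVID == 0]
  pc2 <- gc_pcvpc(coh2, p, n_sim = 200, seed = 82)
  expect_equal(pc2$bins$observed, 2 * pc$bins$observed, tolerance = 1e-9)
  # simulation bands identical because parameters and seed are unchanged
  expect_equal(pc2$bins$sim_low, pc$bins$sim_low)
})

test_that("pcVPC covers its own simulations under the true model", {
  p <- gc_parameters()
  coh <- generate_cohort(gc_design("external"), p, seed = 83)
  pc <- gc_pcvpc(coh, p, n_sim = 400, seed = 84)
  expect_gte(pc$coverage, 0.8)
  g <- glance(pc)
  expect_equal(g$coverage, pc$coverage)
})
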