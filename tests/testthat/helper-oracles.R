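# Independent numerical oracles used to validate the analytic solver and
# the Laplacian likelihood approximation.

# Two-compartment infusion model integrated numerically, segment by
# segment between input breakpoints (deSolve steps over sub-hour
# infusions if integrated in one sweep).  Optionally tracks cumulative
# elimination for mass-balance checks.
ode_oracle <- function(times, doses, cl, vc, q, vp, cl_factor = 1,
                       t_switch = Inf, tol = 1e-13, amounts = FALSE) {
  ds <- doses$start_time; da <- doses$amount; dd <- doses$duration
  brk <- sort(unique(c(0, ds, ds + dd,
                       if (is.finite(t_switch)) t_switch, times)))
  y <- c(0, 0, 0)   # central, peripheral, eliminated
  tcur <- 0
  conc <- numeric(length(times))
  amt <- matrix(0, length(times), 3)
  for (b in brk[brk > 0]) {
    tm <- (tcur + b) / 2
    rate <- sum((ds <= tm & tm < ds + dd) * da / dd)
    clt <- if (tm <= t_switch) cl else cl * cl_factor
    k10 <- clt / vc; k12 <- q / vc; k21 <- q / vp
    rhs <- function(t, yy, p)
      list(c(rate - (k10 + k12) * yy[1] + k21 * yy[2],
             k12 * yy[1] - k21 * yy[2],
             k10 * yy[1]))
    sol <- deSolve::ode(y, c(tcur, b), rhs, NULL, rtol = tol, atol = tol)
    y <- sol[2, 2:4]
    tcur <- b
    hit <- which(abs(times - b) < 1e-12)
    if (length(hit)) {
      conc[hit] <- y[1] / vc
      amt[hit, ] <- rep(y, each = length(hit))
    }
  }
  if (amounts) list(conc = conc, amounts = amt) else conc
}

# Adaptive Gauss-Hermite quadrature of one subject's marginal likelihood:
# mode and curvature located with R's own optimisers (independent of the
# package's inner Newton), then a product-rule quadrature centred there.
# h(eta) is the joint -2 log density; returns -2 log integral exp(-h/2).
agq_neg2ll <- function(h_fun, active, n_nodes = 9) {
  m <- length(active)
  hm <- function(ea) {
    eta <- numeric(4); eta[active] <- ea
    h_fun(eta)
  }
  opt <- optim(numeric(m), hm, method = if (m == 1) "Brent" else "BFGS",
               lower = if (m == 1) -10 else -Inf,
               upper = if (m == 1) 10 else Inf,
               control = list(reltol = 1e-14, maxit = 2000))
  mode <- opt$par
  hstep <- 1e-4
  H <- matrix(0, m, m)
  for (i in 1:m) for (j in i:m) {
    ei <- ej <- numeric(m); ei[i] <- hstep; ej[j] <- hstep
    H[i, j] <- H[j, i] <-
      (hm(mode + ei + ej) - hm(mode + ei - ej) -
         hm(mode - ei + ej) + hm(mode - ei - ej)) / (4 * hstep^2)
  }
  Hhalf <- H / 2                       # curvature of h/2
  L <- t(chol(solve(Hhalf)))           # integration scale
  gh <- statmod::gauss.quad(n_nodes, kind = "hermite")
  grid <- do.call(expand.grid, rep(list(seq_len(n_nodes)), m))
  h0 <- hm(mode)
  total <- 0
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    z <- gh$nodes[idx]
    w <- prod(gh$weights[idx])
    eta <- mode + sqrt(2) * as.vector(L %*% z)
    total <- total + w * exp(-(hm(eta) - h0) / 2 + sum(z^2))
  }
  val <- total * sqrt(2)^m * prod(diag(L))
  -2 * (log(val) - h0 / 2)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-9)), tol)
}
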