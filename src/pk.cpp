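#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Two-compartment kinetics with zero-order infusion input, solved by exact
// state propagation over intervals of constant input rate and constant
// clearance.  State x = (amount central, amount peripheral); within an
// interval dx/dt = M x + u with
//   M = [ -(k10+k12)  k21 ; k12  -k21 ],  u = (rate, 0),
// and the exact update x(t0+dt) = x_p + expm(M dt) (x(t0) - x_p) where
// x_p = -M^{-1} u is the infusion steady state.  expm of the 2x2 matrix is
// built from the hybrid rate constants alpha, beta (negated eigenvalues,
// alpha + beta = k10 + k12 + k21, alpha * beta = k10 * k21); a repeated
// eigenvalue uses the exact limit expm(M dt) = e^{l dt}(I + dt (M - l I)).

struct TwoCpt {
  double k10, k12, k21;
  double m11, m12, m21, m22;
  TwoCpt() : k10(0), k12(0), k21(0), m11(0), m12(0), m21(0), m22(0) {}
  TwoCpt(double cl, double vc, double q, double vp) {
    k10 = cl / vc; k12 = q / vc; k21 = q / vp;
    m11 = -(k10 + k12); m12 = k21; m21 = k12; m22 = -k21;
  }
  void step(double &a1, double &a2, double dt, double rate) const {
    if (dt <= 0.0) return;
    double xp1 = 0.0, xp2 = 0.0;
    if (rate != 0.0) {
      xp1 = rate / k10;
      xp2 = rate * k12 / (k10 * k21);
    }
    double d1 = a1 - xp1, d2 = a2 - xp2;
    double s = k10 + k12 + k21;
    double p = k10 * k21;
    double disc2 = s * s - 4.0 * p;
    double disc = disc2 > 0.0 ? std::sqrt(disc2) : 0.0;
    double e11, e12, e21, e22;
    if (disc > 1e-9 * s) {
      double alpha = 0.5 * (s + disc), beta = 0.5 * (s - disc);
      double ea = std::exp(-alpha * dt), eb = std::exp(-beta * dt);
      double inv = 1.0 / (alpha - beta);
      // expm(M dt) = (eb (M + alpha I) - ea (M + beta I)) / (alpha - beta)
      e11 = (eb * (m11 + alpha) - ea * (m11 + beta)) * inv;
      e12 = (eb - ea) * m12 * inv;
      e21 = (eb - ea) * m21 * inv;
      e22 = (eb * (m22 + alpha) - ea * (m22 + beta)) * inv;
    } else {
      double l = -0.5 * s;
      double el = std::exp(l * dt);
      e11 = el * (1.0 + dt * (m11 - l));
      e12 = el * dt * m12;
      e21 = el * dt * m21;
      e22 = el * (1.0 + dt * (m22 - l));
    }
    a1 = xp1 + e11 * d1 + e12 * d2;
    a2 = xp2 + e21 * d1 + e22 * d2;
  }
};

// Concentration profile for one subject.  Clearance is cl for t <= t_switch
// and cl * cl_factor beyond (piecewise clearance by timeline segmentation
// with amount carry-over).  times sorted ascending, all >= 0; dose i runs
// from ds[i] for dd[i] hours at rate da[i] / dd[i].
static void conc_core(const std::vector<double> &times,
                      const std::vector<double> &ds,
                      const std::vector<double> &da,
                      const std::vector<double> &dd,
                      double cl, double vc, double q, double vp,
                      double cl_factor, double t_switch,
                      std::vector<double> &out) {
  size_t nt = times.size(), nd = ds.size();
  out.assign(nt, 0.0);
  if (nt == 0) return;

  std::vector<double> brk;
  brk.reserve(2 * nd + 1);
  for (size_t i = 0; i < nd; ++i) {
    brk.push_back(ds[i]);
    brk.push_back(ds[i] + dd[i]);
  }
  if (R_FINITE(t_switch) && cl_factor != 1.0) brk.push_back(t_switch);
  std::sort(brk.begin(), brk.end());
  brk.erase(std::unique(brk.begin(), brk.end()), brk.end());

  TwoCpt pre(cl, vc, q, vp);
  TwoCpt post(cl * cl_factor, vc, q, vp);

  double t = 0.0, a1 = 0.0, a2 = 0.0;
  size_t ib = 0;

  auto advance = [&](double t1) {
    if (t1 <= t) return;
    double tm = 0.5 * (t + t1);       // interval contains no breakpoint
    double rate = 0.0;
    for (size_t i = 0; i < nd; ++i)
      if (ds[i] <= tm && tm < ds[i] + dd[i]) rate += da[i] / dd[i];
    const TwoCpt &mod = (tm <= t_switch) ? pre : post;
    mod.step(a1, a2, t1 - t, rate);
    t = t1;
  };

  for (size_t j = 0; j < nt; ++j) {
    double target = times[j];
    while (ib < brk.size() && brk[ib] <= target) {
      if (brk[ib] > t) advance(brk[ib]);
      ++ib;
    }
    advance(target);
    out[j] = a1 / vc;
  }
}

// [[Rcpp::export]]
NumericVector cpp_conc(NumericVector times,
                       NumericVector dose_start, NumericVector dose_amt,
                       NumericVector dose_dur,
                       double cl, double vc, double q, double vp,
                       double cl_factor, double t_switch) {
  std::vector<double> t(times.begin(), times.end());
  std::vector<double> ds(dose_start.begin(), dose_start.end());
  std::vector<double> da(dose_amt.begin(), dose_amt.end());
  std::vector<double> dd(dose_dur.begin(), dose_dur.end());
  std::vector<double> out;
  conc_core(t, ds, da, dd, cl, vc, q, vp, cl_factor, t_switch, out);
  return wrap(out);
}

// Replicate-batched profile: row k uses cl[k], vc[k], vp[k] (q shared).
// [[Rcpp::export]]
NumericMatrix cpp_conc_batch(NumericVector times,
                             NumericVector dose_start, NumericVector dose_amt,
                             NumericVector dose_dur,
                             NumericVector cl, NumericVector vc,
                             double q, NumericVector vp,
                             double cl_factor, double t_switch) {
  int nrep = cl.size(), nt = times.size();
  std::vector<double> t(times.begin(), times.end());
  std::vector<double> ds(dose_start.begin(), dose_start.end());
  std::vector<double> da(dose_amt.begin(), dose_amt.end());
  std::vector<double> dd(dose_dur.begin(), dose_dur.end());
  NumericMatrix out(nrep, nt);
  std::vector<double> buf;
  for (int k = 0; k < nrep; ++k) {
    conc_core(t, ds, da, dd, cl[k], vc[k], q, vp[k], cl_factor, t_switch, buf);
    for (int j = 0; j < nt; ++j) out(k, j) = buf[j];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Laplacian (conditional-mode) approximate marginal -2 log-likelihood.
//
// eta = (eta_cl, eta_vc, eta_vp, eta_eps), log-normal IIV on CL, Vc, Vp and
// on the additive residual SD (sigma_i = sigma * exp(eta_eps)); the joint
// -2 log density of one subject is
//   h(eta) = sum_j [ log(2 pi s^2) + (y_j - f_j(eta))^2 / s^2 ]
//          + sum_{a active} [ log(2 pi w2_a) + eta_a^2 / w2_a ]
// and the Laplace approximation at the conditional mode eta* gives
//   -2 log L = h(eta*) - m log(2 pi) + log det(H/2),  H = hessian of h.
// Residual variance is evaluated at the conditional eta (interaction).

struct SubjData {
  std::vector<double> times, y, ds, da, dd;
  double tvcl, tvvc, tvq, tvvp;
  double cl_factor, t_switch;
};

static double subj_h(const SubjData &d, const double *eta,
                     const double *omega2, double sigma,
                     const std::vector<int> &active) {
  double cl = d.tvcl * std::exp(eta[0]);
  double vc = d.tvvc * std::exp(eta[1]);
  double vp = d.tvvp * std::exp(eta[2]);
  double sig = sigma * std::exp(eta[3]);
  std::vector<double> f;
  conc_core(d.times, d.ds, d.da, d.dd, cl, vc, d.tvq, vp,
            d.cl_factor, d.t_switch, f);
  const double LOG2PI = 1.8378770664093453;
  double s2 = sig * sig;
  double h = 0.0;
  for (size_t j = 0; j < d.y.size(); ++j) {
    double r = d.y[j] - f[j];
    h += LOG2PI + std::log(s2) + r * r / s2;
  }
  for (size_t a = 0; a < active.size(); ++a) {
    int i = active[a];
    h += LOG2PI + std::log(omega2[i]) + eta[i] * eta[i] / omega2[i];
  }
  if (!std::isfinite(h)) h = 1e12;
  return h;
}

// [[Rcpp::export]]
double cpp_subject_h(NumericVector eta, NumericVector y, NumericVector times,
                     NumericVector dose_start, NumericVector dose_amt,
                     NumericVector dose_dur,
                     double tvcl, double tvvc, double tvq, double tvvp,
                     double cl_factor, double t_switch,
                     NumericVector omega2, double sigma) {
  SubjData d;
  d.times.assign(times.begin(), times.end());
  d.y.assign(y.begin(), y.end());
  d.ds.assign(dose_start.begin(), dose_start.end());
  d.da.assign(dose_amt.begin(), dose_amt.end());
  d.dd.assign(dose_dur.begin(), dose_dur.end());
  d.tvcl = tvcl; d.tvvc = tvvc; d.tvq = tvq; d.tvvp = tvvp;
  d.cl_factor = cl_factor; d.t_switch = t_switch;
  std::vector<int> active;
  for (int i = 0; i < 4; ++i) if (omega2[i] > 0) active.push_back(i);
  double e[4] = {eta[0], eta[1], eta[2], eta[3]};
  return subj_h(d, e, REAL(omega2), sigma, active);
}

// small dense Cholesky; returns false if not positive definite
static bool chol_small(int m, double A[4][4], double L[4][4]) {
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j) L[i][j] = 0.0;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i][j];
      for (int k = 0; k < j; ++k) s -= L[i][k] * L[j][k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i][i] = std::sqrt(s);
      } else {
        L[i][j] = s / L[j][j];
      }
    }
  }
  return true;
}

static void solve_chol(int m, double L[4][4], const double *b, double *x) {
  double z[4];
  for (int i = 0; i < m; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i][k] * z[k];
    z[i] = s / L[i][i];
  }
  for (int i = m - 1; i >= 0; --i) {
    double s = z[i];
    for (int k = i + 1; k < m; ++k) s -= L[k][i] * x[k];
    x[i] = s / L[i][i];
  }
}

static void fd_grad_hess(const SubjData &d, const double *eta0,
                         const double *omega2, double sigma,
                         const std::vector<int> &active,
                         double *g, double H[4][4], double hstep) {
  int m = (int)active.size();
  double e[4];
  double f0 = subj_h(d, eta0, omega2, sigma, active);
  std::vector<double> fp(m), fm(m);
  for (int a = 0; a < m; ++a) {
    int i = active[a];
    std::copy(eta0, eta0 + 4, e);
    e[i] = eta0[i] + hstep; fp[a] = subj_h(d, e, omega2, sigma, active);
    e[i] = eta0[i] - hstep; fm[a] = subj_h(d, e, omega2, sigma, active);
    g[a] = (fp[a] - fm[a]) / (2.0 * hstep);
    H[a][a] = (fp[a] - 2.0 * f0 + fm[a]) / (hstep * hstep);
  }
  for (int a = 0; a < m; ++a)
    for (int b = a + 1; b < m; ++b) {
      int i = active[a], j = active[b];
      std::copy(eta0, eta0 + 4, e);
      e[i] += hstep; e[j] += hstep;
      double fpp = subj_h(d, e, omega2, sigma, active);
      std::copy(eta0, eta0 + 4, e);
      e[i] += hstep; e[j] -= hstep;
      double fpm = subj_h(d, e, omega2, sigma, active);
      std::copy(eta0, eta0 + 4, e);
      e[i] -= hstep; e[j] += hstep;
      double fmp = subj_h(d, e, omega2, sigma, active);
      std::copy(eta0, eta0 + 4, e);
      e[i] -= hstep; e[j] -= hstep;
      double fmm = subj_h(d, e, omega2, sigma, active);
      H[a][b] = H[b][a] = (fpp - fpm - fmp + fmm) / (4.0 * hstep * hstep);
    }
}

// Newton with Levenberg damping and backtracking on the penalized joint
// objective; returns the Laplace -2 log L contribution and the mode.
static double subj_laplace(const SubjData &d, const double *omega2,
                           double sigma, double *eta_io, bool &ok) {
  std::vector<int> active;
  for (int i = 0; i < 4; ++i) if (omega2[i] > 0) active.push_back(i);
  int m = (int)active.size();
  double eta[4] = {0, 0, 0, 0};
  for (int a = 0; a < m; ++a) eta[active[a]] = eta_io[active[a]];

  double h = subj_h(d, eta, omega2, sigma, active);
  ok = true;
  if (m == 0) {
    return h;  // no random effects: exact Gaussian -2 log-likelihood
  }
  double g[4], H[4][4], L[4][4], step[4];
  // two damped-Newton phases: a coarse finite-difference step locates the
  // mode, a finer step then polishes it so that the (non-stationary)
  // log-determinant term is evaluated at a mode reproducible to ~1e-9 —
  // this keeps the summed objective smooth enough for quasi-Newton outer
  // optimisation
  const double phase_hstep[2] = {1e-4, 1e-5};
  const double phase_gtol[2] = {1e-6, 3e-9};
  const int phase_maxit[2] = {60, 8};
  for (int ph = 0; ph < 2; ++ph) {
    for (int it = 0; it < phase_maxit[ph]; ++it) {
      fd_grad_hess(d, eta, omega2, sigma, active, g, H, phase_hstep[ph]);
      double gmax = 0.0;
      for (int a = 0; a < m; ++a) gmax = std::max(gmax, std::fabs(g[a]));
      if (gmax < phase_gtol[ph]) break;
      double mu = 0.0;
      double Hd[4][4];
      bool pd = false;
      for (int tries = 0; tries < 12 && !pd; ++tries) {
        for (int a = 0; a < m; ++a)
          for (int b = 0; b < m; ++b)
            Hd[a][b] = H[a][b] + (a == b ? mu : 0.0);
        pd = chol_small(m, Hd, L);
        if (!pd) mu = (mu == 0.0 ? 1e-4 : mu * 10.0);
      }
      if (!pd) { ok = false; break; }
      solve_chol(m, L, g, step);
      // backtracking line search on h
      double lam = 1.0, hnew = 0.0, enew[4];
      bool improved = false;
      for (int ls = 0; ls < 25; ++ls) {
        std::copy(eta, eta + 4, enew);
        for (int a = 0; a < m; ++a) enew[active[a]] -= lam * step[a];
        hnew = subj_h(d, enew, omega2, sigma, active);
        if (hnew < h + 1e-12) { improved = true; break; }
        lam *= 0.5;
      }
      if (!improved) break;
      std::copy(enew, enew + 4, eta);
      double dh = h - hnew;
      h = hnew;
      if (ph == 0 && dh < 1e-13 && it > 2) break;
      if (ph == 1 && dh < 1e-15) break;
    }
  }
  // curvature at the mode for the Gaussian integral
  fd_grad_hess(d, eta, omega2, sigma, active, g, H, 1e-4);
  double Hhalf[4][4], L2[4][4];
  for (int a = 0; a < m; ++a)
    for (int b = 0; b < m; ++b) Hhalf[a][b] = 0.5 * H[a][b];
  bool pd = chol_small(m, Hhalf, L2);
  if (!pd) {  // ridge the curvature; flag subject
    for (int a = 0; a < m; ++a) Hhalf[a][a] += 1e-6;
    pd = chol_small(m, Hhalf, L2);
    if (!pd) { ok = false; return 1e12; }
  }
  double logdet = 0.0;
  for (int a = 0; a < m; ++a) logdet += 2.0 * std::log(L2[a][a]);
  const double LOG2PI = 1.8378770664093453;
  std::copy(eta, eta + 4, eta_io);
  return h - m * LOG2PI + logdet;
}

// [[Rcpp::export]]
List cpp_subject_laplace(NumericVector eta_start, NumericVector y,
                         NumericVector times,
                         NumericVector dose_start, NumericVector dose_amt,
                         NumericVector dose_dur,
                         double tvcl, double tvvc, double tvq, double tvvp,
                         double cl_factor, double t_switch,
                         NumericVector omega2, double sigma) {
  SubjData d;
  d.times.assign(times.begin(), times.end());
  d.y.assign(y.begin(), y.end());
  d.ds.assign(dose_start.begin(), dose_start.end());
  d.da.assign(dose_amt.begin(), dose_amt.end());
  d.dd.assign(dose_dur.begin(), dose_dur.end());
  d.tvcl = tvcl; d.tvvc = tvvc; d.tvq = tvq; d.tvvp = tvvp;
  d.cl_factor = cl_factor; d.t_switch = t_switch;
  double eta[4] = {eta_start[0], eta_start[1], eta_start[2], eta_start[3]};
  bool ok;
  double val = subj_laplace(d, REAL(omega2), sigma, eta, ok);
  return List::create(_["value"] = val,
                      _["eta"] = NumericVector(eta, eta + 4),
                      _["ok"] = ok);
}

// Sum of per-subject Laplace contributions over a cohort.  `subjects` is a
// list of lists with elements times, y, dose_start, dose_amt, dose_dur;
// tv is n x 4 (TVCL, TVVc, TVQ, TVVp with the day-5 factor excluded from
// TVCL); eta_warm (n x 4) carries warm starts and is returned updated.
// [[Rcpp::export]]
List cpp_cohort_ofv(List subjects, NumericMatrix tv,
                    double cl_factor, double t_switch,
                    NumericVector omega2, double sigma,
                    NumericMatrix eta_warm) {
  int n = subjects.size();
  NumericMatrix etas(n, 4);
  LogicalVector okv(n);
  double ofv = 0.0;
  for (int i = 0; i < n; ++i) {
    List s = subjects[i];
    SubjData d;
    NumericVector times = s["times"], y = s["y"];
    NumericVector ds = s["dose_start"], da = s["dose_amt"], dd = s["dose_dur"];
    d.times.assign(times.begin(), times.end());
    d.y.assign(y.begin(), y.end());
    d.ds.assign(ds.begin(), ds.end());
    d.da.assign(da.begin(), da.end());
    d.dd.assign(dd.begin(), dd.end());
    d.tvcl = tv(i, 0); d.tvvc = tv(i, 1); d.tvq = tv(i, 2); d.tvvp = tv(i, 3);
    d.cl_factor = cl_factor; d.t_switch = t_switch;
    double eta[4] = {eta_warm(i, 0), eta_warm(i, 1),
                     eta_warm(i, 2), eta_warm(i, 3)};
    bool ok;
    double v = subj_laplace(d, REAL(omega2), sigma, eta, ok);
    ofv += v;
    for (int k = 0; k < 4; ++k) etas(i, k) = eta[k];
    okv[i] = ok;
  }
  return List::create(_["ofv"] = ofv, _["etas"] = etas, _["ok"] = okv);
}
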