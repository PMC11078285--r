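---
title: "Methods: the gentamicin hypothermia model and its validation workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the gentamicin hypothermia model and its validation workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`gentacool` implements a population pharmacokinetic model for gentamicin
in (near) term neonates with perinatal asphyxia treated with controlled
therapeutic hypothermia: core temperature is lowered to 33.5 °C for the
first 72 hours of life, rewarming follows until 96 hours, and
normothermia thereafter. Gentamicin — renally cleared, with a narrow
therapeutic window — is dosed as 30-minute intravenous infusions of
4 mg/kg every 24 hours while sepsis cannot be excluded.

The structural model is a linear two-compartment disposition model with
zero-order infusion input. Typical values are allometrically scaled to
body weight with a 70 kg reference, and clearance carries two covariates:
a power term in gestational age (GA) and a categorical "study day 5" step:

$$
TVCL = CL \cdot \left(\frac{BW}{70}\right)^{0.75}
       \cdot \theta_{SD5}^{\,SD5}
       \cdot \left(\frac{GA}{GA_{med}}\right)^{\theta_{CLGA}}, \qquad
TVV_c = V_c \cdot \frac{BW}{70},
$$

with $TVQ$ scaled like clearance and $TVV_p$ like volume. $SD5$ is 1 when
postnatal age exceeds 96 h (normothermia re-established) and 0 before;
the boundary itself belongs to the pre-step period. Clearance is
constant through hypothermia *and* rewarming — the physiological reading
is that renal recovery, not the temperature ramp, drives the step.

Interindividual variability (IIV) is log-normal on $CL$, $V_c$ and $V_p$
(none on $Q$), and the residual error is additive with an individual
log-normal scale:

$$
DV_{ij} = f(t_{ij}; \theta_i) + \sigma_{add}\, e^{\eta_{\epsilon,i}}\,
\varepsilon_{ij}, \qquad \varepsilon_{ij} \sim N(0,1).
$$

The exact NONMEM encoding of "IIV on the additive residual error" is not
published; the multiplicative $e^{\eta_\epsilon}$ scale on
$\sigma_{add}$ is the most common one and is adopted here as a stated
assumption.

Default parameter values (`gc_parameters()`) are the published
model-building estimates: $CL$ 1.89 L/h/70 kg, $V_c$ 32.5 L/70 kg, $Q$
2.01 L/h/70 kg, $V_p$ 30.3 L/70 kg, $\theta_{CLGA}$ 3.0, $\theta_{SD5}$
1.29, additive error 0.15 mg/L, and IIV of 26.6 % (CL), 40.8 %
($V_c$), 53.3 % ($V_p$) and 50.2 % (residual scale), stored as
variances $\omega^2$ under the convention CV% $\approx 100\,\omega$.
`iiv_cv()` reports both that convention and the exact log-normal CV
$100\sqrt{e^{\omega^2}-1}$. The merged-data refit column is available
via `gc_parameters(profile = "merged_refit")`.

# Concentration prediction

Concentrations are computed by exact state propagation: between any two
input breakpoints (infusion start/stop, the 96 h clearance step) the
system $\dot x = Mx + u$ has constant coefficients and the update
$x(t+\Delta) = x_p + e^{M\Delta}(x(t) - x_p)$ is evaluated in closed form
from the hybrid rate constants $\alpha, \beta$
($\alpha+\beta = k_{10}+k_{12}+k_{21}$, $\alpha\beta = k_{10}k_{21}$).
The day-5 clearance step is therefore handled by segmenting the timeline
at 96 h and carrying compartment amounts across the boundary — a dose
infused before the step contributes correctly to concentrations after
it. The degenerate repeated-eigenvalue case ($\alpha = \beta$) uses the
exact limit $e^{M\Delta} = e^{\lambda\Delta}(I + \Delta(M - \lambda I))$
rather than an ODE fallback; for strictly positive parameters the case
is unreachable (it requires $k_{12}=0$ and $k_{10}=k_{21}$) but the
branch keeps the solver total. The test suite checks the analytic path
against independent `deSolve` integration to a relative 1e-6 over
randomized regimens, plus dose linearity, superposition and mass
balance.

# Simulation

`gc_simulate()`/`simulate_subject()` draw fresh random effects and
residuals per replicate on the subject's own design. Random-number
streams are derived per subject from the master seed, so results are
invariant under subject reordering and identical seeds give
bit-identical output. Negative simulated concentrations are **retained**
by default: the rank-based distribution-error diagnostics require the
untruncated residual distribution, and truncation measurably deflates
the null NPDE variance. `truncate_negative()` is applied only for
dosing-evaluation displays (and optionally in the cohort generator).

# The synthetic cohort generator

`generate_cohort()` emulates the observed trial design so that every
downstream stage runs end to end without the original (non-public)
data: 39 ("external" profile) or 47 ("model_building" profile) neonates;
integer GA 36–42 weeks weighted by a discretised normal centred at the
40-week reference (SD 1.4 weeks); birth weight from a truncated normal,
mean 3.3 kg, SD 0.5 kg, bounded to the published 2.09–5.07 kg range;
first dose uniform between 2 and 12 h of postnatal age; 4 mg/kg q24h
30-minute infusions for a treatment duration drawn to match the
published medians (external: median 1.5 days, range 0–4; model-building:
2 days, 0–5; 0 days means a single dose). Sampling times are drawn
without replacement from nominal grids at 24–72 h (hypothermia, 9 slots)
and 78–120 h (later phases, 6 slots), with a Binomial split targeting
the published hypothermic-phase fractions (80 % external, 63 %
model-building) and per-subject counts centred on the published medians
(8 and 14). The exact hour-level protocol of the study is not printed;
these grids are an emulation choice. Nuisance clinical covariates (serum
creatinine, urine output, sex) are generated with **no** kinetic effect,
so covariate selection should reject them.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: assay quantification limits and BLQ
reporting (negative model realisations are kept, see above),
concentration-guided dose adaptation by local TDM protocols, missing
records, covariate–outcome links (renal function is independent of
clearance here), and inter-occasion variability.

# Estimation

The marginal likelihood is approximated per subject by a Laplacian
expansion at the conditional mode of the random effects, with the
residual variance evaluated at those conditional estimates — the
"with interaction" ingredient of FOCE-I. Writing $h(\eta)$ for the joint
$-2\log$ density of a subject's data and random effects,

$$
-2\log L_i \approx h(\eta^*) - m\log 2\pi + \log\det\tfrac{H}{2},
\qquad H = \nabla^2 h(\eta^*),
$$

summed over subjects. With all $\omega^2 = 0$ this is the exact Gaussian
residual likelihood. The inner mode search is a damped Newton iteration
with finite-difference derivatives, run in two phases (step $10^{-4}$,
then $10^{-5}$) so that the mode is reproducible to about $10^{-9}$ —
necessary because the log-determinant term is not stationary at the mode
and mode jitter would otherwise make the outer objective rough.

The outer maximisation works on transformed parameters (log scale for
positive quantities and variances, identity for the GA exponent) and
alternates a quasi-Newton pass (`nlminb` with explicit central-difference
gradients) with a derivative-free Nelder–Mead polish until a full round
improves the objective function value by less than $10^{-3}$; up to
three jittered starts (SD 0.1 on the transformed scale) guard against
local optima. Standard errors come from the observed-information
Hessian with delta-method mapping to the natural scale; when the
information matrix is ill-conditioned they are reported as `NA` and
`gc_bootstrap()` is the fallback.

Accuracy of the Laplacian scheme was cross-checked against adaptive
Gauss–Hermite quadrature: agreement is within 0.1 OFV units for a
single random effect and within 1 unit per small cohort for the three
structural effects. The full model adds the $\omega_\epsilon = 0.502$
residual-scale effect, whose log-normal mixture makes the
$\eta_\epsilon$ integrand distinctly non-Gaussian; the per-subject
Laplace error is then of order 0.5 (systematically positive). Any
conditional-mode implementation of this model shares that property; it
cancels almost entirely in the likelihood-ratio differences used for
covariate selection.

`gc_posthoc()` is the estimation-free mode: population parameters stay
locked, each subject's random effects are set to their conditional mode,
and both population (`PRED`, $\eta = 0$) and individual (`IPRED`)
predictions are returned. A subject without observations keeps the prior
mode $\eta = 0$ exactly.

Stepwise covariate selection uses forward inclusion at a drop in
objective function value of at least 3.8 (the published first-stage
threshold) and backward elimination at 10.83 ($P < 0.001$). Continuous
candidates enter clearance as $(\mathrm{cov}/\mathrm{median})^\theta$,
categorical ones as $\theta^{\mathrm{indicator}}$, matching the
published GA and day-5 forms. The bootstrap resamples subjects with
replacement (the resample count was not published; 1000 unstratified is
the default), refits each resample, and reports percentile 2.5/97.5 %
intervals; failed fits are excluded and counted, with a warning beyond
10 %.

# The validation battery

*Prediction errors.* $PE = \text{predicted} - \text{observed}$ with
population predictions, so over-prediction is positive;
$MPE$ (bias) and $RMSE$ (precision) follow, satisfying the exact
identity $RMSE^2 = MPE^2 + \frac{N-1}{N}\mathrm{var}(PE)$. The published
table prints 95 % CIs without naming a method; a nonparametric
percentile bootstrap (B = 1000) is the default, with a t-based interval
available (`method = "t"`). Strata: low concentrations are observed
values at or below 1.5 mg/L (cutoff inclusive; a trough substitute,
since true troughs were scarce), high concentrations are samples within
2 h *after the start* of the preceding infusion (boundary inclusive).
The strata overlap by construction and a sample can be neither. Phases
are hypothermia (0–72 h, 72 included), rewarming (72–96 h) and
normothermia (> 96 h).

*NPDE.* Per subject, 1000 replicate observation vectors are simulated;
observed and simulated vectors are decorrelated with the empirical
simulation mean and inverse lower Cholesky factor of the simulation
covariance (ridge-regularised at 1e-8 with a warning if singular); each
decorrelated observation's rank among its decorrelated simulations is
mapped through $(r + 0.5)/(K + 1)$ — which also keeps boundary ranks off
0 and 1 — and then through $\Phi^{-1}$. Location is tested by the
Wilcoxon signed-rank test and spread by the one-sample chi-square
variance test against 1 (reported under the "Fisher variance test" name
used in the model-validation literature). A calibration caveat
established by this package's own null experiments: with the published
50.2 % residual-scale IIV the NPDE within a subject are uncorrelated
but *not* independent (a scale mixture survives linear decorrelation),
inflating the sampling variance of the pooled NPDE variance about
2.2-fold over the chi-square reference; the variance test then rejects
a correct model in roughly a quarter of null replicates. With
$\omega_\epsilon = 0$ the test calibrates exactly. Significant variance
tests on this model should therefore be read together with the pcVPC
rather than taken at face value.

*pcVPC.* Prediction-corrected values
$pcY_{ij} = Y_{ij} \cdot \widetilde{PRED}_{bin} / PRED_{ij}$ are formed
for observations and simulations alike, binned by default on time since
the start of the most recent dose (edges 0, 1, 2, 4, 8, 12, 18, 24,
36 h; bins under 5 observations are merged; binning on postnatal age is
available, as the published binning variable is not stated). Per bin the
observed 5th/50th/95th percentiles are compared with the simulation-
derived 95 % CIs of the same percentiles, and the fraction of observed
bin-percentiles inside their band is reported as a coverage summary.
Observations with zero population prediction or before the first dose
are excluded from the correction with a warning.

# Dosing evaluation

`recommend_regimen()` returns the GA-stratified empiric algorithm
(5 mg/kg q36h for GA 36–41 weeks, q24h at 42 weeks, 30-minute
infusions) and errors outside 36–42 weeks, where the model was not
validated. `evaluate_regimen()` simulates virtual subjects on a regimen
and reports per-interval peaks (at infusion end and 0.5 h later, since
post-distribution peak conventions differ) and troughs (immediately
before the next dose), with target-attainment fractions and binomial
Monte-Carlo standard errors. The default targets — peak 8–12 mg/L,
trough below 1 mg/L — are routine gentamicin TDM practice and
deliberately labelled as configuration, not study estimates.

# Problem sizes and reproducibility

The shipped experiments use the design sizes of the study itself: 39
external-profile subjects for the NPDE and pcVPC null checks (20
replicate cohorts with 1000 simulations each for calibration), and the
merged 86-subject design (47 + 39) for simulation-refit recovery and
covariate selection, with single-start refits from jittered starting
values; the type-I screen for noise covariates uses 6 replicate
30-subject cohorts with variance components held at their generating
values. `scripts/acceptance.R` re-runs the main quantities from scratch
under a caller-supplied seed. Every stochastic function takes an
explicit seed and derives per-subject streams from it, so all results
in the tests and the script are bit-reproducible.

# Known limitations

No inter-occasion variability or correlated random-effect blocks; no
saturable elimination or maturation beyond the printed GA power; no
covariates on the volumes; no BLQ/censoring handling; the Laplacian
approximation (not stochastic EM) is the only estimation scheme; and
the synthetic cohorts, however carefully matched to the published
design margins, cannot stand in for the real patients — the package
validates the *machinery* of the workflow, not the clinical conclusions.
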