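---
title: "Methods: population PK of meropenem in children on extracorporeal life support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK of meropenem in children on extracorporeal life support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Meropenem is a hydrophilic carbapenem with low protein binding (<2%) that is
cleared renally. In septic children supported by ECMO and/or continuous
venovenous hemodiafiltration (CVVHDF), both the volume of distribution and the
clearance can shift, and a hemofilter adds an extracorporeal elimination
route. The clinically relevant exposure index for beta-lactams is the
fraction of the dosing interval during which free drug stays above the
pathogen's MIC (fT>MIC). This package implements the full analysis chain for
that setting: a structural PK model with a CRRT effluent compartment,
nonlinear mixed-effects estimation with censored-data handling, covariate
screening, model diagnostics, and Monte-Carlo probability-of-target-attainment
(PTA) simulation that turns the fitted model into dosing recommendations.

## Structural model

Disposition is one-compartment with first-order elimination; infusions enter
as piecewise-constant rates. For a segment with rate $R$ on $[s_0, s_1]$ the
closed-form contribution at time $t \ge s_0$ is

$$C(t) = \frac{R}{CL}\left(e^{-k\,\max(0,\,t-s_1)} - e^{-k\,(t-s_0)}\right),
\qquad k = CL/V_1,$$

and contributions superpose. Steady state over a dosing interval $\tau$ is
computed exactly by geometric accumulation,
$C_{ss}(t) = D(t) + D(\tau)\,e^{-kt}/(1-e^{-k\tau})$ with $D$ the single-dose
solution — exact for linear kinetics, and validated in the test suite against
a simulate-20-doses fallback and an adaptive ODE oracle (relative error
below $10^{-6}$).

Covariates enter clearance and volume as

$$CL = \theta_{CL}\,\Big(\tfrac{BW}{12}\Big)^{0.75}
\big(1 + (eCRCL - 150)\,\theta_{CRCL}\big) \;+\; SC \cdot Q \,[\text{if CRRT}],
\qquad V_1 = \theta_{V1}\,\tfrac{BW}{12},$$

with bodyweight in kg, eCRCL the bedside-Schwartz estimated creatinine
clearance (ml/min/1.73m²), $SC$ the hemofilter sieving coefficient and
$Q = 0.045 \cdot BW$ L/h the effluent (replacement + filtration) flow. $Q$
and the post-CRRT compartment volume $V_2 = 0.025$ L are circuit constants
and are always frozen during estimation. A sigmoidal age-maturation factor
$Age/(Age + Age_{50})$ (Hill coefficient 1) is available as a screenable
covariate but is excluded from the final model. The effluent concentration
follows $dC_2/dt = (Q/V_2)(SC \cdot C_1 - C_2)$; because $V_2/Q \approx$
0.06 h, the effluent tracks $SC \cdot C_1$ at quasi-steady state. We solve
this filter in closed form per infusion segment rather than numerically.

Default parameter values shipped with the package
(`inst/extdata/final_model_params.cfg`): $\theta_{CL} = 7.6$ L/h,
$\theta_{V1} = 21.4$ L, $\theta_{CRCL} = 0.0035$, $SC = 0.257$, log-scale IIV
SDs $\omega_{CL} = 0.557$, $\omega_{V1} = 0.562$, and residual SDs 0.575
(plasma) / 0.284 (effluent) on the natural-log scale.

Two reporting conventions required a decision:

* The printed IIV percentages are taken as $100\,\omega$ on the log scale
  (the common NONMEM reporting shorthand). The alternative reading
  $\omega = \sqrt{\ln(1+CV^2)}$ is available via
  `table4_params(cv_as_sdlog = "lognormal")`.
* The residual-error magnitudes are taken as SDs (not variances) on the log
  scale; with magnitudes near 0.5, the variance reading would imply
  implausibly noisy assays.
* The printed uncertainty interval for the eCRCL slope (0.17–0.61) is on a
  different scale than its point estimate and is ignored; the 0.0035 point
  estimate is used.

The linear eCRCL factor can reach zero for pathological covariate
combinations; it is floored at 0.05 with a warning. The floor can never
trigger for non-negative eCRCL at the default slope.

## Units

mg, L and h package-wide; concentrations mg/L (numerically equal to µg/ml);
eCRCL in ml/min/1.73m² used directly in the linear covariate term; creatinine
µmol/L (converted internally by 88.4 to mg/dL inside the Schwartz formula).

## Estimation

The marginal likelihood integrates the subject likelihood over log-normal
random effects on CL and V1 (diagonal $\Omega$; no eta covariance is
estimated, as none is identifiable at this cohort size). We use a Laplace
expansion about each subject's conditional mode — the same conditional
mode-expansion family as FOCE-I; with a log-additive residual error the
residual variance is constant on the log scale, so the eta-epsilon
interaction is carried entirely by the prediction. Correctness is defined
against an adaptive Gauss–Hermite quadrature oracle (agreement within 0.5
OFV units on randomized small datasets, 0.1 on a two-observation toy).

The inner mode search is a damped Newton iteration on a finite-difference
stencil (step $10^{-4}$, gradient tolerance $10^{-7}$), warm-started per
subject across outer iterations; determinism of the inner solve keeps the
outer objective smooth. The outer optimizer is `nlminb` on transformed
parameters (log for positive parameters, logit for $SC$, a ×100 scaling for
the eCRCL slope, and per-SD scaling for screened covariate coefficients) with
explicit central-difference gradients; optional Nelder–Mead escape rounds
(`polish = TRUE`) and jittered multi-starts (`n_starts`) are available, but
with the scaled parameterization the surface proved effectively unimodal in
our screen and recovery experiments, so a single gradient-based start is the
default. `nlminb`'s "false convergence" stop on this numerically flat
objective is treated as convergence; the suite verifies the fixed-point
property (refitting from the optimum moves the OFV by less than 0.01)
directly.

Censored observations (below the 0.2 mg/L quantification limit) are handled
by three policies: M1 discards them; M3 keeps them as censored-likelihood
contributions $\log \Phi\big((\ln LLOQ - \ln \hat C)/\sigma\big)$ (verified
against numerical integration of the censored log-normal mass to $10^{-8}$);
M6 imputes the first censored record per subject at LLOQ/2 and discards the
rest.

Model comparison uses the objective function value (OFV, $-2\log L$ including
constants; differences are what matter). The stepwise covariate screen adds
candidates one at a time (linear, power or exponential forms centered at the
dataset median), includes the best candidate when the OFV drops by at least
$\chi^2_{0.95}(df)$ (3.84 at 1 df), and at the backward stage eliminates any
included covariate whose removal raises the OFV by less than
$\chi^2_{0.999}(df)$ (10.83 at 1 df). Thresholds are computed from `qchisq`,
not hard-coded.

## Diagnostics

* **GOF / CWRES** — conditional weighted residuals from the first-order
  expansion about the empirical Bayes etas:
  $\mathrm{CWRES} = \mathrm{chol}(G\Omega G' + \Sigma)^{-T}
  (y - f(\hat\eta) + G\hat\eta)$ on the log scale. On self-simulated data the
  suite checks calibration (mean near 0, variance near 1) and invariance to
  concentration unit rescaling.
* **VPC** — replicate datasets simulated on the original design; observed
  5/50/95th percentiles per time bin against their 95% simulation bands.
  Bins are the design's nominal sampling times when few enough, else
  quantile bins. Values below the LLOQ are excluded from the observed *and*
  the simulated percentiles, so censoring distorts both sides identically;
  the censoring signal itself is examined by the categorical VPC, which
  compares observed and simulated below-LLOQ fractions per bin. Study settings: 2000 simulations,
  percentiles {5, 50, 95}. One caveat found while testing: empirical
  quantile bands from few replicates are slightly *narrower* (inward-biased
  order statistics), not wider, so band width should not be used to choose
  the replicate count downward.
* **SIR** — parameter uncertainty by sampling importance resampling: one
  round, multivariate-normal proposal from the inverse OFV Hessian
  (covariance $2H^{-1}$ on the transformed scale), importance weights
  $\exp(-\tfrac12\Delta\mathrm{OFV})/q(\theta)$, resampling without
  replacement (study settings: 2000 samples, 1000 resamples). Validated
  against the analytic posterior of a conjugate Gaussian toy.

## PTA simulation

Virtual populations draw $(\eta_{CL}, \eta_{V1})$ i.i.d. normal. IIV applies
to the intrinsic (renal + non-renal) clearance; the hemofilter clearance
$SC \cdot Q$ is a circuit property added without IIV. Following the study's
simulation rules, scenarios at eCRCL 90 use intrinsic clearance only, while
impaired-renal-function scenarios (eCRCL 30/60) add the CRRT clearance.
Free fraction defaults to 1.0 (protein binding <2%) and is configurable.

The default PTA procedure emulates a full stochastic simulation from the
model *including its residual error*: concentrations are simulated on an
hourly grid over the steady-state dosing interval with log-additive residual
noise, and fT>MIC is the fraction of simulated time points above the MIC.
This choice was driven by evidence: with noise-free model-predicted curves
every reference PTA table cell we checked ran 6–13 percentage points high,
while the residual-inclusive procedure reproduces all of them within ~2
points across seeds; neither the first-dose reading (which collapses
100%-target cells to zero) nor the alternative omega convention reconciles
the noise-free variant. `ruv = FALSE` switches to noise-free curves, whose
MIC crossings are then located *analytically*: at steady state the
concentration on each inter-breakpoint piece has the form $A + Be^{-kt}$, so
each piece holds at most one crossing and fT>MIC is exact (no grid bias).

Common random numbers (one set of eta and residual draws shared across all
scenario cells and MICs) make PTA exactly non-increasing in MIC and
non-decreasing in dose. Default population size 5000 per cell, binomial
Monte-Carlo SE at most 0.71 points. The recommendation rule selects the
least-intensive regimen (20 mg/kg 1 h < 20 mg/kg 3 h < 40 mg/kg 1 h <
40 mg/kg 3 h) whose PTA strictly exceeds 70%.

## Synthetic cohorts and trials

Because the study's raw data are not public, the generator emulates the
design so every stage is testable end to end: 25 septic children, 13 on
ECLS (all flagged ECMO, 9 of the 13 on CRRT — the cohort tables and the
enrollment narrative disagree slightly on these margins, and we follow the
13/12 ECLS split), bodyweight/height/age log-normal with a shared latent
size factor (loading 0.85) matched to the reported medians and IQRs
(bodyweight median 11.5 kg), serum creatinine log-normal by stratum (medians
46 vs 20 µmol/L, so the ECLS stratum has distinctly lower eCRCL), and eCRCL
derived mechanistically from simulated height and creatinine through the
bedside Schwartz formula ($k = 0.413$ by default; the constant is
configurable since source datasets differ). Doses: 20 mg/kg q8h except three
subjects at 40 mg/kg; 12 two-step 3-h infusions, 13 one-hour infusions.

Sampling follows the intensive design: after at least five doses, samples at
pre-dose and 5, 45, 90, 180, 360, 480 min after the end of infusion (a
10-point schedule above 30 kg), with effluent sampled at the same nominal
times for CRRT subjects. Since the late samples extend past the 8-h
interval, the sampled interval is modeled as terminal (no further dose
during sampling); the pre-dose sample is the trough of the preceding
interval. Observations below 0.2 mg/L are flagged BLQ; under the default
parameters the simulated censoring fraction averages near the study's 15.6%.

What the generator does *not* emulate: disease progression, time-varying
renal function or CRRT settings, ECMO circuit adsorption, covariate
measurement error, and any eta or residual correlation structure. Passing
tests therefore demonstrate correctness of the machinery under the stated
statistical assumptions, not robustness of the published model to violations
of them.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own verification design: PTA tables at 5000 subjects
per cell (one shared draw set for the whole grid); parameter recovery over 20
replicate 25-subject trials with $\theta_{CL}$, $\theta_{V1}$, both omegas
and both sigmas estimated and the covariate submodel (eCRCL slope, SC)
conditioned at truth — the recovery criterion concerns CL/V1/IIV, and
conditioning keeps the experiment identifiable at n = 25; the covariate
screen's planted eCRCL effect uses a slope of 0.007 (twice the final
estimate) so the effect is strong enough to survive the backward 10.83
threshold at n = 25, which the study-sized effect (forward ΔOFV ≈ 4–5)
deliberately would not; predictive-check self-consistency over 10 replicate
trials at 200 simulations each; quadrature and ODE oracles on small
randomized problems.

## Known limitations

* One-compartment disposition only (the selected structural model);
  no nonlinear binding or saturable elimination; no inter-occasion
  variability; diagonal $\Omega$ only.
* Laplace/FOCE-I-style approximation shows visible small-sample bias at
  n = 25 with ~56% IIV (clearance medians a few percent low, volume a few
  percent high in the recovery experiment) — inherent to the estimator
  class at this design, and within the recovery tolerances.
* The PTA residual-error convention (hourly grid) is an inference about the
  reference procedure, not a documented fact; both conventions are exposed.
* Continuous (24-h) infusion regimens and PK/PD indices other than fT>MIC
  are out of scope.
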