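---
title: "Population pharmacokinetics of meropenem during ECMO: models, simulation and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of meropenem during ECMO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmopk)
```

# The problem

Critically ill adults supported by extracorporeal membrane oxygenation
(ECMO) often receive meropenem, a carbapenem whose efficacy tracks the
percentage of the dosing interval during which the free plasma
concentration stays above the pathogen's minimum inhibitory concentration
(fT>MIC). The ECMO circuit can alter drug disposition (hemodilution,
sequestration), and renal function in this population spans anuria to
augmented clearance, so standard dosing may miss pharmacodynamic targets.
`ecmopk` implements a complete workflow for this setting: a two-compartment
population model with creatinine clearance and ECMO blood-flow as
covariates, maximum-likelihood estimation of that model from sparse
concentration data, model diagnostics, and Monte Carlo dosing simulation.

# Structural kinetics

Disposition follows a two-compartment model with elimination from the
central compartment and zero-order (constant-rate) drug input over the
infusion duration. With micro-constants $k_{10} = CL/V_c$,
$k_{12} = Q/V_c$, $k_{21} = Q/V_p$, the hybrid rate constants
$\alpha > \beta > 0$ satisfy $\alpha\beta = k_{10}k_{21}$ and
$\alpha + \beta = k_{10} + k_{12} + k_{21}$. The central concentration
during and after one infusion is the standard biexponential closed form;
multiple doses superpose by linearity; and the steady-state profile over
one interval $[0, \tau)$ applies the accumulation factor
$1/(1 - e^{-\lambda\tau})$ to each exponential term. The closed form — not
numerical integration — is the production path everywhere, because the
Monte Carlo layer evaluates tens of millions of concentrations; a stiff ODE
integration exists only inside the test suite as an independent oracle
(agreement to a relative tolerance of $10^{-6}$ is asserted over random
parameter sets and regimens). Parameter sets whose two hybrid rate
constants coincide to within $10^{-12}$ relative are rejected at
construction; they are unreachable for physiological values and excluding
them avoids a repeated-eigenvalue branch in the closed form.

# The population model

The fitted covariate model is linear in each centered covariate:

$$CL_i = \theta_1\,(1 + \theta_2\,(CRCL_i - 49.7))\,e^{\eta_{1i}}, \qquad
V_{c,i} = \theta_3\,(1 + \theta_4\,(LPM_i - 3.7))\,e^{\eta_{2i}},$$

with $V_p$ ($e^{\eta_{3i}}$) and $Q$ (no random effect) covariate-free.
`ecmo_meropenem_model()` returns the final estimates: $\theta_1 = 7.35$
L/h, $\theta_2 = 0.0104$ per ml/min, $\theta_3 = 17.3$ L, $\theta_4 =
0.337$ per L/min, $Q = 14.5$ L/h, $V_p = 12.8$ L; between-subject
variability (BSV) 39.6/48.5/38.8% on CL/Vc/Vp and combined residual error
(0.370 mg/L additive, 4.73% proportional). Percentages follow the
$100\,\omega$ convention, i.e. 39.6% means the log-scale standard
deviation is 0.396 (not the CV $\sqrt{e^{\omega^2}-1}$); the two differ by
under 1% at these magnitudes but the convention is fixed and documented.

Two modelling guards are deliberate:

* **Admissible region.** The linear flow–Vc relation crosses zero at a flow
  of $3.7 - 1/0.337 \approx 0.733$ L/min. Covariate values that drive CL or
  Vc non-positive raise an error rather than being clipped; silent clipping
  would bias downstream target-attainment estimates, and the linear
  covariate form must not be extrapolated to such flows.
* **Centering constants as data.** The centering values 49.7 ml/min and
  3.7 L/min are cohort medians, stored in the model object (and re-derived
  from the data during covariate search) rather than hard-coded.

The random-effect covariance is diagonal: no $\eta$ correlations are part
of the final model, and none are estimated.

# The synthetic cohort

Because the clinical dataset is not publicly deposited, `cohort_spec()` +
`simulate_dataset()` generate cohorts that emulate the study design: 30
subjects, a single dose infused over 3 h (one subject on 0.5 g, the others
on 1 g), seven samples per subject under three fixed sampling schemes
assigned cyclically (1, 2, 3, 1, ...), and a 10/30 continuous renal
replacement therapy (CRRT) split. Covariates are drawn per CRRT stratum
from independent log-normal distributions whose median and interquartile
range match the reported cohort (creatinine clearance 69.6 (42.2–115)
ml/min non-CRRT, 43.4 (31.8–51.0) CRRT; ECMO flow 3.62 (2.62–4.08) and
3.83 (3.47–4.17) L/min): for a log-normal, $\mu = \log(\text{median})$ and
$\sigma = \log(q_{75}/q_{25})/(2\,z_{0.75})$. The log-normal marginal on
$(0,\infty)$ is the simplest distribution consistent with the reported
median/IQR; no joint covariate distribution is reported, so independence is
assumed. Flow draws below 0.8 L/min are resampled (admissibility).

Design choices worth noting:

* Predose (t = 0) samples are recorded as exactly zero and marked
  non-informative (`MDV = 1`): in a single-dose study they contain no
  drug and no residual information, and retaining them as exact zeros in
  the likelihood would spuriously drive the additive error variance to
  zero.
* Observations below the 1 mg/L quantitation limit are flagged (`BLQ`) but
  retained by default; a `censor_blq` switch marks them missing instead
  (the likelihood then conditions on quantifiable observations only).
* Simulated observations driven negative by the additive error are
  truncated at zero and flagged; concentrations are physically
  non-negative.
* Cyclic scheme assignment is deterministic for reproducibility
  (switchable to random); how schemes were allocated in the study is not
  reported.

What the generator does **not** emulate: model misspecification (the data
really come from the fitted model family), assay drift, correlated
covariates, CRRT as a mechanistic elimination pathway (no significant CRRT
effect was found on any PK parameter), or time-varying ECMO flow. Passing
simulation–estimation tests therefore demonstrates internal consistency of
estimator and generator, not correctness of the model for real patients.
One distributional subtlety: even with between-subject variability on CL
only, the end-of-infusion concentration is a *nonlinear* monotone transform
of the log-normal clearance, so its log is measurably left-skewed at large
n — the package's tests assert "log-normal-ish" behaviour through a
quantile–quantile correlation rather than a formal normality test, which
would correctly reject.

# Estimation: FOCE with interaction

`pk_fit()` maximizes the first-order conditional estimation with
interaction (FOCE-I) approximation of the marginal likelihood. Per subject,
an inner damped Gauss–Newton search (finite-difference sensitivities,
gradient norm below $10^{-6}$, started at $\eta = 0$ with warm starts
across outer iterations) finds the posterior mode $\hat\eta_i$; the model
is linearized there, the residual variance is evaluated at the individual
predictions (the "interaction"), and the subject's contribution is
$\log|2\pi V_i| + r_i^\top V_i^{-1} r_i$ with
$V_i = F_i \Omega F_i^\top + \mathrm{diag}(g_i)$ and
$r_i = y_i - f_i(\hat\eta_i) + F_i\hat\eta_i$. The objective includes the
$2\pi$ constants, so its additive constant differs from NONMEM's
convention; all model comparisons are differences, which the convention
does not affect. On one-subject problems the objective agrees with
adaptive-quadrature marginal likelihoods to within 0.003 units across
$\omega \in \{0.1, 0.3, 0.5\}$ (asserted at 0.1 in the tests).

The outer problem runs a box-constrained quasi-Newton (L-BFGS-B) on
transformed parameters — logs for the positive parameters
($\theta_1, \theta_3, V_p, Q, \omega, \sigma$), covariate slopes linear but
standardized by the covariate SD — followed by an unconstrained BFGS
polish. The FOCE surface for 30-subject sparse designs is mildly
multimodal; two mitigations are built in and were chosen after observing
real traps (a "solution" with $Q \to 0.4$ L/h and $\omega_{V_p} > 200\%$):
an optional second start from a moderate-variability variant of the
initial model (`n_starts = 2`), and, inside the stepwise search, a repair
step that refits warm from the parent model whenever a richer model scores
worse than its parent — a certificate of a secondary optimum, since the
parent is nested in it.

Relative standard errors come from the inverse finite-difference Hessian of
the objective (covariance $2H^{-1}$); a singular Hessian yields `NA` RSEs
rather than a failed fit. Eta shrinkage is $100(1 -
\mathrm{SD}(\hat\eta)/\omega)$.

Covariate selection (`stepwise_covariate_search()`) follows forward
inclusion at $\Delta\mathrm{OFV} \ge 6.63$ ($p < 0.01$, 1 df) and backward
elimination retaining only terms whose removal costs more than 10.8
($p < 0.001$), each candidate parameterized as
$\theta\,(1 + s\,(x - \mathrm{median}(x)))$. Collinear candidates
(|r| > 0.99) are dropped with a warning before the search. The
nonparametric bootstrap (`pk_bootstrap()`) resamples subjects with
replacement, refits warm-started from the original estimates, reports
2.5/50/97.5 percentiles, and counts non-converged replicates.

# Diagnostics

`conditional_residuals()` returns CWRES — the FOCE residual vector
decorrelated by the Cholesky factor of $V_i$ — together with population
(`PRED`, $\eta = 0$) and individual (`IPRED`) predictions. Under a correct
model CWRES are approximately standard normal; the test suite asserts mean
within $\pm 0.1$ and SD within $[0.9, 1.1]$ on a study-design cohort.

`pc_vpc()` is a prediction-corrected visual predictive check: `n_sim`
replicate datasets are simulated under the fitted model with the original
design, observations are binned by nominal sampling time (the design has at
most ten distinct nominal times, so data-driven binning is unnecessary),
and within bin $b$ each observed and simulated value is scaled by
$\mathrm{median}(PRED_b)/PRED_{ij}$. Rows with $PRED = 0$ are left
uncorrected, and because the correction applies identically to observed and
simulated values the calibration of the 80% prediction interval (10th–90th
simulated percentiles) is preserved; when all subjects share covariates and
doses the ratio is exactly 1, recovering an ordinary VPC. The additional
variability-correction factor of the published pcVPC formulation (scaling
by bin-wise prediction-interval widths) matters when covariates differ
systematically *across* bins; with per-nominal-time bins and time-constant
covariates it reduces to the prediction correction implemented here. The
headline metric is the fraction of corrected observations inside the 80%
interval.

# Monte Carlo target attainment

`simulate_pta()` and the grid/policy wrappers generate virtual patients:
creatinine clearance uniform within a renal-function group (0–10, 10–25,
25–50, 50–90, 90–130, 130–170 ml/min), ECMO flow fixed at 3.7 L/min
(or varied explicitly in `flow_rate_sensitivity()`), log-normal BSV applied
to CL, Vc and Vp, and Q fixed — no residual (assay) error, because targets
concern true free concentrations. Steady-state profiles are evaluated
analytically on a one-minute grid; fT>MIC uses linear interpolation at
threshold crossings, which bounds the error below 0.05 percentage points
of an interval (asserted against a 0.1-second brute force). By
periodicity, the per-interval percentage equals the 24-h percentage for
q8h/q12h/q24h regimens. The unbound fraction defaults to $f_u = 0.98$
(~2% protein binding) and is a parameter, not a constant. Targets are 40%
fT>MIC, 100% fT>MIC and 100% fT>4×MIC on the MIC grid {0.06, 0.125, 0.25,
0.5, 1, 2, 4, 8, 16} mg/L; a regimen is "optimal" at PTA ≥ 90%. Paired
(common-random-number) cohorts are reused across regimens within a renal
group so that regimen and flow contrasts are not washed out by Monte Carlo
noise. `recommended_regimen_pta()` evaluates a renal dosing policy
(product label by default: >50 ml/min 1 g q8h; 26–50 1 g q12h; 10–25
0.5 g q12h; <10 0.5 g q24h) against a user-supplied MIC frequency
distribution — MIC histograms (e.g. EUCAST) are external data supplied as
a two-column table, never bundled. For this first-simulation mode the
covariate distributions are log-normals matched to the cohort's
median/IQR and exposed as arguments, since the exact distributions used in
the original analysis are not reported.

# Problem sizes and numerical choices

Defaults reflect the study: 30 subjects × 7 samples for estimation
experiments, n = 1000 virtual patients per PTA scenario, 500 simulated
replicates per VPC, bootstrap replicates configurable (the stability check
in the original analysis used 2000; package experiments typically use
hundreds). Time is in hours everywhere (minute grids are `dt = 1/60`),
concentrations in mg/L. Residual variances are floored at $10^{-12}$ in
the likelihood; optimizer box bounds keep $\omega \le 5$ on the log-SD
scale and $\sigma$ positive; all randomness flows from explicit seeds.

# Known limitations

* FOCE-I is an approximation; its small-sample bias on variance components
  is inherited, and the sparse 7-point design estimates the two covariate
  slopes with sampling CVs of roughly 20–45%, so single-dataset slope
  estimates are imprecise (the package's own simulation experiments
  quantify this).
* The flow–Vc relation is linear and valid only above ~0.73 L/min; the
  package refuses, rather than extrapolates, outside it.
* BLQ handling is flag-or-drop (conditioning on quantifiable data); no
  censored-likelihood (M3-style) option.
* One- and three-compartment structural alternatives are not fitted; the
  two-compartment structure is fixed.
* PTA conclusions are conditional on the model and on MIC distributions
  supplied by the user.
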