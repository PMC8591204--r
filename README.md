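# ecmopk

Population pharmacokinetics and dosing simulation of meropenem in
critically ill adults on extracorporeal membrane oxygenation (ECMO).

Meropenem is a time-dependent carbapenem: efficacy tracks **fT>MIC**, the
percentage of the dosing interval during which the free plasma
concentration exceeds the pathogen's minimum inhibitory concentration.
Patients on ECMO combine altered drug distribution with renal function
ranging from anuria to augmented clearance, so fixed dosing can miss
pharmacodynamic targets. `ecmopk` is for pharmacometricians and
clinical-pharmacology researchers who want a self-contained, tested
implementation of the full workflow for this setting:

* **Kinetics** — exact closed-form two-compartment model for zero-order IV
  infusions: single dose, superposition, analytic steady state
  (`conc_single_dose()`, `conc_multidose()`, `steady_state_profile()`,
  `half_lives()`, `vss()`).
* **Population model** — the final covariate model

  `CL = θ1·(1 + θ2·(CRCL − 49.7))`, `Vc = θ3·(1 + θ4·(LPM − 3.7))`,

  with log-normal between-subject variability on CL/Vc/Vp and combined
  additive + proportional residual error (`ecmo_meropenem_model()`,
  `typical_params()`, `individual_params()`). Typical estimates:
  CL 7.35 L/h, Vc 17.3 L, Vp 12.8 L, Q 14.5 L/h (Vss 30.1 L).
* **Synthetic cohorts** — a generator emulating the study design (30
  subjects, single 0.5/1 g dose over 3 h, seven samples under three
  schemes, covariates matched to the cohort's median/IQR), writing
  NONMEM-style CSV (`cohort_spec()`, `simulate_dataset()`,
  `read_pk_dataset()`).
* **Estimation** — first-order conditional estimation with interaction
  (FOCE-I) written from scratch with an Rcpp core: `pk_fit()`,
  `foce_objective()`, likelihood-ratio comparison (`compare_nested()`),
  stepwise covariate selection (ΔOFV ≥ 6.63 forward / > 10.8 backward),
  nonparametric bootstrap.
* **Diagnostics** — CWRES residuals and a prediction-corrected visual
  predictive check (`conditional_residuals()`, `pc_vpc()`).
* **Target attainment** — Monte Carlo PTA over renal-function groups,
  doses, infusion durations, intervals, MIC grids, MIC frequency
  distributions and ECMO flow rates (`simulate_pta()`,
  `regimen_grid_search()`, `recommended_regimen_pta()`,
  `flow_rate_sensitivity()`), with the ≥ 90% PTA optimality rule.

## Worked example

```r
library(ecmopk)

m <- ecmo_meropenem_model()
dat <- simulate_dataset(cohort_spec(), m, seed = 42)   # 30 subjects, 210 samples
fit <- pk_fit(dat, structure = fit_structure(
  data.frame(param = c("CL", "Vc"), cov = c("CRCL", "LPM"),
             ref = c(49.7, 3.7))))
print(fit)
```

```
FOCE-I fit: OFV = 545.788 (30 subjects, 180 observations)
  theta: CL=8.19 Vc=20.1 Vp=11.4 Q=15.9
  slope CRCL on CL = 0.01054 (centered at 49.7)
  slope LPM on Vc = 0.3567 (centered at 3.7)
  omega (%): CL 32.1, Vc 49.6, Vp 34.6 | sigma: add 0.358 mg/L, prop 4.35%
  eta shrinkage (%): CL 1.8, Vc 19.3, Vp 27.8
```

The fixed effects recover the generating values (CL 7.35→8.19 at this
seed, CRCL slope 0.0104→0.0105, flow slope 0.337→0.357) within the
sampling noise of a 30-subject sparse design; 180 of the 210 records are
quantifiable post-dose observations (predose samples are zero by design).

```r
simulate_pta(m, crcl_range = c(50, 90),
             regimen = dosing_regimen(1000, tinf = 3, tau = 8),
             targets = pd_target(mic = 1, fraction = 100),
             n = 1000, seed = 1)
```

```
  dose_mg tinf_h tau_h crcl_lo crcl_hi lpm mic      target    n   pta optimal
1    1000      3     8      50      90 3.7   1 100% fT>MIC 1000 0.946    TRUE
```

i.e. for virtual patients with creatinine clearance 50–90 ml/min on an
ECMO flow of 3.7 L/min, 1 g infused over 3 h every 8 h keeps the free
concentration above 1 mg/L for the whole interval in 94.6% of patients —
an "optimal" regimen under the PTA ≥ 90% rule.

A thin command-line wrapper around the same functions is installed at
`inst/scripts/ecmopk-cli.R` (subcommands `simulate-data`, `fit`,
`bootstrap`, `vpc`, `pta`, `grid`).

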