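# eatrialsim

Simulation-aided design of randomized controlled trials (RCTs) of
EEG-guided anti-seizure treatment in acute brain injury.

Patients with aneurysmal subarachnoid hemorrhage (aSAH) frequently develop
epileptiform activity (EA) — seizures and periodic/rhythmic patterns — on
continuous EEG, and higher EA burden is associated with worse discharge
outcomes. Anti-seizure medications (levetiracetam) and anesthetics
(propofol) are widely used against EA, but no adequately powered RCT
supports this practice, and drug-response heterogeneity makes classical
power calculations unreliable. `eatrialsim` is for trialists and
biostatisticians who want to ground the null hypothesis and the sample-size
calculation of such a trial in a mechanistic model estimated from
observational cohort data, rather than in guessed response rates.

## What the package computes

The pipeline has four modeling stages and a Monte-Carlo trial engine:

1. **EA burden** — binary EA labels on 2-second EEG segments are aggregated
   into the fraction of positive segments per non-overlapping 10-minute
   window; the exposure summary is *E*ₘₐₓ, the maximum mean burden over
   6-hour sliding windows.
2. **Pharmacokinetics** — one-compartment model with closed-form
   superposition: a bolus *D* at *t₀* contributes (*D/V*)·e^(−kₑ(t−t₀)); an
   infusion at rate *R* rises to steady state *R*/(kₑ·V) and decays after
   stopping. *V* is fixed per drug (plasma levels are unobserved), kₑ is
   estimated.
3. **Pharmacodynamics** — Hill suppression of the EA baseline:
   b(t) = b₀·e^(−λt) · (1 − Cʰ/(ED50ʰ + Cʰ)), where ED50 is the
   concentration halving the 10-minute EA burden and *h* the Hill
   coefficient. Per-patient parameters are estimated by minimizing the
   mean-squared error between simulated and observed burden trajectories
   (multi-start Nelder–Mead).
4. **Discharge outcome** — a cross-fitted doubly robust (double-ML,
   partialling-out) estimator with gradient-boosted nuisance models learns
   the effect of (*E*ₘₐₓ, mean drug exposure) on the probability of a poor
   discharge outcome (modified Rankin Scale 4–6), adjusting for baseline
   covariates and PK/PD parameters as confounders; a boosted classifier
   ĝ(*E*ₘₐₓ, exposure, X) predicts outcomes for virtual patients.
5. **Trial engine** — virtual patients are resampled from the cohort,
   randomized to arms (levetiracetam 15/7/3 mg/kg q8h or propofol
   1/0.5/0.25 mg/kg/h, plus placebo, all on top of background standard
   care), their burden trajectories simulated with their own PK/PD
   parameters, outcomes drawn from ĝ, and arms compared with a two-sided
   Welch t-test. Repeating this yields power curves, minimal sample sizes,
   and power as a function of drug potency (ED50 sweeps). The classical
   two-proportion formula is included as an analytic benchmark.

A synthetic cohort generator reproduces the observational cohort's
published covariate distributions (n = 48, 79% female, age median 61,
66.7% treated, ...) with known ground-truth parameters, so every stage is
testable end to end without access to clinical data.

## Worked example

```r
library(eatrialsim)

cohort <- generate_cohort(cohort_config(seed = 42))   # 48 virtual patients
model  <- fit_outcome_model(cohort, seed = 42)        # doubly robust fit
round(model$theta, 3)
#>     e_max mean_conc
#>     0.995    -0.019

design <- trial_design(standard_arms("levetiracetam"), contrast = c(2L, 4L))
probs  <- arm_outcome_probs(cohort, model, design)
round(colMeans(probs), 3)
#> levetiracetam 15 mg/kg q8h  levetiracetam 7 mg/kg q8h
#>                      0.182                      0.185
#>  levetiracetam 3 mg/kg q8h    placebo + standard care
#>                      0.169                      0.230

power_curve(cohort, model, design, n_grid = c(100, 200, 400, 800),
            replicates = 500, seed = 42, probs = probs)
#>   n_per_arm power         se replicates
#> 1       100 0.148 0.01588055        500
#> 2       200 0.188 0.01747318        500
#> 3       400 0.358 0.02143996        500
#> 4       800 0.626 0.02163904        500

find_sample_size(cohort, model, design, replicates = 500, seed = 42,
                 probs = probs)$n
#> [1] 1407
```

Reading: in this synthetic cohort the fitted burden effect (`theta["e_max"]`
≈ 1.0 on the probability scale, i.e. moving *E*ₘₐₓ from 0 to 1 adds ~1 to
P(poor)) drives a poor-outcome difference of about 4.5 percentage points
between the median-dose arm (0.185) and placebo (0.230); detecting an
effect that small at 80% power needs ~1400 patients per arm. The analytic
benchmark `two_proportion_n(0.60, 0.45)` = 173 per group, and
`two_proportion_n(0.90, 0.83)/84` ≈ 4.4 shows how a misspecified null can
understate a published trial's required size several-fold.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/ea-trial-sim.R run --config cfg.yaml --out-dir out/
```

with subcommands `generate`, `fit-pkpd`, `fit-outcome`, `power`,
`sample-size`, `sweep-ed50`, `run` (see `?run_pipeline` for the config).

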