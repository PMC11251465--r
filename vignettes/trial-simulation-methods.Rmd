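---
title: "Mechanistic trial simulation for EEG-guided anti-seizure treatment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic trial simulation for EEG-guided anti-seizure treatment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`eatrialsim` estimates how large a randomized trial of anti-seizure
treatment in aneurysmal subarachnoid hemorrhage (aSAH) would have to be,
by chaining a mechanistic model of drug effect on epileptiform activity
(EA) with a flexible outcome model and a Monte-Carlo trial engine. This
vignette is the package's account of those models: what is assumed, which
knobs matter, how the numerics are handled, and what the synthetic test
bed does and does not establish.

## 1. EA burden and the exposure summary

The pharmacodynamic observable is the *EA burden*: the fraction of
2-second EEG segments labeled epileptiform within consecutive,
non-overlapping 10-minute windows (300 segments per window). Labels are
taken as given — they come from an upstream EEG classifier and the package
deliberately contains no signal processing. `compute_burden()` drops a
trailing partial window rather than padding it: a partial window's
fraction has higher variance and the non-overlapping-window definition
presumes complete windows. Labels are assumed dense; artifact gaps must be
handled upstream.

The exposure summary is `e_max <- compute_emax(burden)`: the maximum mean
burden over 6-hour sliding windows. The slide stride is one 10-minute bin
— the finest stride the burden resolution supports; any coarser stride
could only miss the maximum. Records shorter than 6 h collapse to a single
degenerate window, so `compute_emax` then returns the whole-record mean:
this keeps the output defined and inside [0, 1] for every non-empty
record. E_max is computed over the full monitoring record (not only during
treatment); the treatment-period information enters the outcome model
through the separate exposure covariate instead.

## 2. Pharmacokinetics

Concentration follows a one-compartment model with first-order
elimination, solved in closed form by superposition
(`concentration_profile()`):

* bolus *D* (mg/kg) at *t₀*: adds (*D/V*)·e^(−kₑ(t−t₀)) for *t ≥ t₀*
  (IV administration, absorption treated as instantaneous);
* infusion at rate *R* (mg/kg/h) on [*tₐ*, *t_b*]: adds
  (*R*/(kₑV))·(1−e^(−kₑ(t−tₐ))) during the infusion, decaying as
  e^(−kₑ(t−t_b)) afterwards.

One compartment is adequate at the hours-scale of EA treatment and keeps
the per-patient estimation problem two-dimensional on the PK side. Because
plasma concentrations are not observed, *D/V* and ED50 are jointly
unidentifiable from burden data alone; the distribution volume is
therefore fixed at literature values per drug (levetiracetam 0.6 L/kg,
propofol 4.0 L/kg effective) and only the elimination rate kₑ is
estimated, bounded to one decade around the literature default
(levetiracetam t½ ≈ 7 h → kₑ ≈ 0.099/h; propofol effective t½ ≈ 1 h →
kₑ ≈ 0.69/h). All per-kg dosing cancels body weight out of the
concentration scale, so weight only matters for absolute-mg bookkeeping.

The time grid is the 10-minute burden grid everywhere. The closed form is
verified in the test suite against `deSolve` numeric integration of
dC/dt = input/V − kₑC on random mixed schedules (agreement within 0.1%);
the closed form is right-continuous at a bolus instant.

## 3. Pharmacodynamics and the untreated baseline

Treated burden is modeled as multiplicative Hill suppression of a
decaying baseline:

> b(t) = clip(b₀·e^(−λt), 0, 1) · (1 − C(t)ʰ / (ED50ʰ + C(t)ʰ))

* **b₀** (unitless, [0, 1]): untreated burden at the first EA measurement.
* **λ** (1/h, ≥ 0): spontaneous waning rate of EA over days; λ = 0 gives a
  constant baseline. An exponential captures the typical waxing-off of EA
  after the acute phase with a single parameter.
* **ED50** (mg/L): concentration halving the burden in a 10-minute window
  relative to its untreated level — S(ED50) = 0.5 exactly.
* **h** (Hill coefficient, unitless): steepness of the concentration-effect
  curve.

When two drugs are present their suppression factors multiply
(independent action). Explicit drug–drug interaction is out of scope; the
product form is the neutral default and reduces correctly when either
concentration is zero.

### Per-patient estimation

`fit_pkpd()` minimizes the mean-squared error between simulated and
observed burden over all bins where both exist. The objective is smooth
but can be multimodal in (kₑ, ED50, h), so estimation is multi-start:

* parameters are mapped to bounded ranges through a logistic transform
  (kₑ one decade around its default; ED50 one decade either side of the
  median positive concentration under the default kₑ; h ∈ [0.3, 10];
  b₀ ∈ [0, 1]; λ ∈ [0, 0.1]/h);
* 8 starts — the literature-informed default plus 7 Latin-hypercube points
  (seeded, reproducible) — each refined with Nelder–Mead
  (`reltol` 1e-10, 500 iterations), then the incumbent is polished with
  restarts until no further improvement;
* ties are broken by lowest MSE, then lowest ED50;
* a fit touching its bounds is flagged `at_bounds`; an untreated record
  (no dose events) fits only (b₀, λ) and flags ED50/h non-identifiable.

On noise-free self-generated 10-day records the fitter recovers all five
parameters to well under 1% relative error (test suite); with binomial
label-sampling noise, median ED50 relative error across 50 seeds stays
under 25%.

## 4. Discharge outcome model

The outcome is the discharge modified Rankin Scale dichotomized as good
(0–3) versus poor (4–6). The estimand is the effect of the exposure pair
T = (E_max, mean drug exposure) on P(poor) in a partially linear model,
with baseline covariates and each patient's PK/PD parameters as
confounders X. `fit_outcome_model()` implements the
partialling-out double-ML recipe: K = 5 cross-fitting folds; per fold,
gradient-boosted regressions for E[Y|X] and E[T_j|X] trained on the
complement; θ from the OLS regression of cross-fitted outcome residuals
on exposure residuals, with heteroskedasticity-robust (HC1) standard
errors. Hyperparameters are fixed and recorded (depth 3, 200 trees,
learning rate 0.05, single-threaded deterministic boosting); they are
deliberately conservative for cohort-scale n. Squared-loss
partialling-out on a binary outcome gives θ a linear-probability
interpretation — a burden effect of 0.135 means 13.5 percentage points of
poor-outcome probability per unit E_max. The interactive (AIPW) variant
was considered and not implemented; partialling-out matches the
linear-probability estimand the trial engine consumes.

A separate boosted classifier ĝ(E_max, exposure, X) is fit on the full
data for arm-level prediction; its outputs are probabilities in [0, 1]
and are clipped to [0.01, 0.99] before Bernoulli sampling in trials so no
virtual patient is deterministic. ĝ is not constrained monotone in E_max:
the constraint is clinically plausible but the unconstrained fit lets the
data speak and the trial engine only consumes arm-level averages.

**Exposure standardization.** The second exposure component is the
time-averaged concentration divided by the patient's ED50, summed over
drugs (dimensionless). Raw mg/L would be incomparable across drugs whose
therapeutic ranges differ by a factor of ~50 (levetiracetam ~12 mg/L vs
propofol ~0.2 mg/L); ED50 units put both on a common
suppression-relevant scale.

Cross-fitting hygiene is tested by data poisoning (corrupting fold-k rows
must not move fold-k nuisance predictions) and θ is checked invariant to
affine rescaling of confounders (exact-greedy tree splits are invariant to
monotone feature transforms).

## 5. The simulated trial engine

A trial with per-arm size n proceeds as: draw n virtual patients per arm
uniformly with replacement from the cohort; apply the arm's regimen on top
of the patient's own background standard care (placebo = background care
only) for min(EEG duration, 240 h) — the 10-day institutional cEEG
monitoring window; simulate the expected burden trajectory with the
patient's own PK/PD parameters; evaluate ĝ at the resulting
(E_max, exposure, X); draw the 0/1 outcome; compare the designated arm
pair with a two-sided Welch t-test on the 0/1 outcomes. The t-test (not a
chi-square) is the design's prespecified test; each analysis compares one
designated arm pair, without multiplicity correction across the three
possible pairs.

Because exposures and predicted probabilities are deterministic per
(patient, arm), the engine precomputes the cohort × arm probability
matrix once (`arm_outcome_probs()`); Monte-Carlo replicates then only
resample indices and Bernoulli outcomes, which makes thousands of
replicate trials essentially free.

* `estimate_power()` reports the rejection fraction over R replicates with
  its binomial standard error √(p(1−p)/R).
* `find_sample_size()` walks a doubling grid (50, 100, 200, … up to
  `n_max`) and bisects to the smallest n whose estimated power clears the
  target; the default decision rule is MC-error-adjusted
  (power − 2·SE ≥ target) so a sample size is not declared adequate on
  Monte-Carlo luck — set `adjust_mc = FALSE` for the raw point-estimate
  rule. Non-attainment returns a sentinel with the power achieved at
  `n_max` rather than an error. Seeds per evaluated n derive from the
  master seed, so the search is reproducible.
* `two_proportion_n()` is the classical normal-approximation benchmark;
  the engine is tested to agree with it within 15% on degenerate designs
  with fixed per-arm outcome probabilities.
* `sweep_ed50()` rescales every patient's ED50 for one drug and re-runs
  the power estimate at fixed n, interpolating the multiplier at which
  power crosses the target (log-multiplier linear interpolation): the
  drug-potency level a trial of that size could detect.

The treatment arms mirror practice: levetiracetam 15, 7 or 3 mg/kg every
8 h, propofol 1, 0.5 or 0.25 mg/kg/h continuous infusion, each plus a
placebo-with-standard-care arm. Virtual patients always retain their
observed background dosing — randomization adds the study regimen on top —
so the placebo arm is standard care, not no care. The propofol middle arm
is 0.5 mg/kg/h throughout (the enumerated arm list; a 0.6 mg/kg/h figure
appears once as the observational median and is treated as the
inconsistent value).

## 6. The synthetic cohort generator

`generate_cohort()` produces the test bed the whole pipeline is validated
on. It emulates the observational cohort's published structure:

* n = 48; covariates matched to the printed summaries — age log-normal
  matched to median 61 (IQR 51–74), 79% female, Hunt–Hess probabilities
  (.125, .125, .291, .313, .146), Fisher (0, .042, .708, .250),
  time-to-EEG discrete with median 24 h and Q3 48 h, EEG duration
  log-normal matched to median 183 h (IQR 139–230), 66.7% treated.
  Continuous covariates use log-normal forms because only median and IQR
  are published; moment matching on the log scale reproduces both.
  Body weight (unpublished) defaults to a 75 ± 15 kg truncated normal and
  cancels out of all per-kg pharmacology.
* Per-patient PK/PD heterogeneity: log-normal around literature medians
  (kₑ CV 0.3; ED50 medians 12 mg/L levetiracetam / 0.2 mg/L propofol,
  CV 0.5; Hill median 2, CV 0.3); baseline b₀ ~ Beta(2, 3) and waning
  λ log-normal around 0.005/h (EA subsiding over roughly the first week).
  The ED50 medians sit near the concentrations the observed median doses
  produce, so standard care is partially effective — the regime in which
  dose arms can plausibly separate.
* Background standard care for treated patients: 7 mg/kg levetiracetam at
  jittered q8h intervals (±1 h) and/or a 0.5 mg/kg/h propofol infusion
  episode, mixed 60/20/20 (levetiracetam-only / propofol-only / both).
* Observed burden: the expected trajectory is sampled through the
  binomial observation model (300 Bernoulli labels per 10-minute window).
* Outcomes: a clipped linear-probability model,
  P(poor) = clip(0.30 + 0.135·E_max + β·x + 0.03·exposure, 0.01, 0.99),
  with the default burden effect at 13.5 percentage points per unit E_max
  and a small positive exposure coefficient encoding dose-related harm
  (so more drug helps through burden suppression and hurts through
  exposure — the tension that makes dose-finding non-trivial). mRS is then
  drawn within the good (0–3) or poor (4–6) range. The generator matches
  the estimand of the analysis model by design; that makes recovery tests
  sharp, and means they do not test robustness to outcome-model
  misspecification.

Every draw flows from the single config seed; `covariates_only = TRUE`
skips trajectory simulation for large-n distribution checks. Ground truth
is stored per record and exportable (`export_ground_truth()`).

What the generator does **not** emulate: artifact gaps and missing labels,
EA subtype structure, informative treatment assignment beyond the
covariate-linked mechanisms above, multi-compartment kinetics, and
longer-horizon outcomes. Passing tests therefore demonstrate internal
consistency of the estimation-simulation loop under the stated model, not
performance on real EEG.

## 7. Problem sizes and runtime choices

The test suite validates covariate distributions at n = 10 000
(covariates only), parameter recovery on 10-day single-patient records,
double-ML recovery at n = 1000 over 50 seeds, type-I calibration with
2000 replicate trials at n = 200/arm on the 48-patient default cohort, and
pipeline smoke runs on 10–12-patient cohorts with reduced optimizer
settings. These sizes keep the full suite in the minutes range while
leaving every Monte-Carlo band at 3 standard errors or wider.

## 8. Known limitations

* Appendix-level functional forms of the source pharmacological models are
  reconstructed, not transcribed: the decaying-exponential baseline and
  multiplicative suppression are this package's choices (both
  configurable; λ = 0 recovers a constant baseline).
* V fixed per drug means ED50 estimates are identified only up to the
  concentration scale that V implies; comparisons of ED50 across
  patients are internally consistent, absolute values inherit the
  literature V.
* The linear-probability outcome effect can in principle leave [0, 1];
  clipping bounds it but introduces edge bias when covariate effects are
  extreme. A logistic variant of the generator outcome is a natural
  extension and intentionally not the default, to match the estimand.
* Small-cohort ĝ (boosted trees at n = 48) is high-variance; the trial
  engine's arm contrasts average over the cohort, which damps but does not
  remove that variance. Power estimates condition on the fitted models —
  model-estimation uncertainty is not propagated into the power curves.
* Sequential/adaptive designs, multiplicity-corrected multi-arm analyses
  and longer-term outcomes are out of scope.
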