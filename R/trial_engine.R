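# Monte-Carlo simulated RCTs: virtual-patient resampling, regimen
# application through the mechanistic PK/PD model, outcome drawing from the
# fitted discharge model, Welch t-tests, power curves, minimal-sample-size
# search and ED50 sensitivity sweeps.

#' Treatment regimen for a trial arm
#'
#' @param drug Drug name (`NA` allowed for `placebo`/`fixed`).
#' @param kind `"bolus_q"` (repeated boluses), `"infusion"` (continuous),
#'   `"placebo"` (standard care only), or `"fixed"` (degenerate arm with a
#'   fixed poor-outcome probability `p`, used for analytic calibration).
#' @param dose mg/kg per bolus, or mg/kg/h infusion rate.
#' @param interval_h Bolus interval in hours (default 8, i.e. q8h).
#' @param p Fixed poor-outcome probability for `kind = "fixed"`.
#' @param label Optional arm label.
#' @return Object of class `regimen`.
#' @export
regimen <- function(drug = NA_character_,
                    kind = c("bolus_q", "infusion", "placebo", "fixed"),
                    dose = NA_real_, interval_h = 8, p = NA_real_,
                    label = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("bolus_q", "infusion")) {
    if (!drug %in% DRUGS) stop("regimen needs a valid drug")
    if (!is.finite(dose) || dose <= 0) stop("dose must be positive")
    if (kind == "bolus_q" && (!is.finite(interval_h) || interval_h <= 0))
      stop("interval_h must be positive")
  }
  if (kind == "fixed" && (!is.finite(p) || p < 0 || p > 1))
    stop("fixed regimen needs p in [0, 1]")
  if (is.null(label)) {
    label <- switch(kind,
      bolus_q = sprintf("%s %g mg/kg q%gh", drug, dose, interval_h),
      infusion = sprintf("%s %g mg/kg/h", drug, dose),
      placebo = "placebo + standard care",
      fixed = sprintf("fixed p=%g", p))
  }
  structure(list(drug = drug, kind = kind, dose = dose,
                 interval_h = interval_h, p = p, label = label),
            class = "regimen")
}

#' The four per-drug treatment arms of the simulated trials
#'
#' Levetiracetam arms: 15, 7 and 3 mg/kg q8h plus placebo; propofol arms:
#' 1, 0.5 and 0.25 mg/kg/h continuous infusion plus placebo. Every arm is on
#' top of the patient's background standard care.
#'
#' @param drug `"levetiracetam"` or `"propofol"`.
#' @return List of four [regimen] objects (highest dose first, placebo last).
#' @export
standard_arms <- function(drug = DRUGS) {
  drug <- match.arg(drug)
  if (drug == "levetiracetam") {
    list(regimen(drug, "bolus_q", 15), regimen(drug, "bolus_q", 7),
         regimen(drug, "bolus_q", 3), regimen(kind = "placebo"))
  } else {
    list(regimen(drug, "infusion", 1), regimen(drug, "infusion", 0.5),
         regimen(drug, "infusion", 0.25), regimen(kind = "placebo"))
  }
}

#' Trial design
#'
#' @param arms List of [regimen]s (>= 2).
#' @param n_per_arm Patients per arm (>= 2).
#' @param alpha Two-sided significance level (default 0.05).
#' @param contrast Integer pair: which two arms the primary two-sided Welch
#'   t-test compares (default arms 1 and 2).
#' @param max_duration_h Cap on randomized-treatment duration (default 240 h,
#'   the 10-day cEEG monitoring protocol).
#' @return Object of class `trial_design`.
#' @export
trial_design <- function(arms, n_per_arm = 100L, alpha = 0.05,
                         contrast = c(1L, 2L), max_duration_h = 240) {
  if (length(arms) < 2L) stop("need at least two arms")
  if (!all(vapply(arms, inherits, logical(1), "regimen")))
    stop("arms must be regimen objects")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_per_arm < 2L) stop("n_per_arm must be >= 2")
  if (length(contrast) != 2L || any(contrast < 1L | contrast > length(arms)))
    stop("contrast must index two arms")
  structure(list(arms = arms, n_per_arm = as.integer(n_per_arm),
                 alpha = alpha, contrast = as.integer(contrast),
                 max_duration_h = max_duration_h),
            class = "trial_design")
}

#' Draw a virtual patient from the cohort
#'
#' Uniform draw with replacement; covariates, fitted PK/PD parameters and
#' background dosing are carried along.
#'
#' @param cohort A non-empty cohort (list of patient records).
#' @param n Number of draws.
#' @return For `n = 1` a patient record, otherwise a list of records.
#' @export
sample_virtual_patient <- function(cohort, n = 1L) {
  if (!length(cohort)) stop("cohort is empty")
  idx <- sample.int(length(cohort), n, replace = TRUE)
  if (n == 1L) cohort[[idx]] else cohort[idx]
}

#' Apply a randomized regimen to a patient on top of standard care
#'
#' Builds the randomized dose events over
#' `min(eeg_duration, max_duration_h)`, merges them with the patient's
#' background standard-care doses, and forward-simulates the expected EA
#' burden trajectory with the patient's own PK/PD parameters. Placebo arms
#' retain only the background dosing.
#'
#' @param patient A patient record with `pkpd` parameters.
#' @param reg A [regimen].
#' @param max_duration_h Randomized-treatment duration cap (default 240 h).
#' @return List with `exposure` (list `e_max`, `mean_conc`), `burden`
#'   (expected [burden_series]) and `doses` (combined schedule).
#' @export
apply_regimen <- function(patient, reg, max_duration_h = 240) {
  if (is.null(patient$pkpd)) stop("patient record lacks PK/PD parameters")
  if (reg$kind == "fixed")
    stop("fixed regimens have no pharmacology; used only in degenerate designs")
  dur <- min(patient$covariates$eeg_duration, max_duration_h)
  extra <- switch(reg$kind,
    bolus_q = doses_bolus_q(reg$drug, reg$dose, reg$interval_h, dur),
    infusion = doses_infusion(reg$drug, reg$dose, 0, dur),
    placebo = dose_events())
  bg <- patient$doses
  bg <- bg[bg$time_h < dur, , drop = FALSE]
  all_doses <- rbind(bg, extra)
  all_doses <- all_doses[order(all_doses$time_h), , drop = FALSE]
  rownames(all_doses) <- NULL
  class(all_doses) <- c("dose_events", "data.frame")
  n_bins <- max(36L, floor(dur * 6))
  tt <- (seq_len(n_bins) - 1) / 6
  traj <- burden_series(expected_burden(patient, all_doses, tt))
  list(exposure = list(e_max = compute_emax(traj),
                       mean_conc = mean_std_exposure(patient, all_doses, tt)),
       burden = traj, doses = all_doses)
}

#' Expected poor-outcome probability of every patient under every arm
#'
#' Deterministic precomputation used by the Monte-Carlo trial loop: each
#' cohort patient's exposure under each arm is simulated once and pushed
#' through the outcome model; trial replicates then only resample patients
#' and redraw Bernoulli outcomes.
#'
#' @param cohort Cohort (list of patient records).
#' @param model Fitted [fit_outcome_model] (ignored for `fixed` arms).
#' @param design A [trial_design].
#' @param clip Probability clipping range before Bernoulli sampling
#'   (default `c(0.01, 0.99)`).
#' @return Matrix `length(cohort) x length(arms)` of poor-outcome
#'   probabilities, with arm labels as column names.
#' @export
arm_outcome_probs <- function(cohort, model, design,
                              clip = c(0.01, 0.99)) {
  A <- length(design$arms)
  P <- matrix(NA_real_, length(cohort), A)
  colnames(P) <- vapply(design$arms, `[[`, character(1), "label")
  Xall <- cohort_features(cohort)
  for (a in seq_len(A)) {
    reg <- design$arms[[a]]
    if (reg$kind == "fixed") {
      P[, a] <- reg$p
      next
    }
    ex <- vapply(cohort, function(pt) {
      e <- apply_regimen(pt, reg, design$max_duration_h)$exposure
      c(e$e_max, e$mean_conc)
    }, numeric(2))
    P[, a] <- predict_outcome(model,
                              list(e_max = ex[1, ], mean_conc = ex[2, ]),
                              Xall)
  }
  pmin(pmax(P, clip[1]), clip[2])
}

# Two-sided Welch t-test p-value on two 0/1 outcome vectors; degenerate
# zero-variance cases collapse to p = 1 (equal means) or p = 0.
welch_p <- function(y1, y2) {
  n1 <- length(y1); n2 <- length(y2)
  m1 <- mean(y1); m2 <- mean(y2)
  v1 <- stats::var(y1); v2 <- stats::var(y2)
  se2 <- v1 / n1 + v2 / n2
  if (se2 <= 0) return(if (m1 == m2) 1 else 0)
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(stat), df)
}

#' Simulate one randomized trial
#'
#' For each arm, draws `n_per_arm` virtual patients with replacement,
#' assigns the arm's regimen, and draws each patient's dichotomized
#' discharge outcome as Bernoulli with the model-predicted poor-outcome
#' probability. The primary comparison is a two-sided Welch t-test on the
#' 0/1 outcomes of the design's `contrast` pair; all pairwise p-values are
#' also reported.
#'
#' @inheritParams arm_outcome_probs
#' @param seed Integer seed; the full result is reproducible.
#' @param probs Optional precomputed [arm_outcome_probs] matrix.
#' @return List of class `trial_result`: `arm_poor_rate`, `p_value`
#'   (contrast pair), `pairwise` (matrix of p-values), `n_per_arm`, `seed`.
#' @export
simulate_trial <- function(cohort, model, design, seed = 1L, probs = NULL) {
  if (is.null(probs)) probs <- arm_outcome_probs(cohort, model, design)
  withr::local_seed(as.integer(seed))
  A <- ncol(probs)
  n <- design$n_per_arm
  y <- vector("list", A)
  rate <- numeric(A)
  for (a in seq_len(A)) {
    idx <- sample.int(nrow(probs), n, replace = TRUE)
    y[[a]] <- stats::rbinom(n, 1L, probs[idx, a])
    rate[a] <- mean(y[[a]])
  }
  pw <- matrix(NA_real_, A, A, dimnames = list(colnames(probs), colnames(probs)))
  for (a in seq_len(A - 1)) for (b in (a + 1):A) {
    pw[a, b] <- pw[b, a] <- welch_p(y[[a]], y[[b]])
  }
  structure(list(arm_poor_rate = stats::setNames(rate, colnames(probs)),
                 p_value = pw[design$contrast[1], design$contrast[2]],
                 pairwise = pw, n_per_arm = n, alpha = design$alpha,
                 seed = seed),
            class = "trial_result")
}

#' Monte-Carlo power of a trial design
#'
#' Fraction of `replicates` simulated trials whose primary-contrast
#' two-sided Welch t-test rejects at the design's `alpha`, with the binomial
#' Monte-Carlo standard error.
#'
#' @inheritParams simulate_trial
#' @param n_per_arm Patients per arm (overrides the design's value).
#' @param replicates Number of simulated trials (>= 100).
#' @return List: `power`, `se`, `replicates`, `n_per_arm`, `seed`.
#' @export
estimate_power <- function(cohort, model, design, n_per_arm = design$n_per_arm,
                           replicates = 500L, seed = 1L, probs = NULL) {
  if (replicates < 100L) stop("need at least 100 replicates")
  if (n_per_arm < 2L) stop("n_per_arm must be >= 2")
  if (is.null(probs)) probs <- arm_outcome_probs(cohort, model, design)
  i1 <- design$contrast[1]; i2 <- design$contrast[2]
  withr::local_seed(as.integer(seed))
  rej <- logical(replicates)
  for (r in seq_len(replicates)) {
    idx1 <- sample.int(nrow(probs), n_per_arm, replace = TRUE)
    idx2 <- sample.int(nrow(probs), n_per_arm, replace = TRUE)
    y1 <- stats::rbinom(n_per_arm, 1L, probs[idx1, i1])
    y2 <- stats::rbinom(n_per_arm, 1L, probs[idx2, i2])
    rej[r] <- welch_p(y1, y2) < design$alpha
  }
  p <- mean(rej)
  list(power = p, se = sqrt(p * (1 - p) / replicates),
       replicates = replicates, n_per_arm = n_per_arm, seed = seed)
}

#' Search the minimal per-arm sample size reaching a target power
#'
#' Walks a doubling grid `n = 50, 100, 200, ...` up to `n_max`, then bisects
#' between the last insufficient and first sufficient grid points. By
#' default a sample size counts as sufficient when
#' `power - 2 * MC-SE >= target_power`, guarding against Monte-Carlo error
#' (set `adjust_mc = FALSE` to use the raw point estimate). Seeds for each
#' evaluated `n` derive deterministically from `seed`.
#'
#' @inheritParams estimate_power
#' @param target_power Target power (default 0.80).
#' @param n_max Largest per-arm n considered (default 5000).
#' @param adjust_mc Use the MC-error-adjusted decision rule (default `TRUE`).
#' @return List of class `sample_size_result`: `n` (`NA` if not reached),
#'   `reached`, `power_at_n`, `power_at_n_max` (when not reached), and
#'   `trace` (data frame of every evaluated n with power and SE).
#' @export
find_sample_size <- function(cohort, model, design, target_power = 0.80,
                             n_max = 5000L, replicates = 500L, seed = 1L,
                             adjust_mc = TRUE, probs = NULL) {
  if (target_power <= 0 || target_power >= 1) stop("target_power must be in (0, 1)")
  if (is.null(probs)) probs <- arm_outcome_probs(cohort, model, design)
  trace <- data.frame(n = integer(), power = numeric(), se = numeric())
  eval_n <- function(n) {
    est <- estimate_power(cohort, model, design, n_per_arm = n,
                          replicates = replicates,
                          seed = (seed + n) %% .Machine$integer.max,
                          probs = probs)
    trace[nrow(trace) + 1L, ] <<- list(n, est$power, est$se)
    est
  }
  ok <- function(est) {
    if (adjust_mc) est$power - 2 * est$se >= target_power
    else est$power >= target_power
  }
  grid <- 50L
  lo <- NA_integer_; hi <- NA_integer_; hi_est <- NULL
  prev <- NA_integer_
  while (grid <= n_max) {
    est <- eval_n(grid)
    if (ok(est)) { hi <- grid; hi_est <- est; lo <- prev; break }
    prev <- grid
    grid <- grid * 2L
  }
  if (is.na(hi) && (is.na(prev) || prev < n_max)) {
    # doubling overshot n_max without success: check the boundary itself
    est <- eval_n(n_max)
    if (ok(est)) { hi <- n_max; hi_est <- est; lo <- prev }
  }
  if (is.na(hi)) {
    pmax_ <- trace$power[which.max(trace$n)]
    return(structure(list(n = NA_integer_, reached = FALSE,
                          power_at_n = NA_real_, power_at_n_max = pmax_,
                          n_max = n_max, target_power = target_power,
                          trace = trace, seed = seed),
                     class = "sample_size_result"))
  }
  if (is.na(lo)) lo <- 2L
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2)
    est <- eval_n(mid)
    if (ok(est)) { hi <- mid; hi_est <- est } else lo <- mid
  }
  structure(list(n = hi, reached = TRUE, power_at_n = hi_est$power,
                 se_at_n = hi_est$se, target_power = target_power,
                 trace = trace, seed = seed),
            class = "sample_size_result")
}

#' Closed-form two-proportion sample size (normal approximation)
#'
#' Per-group n for a two-sided level-`alpha` test of two proportions:
#' `n = (z_{1-a/2} sqrt(2 pbar qbar) + z_{1-b} sqrt(p1 q1 + p2 q2))^2 /
#' (p1 - p2)^2`, rounded up.
#'
#' @param p1,p2 Outcome proportions in the two groups, in (0, 1), unequal.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @return Integer per-group sample size.
#' @export
two_proportion_n <- function(p1, p2, alpha = 0.05, power = 0.80) {
  if (any(c(p1, p2) <= 0 | c(p1, p2) >= 1)) stop("p1, p2 must be in (0, 1)")
  if (p1 == p2) stop("p1 and p2 must differ")
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  pbar <- (p1 + p2) / 2
  n <- (za * sqrt(2 * pbar * (1 - pbar)) +
        zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
  as.integer(ceiling(n))
}

#' Power curve over a grid of per-arm sample sizes
#'
#' @inheritParams estimate_power
#' @param n_grid Integer vector of per-arm sample sizes.
#' @return Data frame of class `power_curve`: `n_per_arm`, `power`, `se`,
#'   `replicates`.
#' @export
power_curve <- function(cohort, model, design, n_grid, replicates = 500L,
                        seed = 1L, probs = NULL) {
  if (is.null(probs)) probs <- arm_outcome_probs(cohort, model, design)
  rows <- lapply(n_grid, function(n) {
    est <- estimate_power(cohort, model, design, n_per_arm = n,
                          replicates = replicates,
                          seed = (seed + n) %% .Machine$integer.max,
                          probs = probs)
    data.frame(n_per_arm = n, power = est$power, se = est$se,
               replicates = replicates)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("power_curve", "data.frame")
  out
}

#' Power as a function of drug potency (ED50 sweep)
#'
#' Rescales every patient's ED50 for the design's drug by each multiplier,
#' re-estimates power at a fixed per-arm n, and reports the interpolated
#' multiplier at which the power curve crosses the target (if it does).
#' Large multipliers make the drug ineffective, driving power to the
#' significance level.
#'
#' @inheritParams estimate_power
#' @param drug Drug whose ED50 is rescaled (default: first non-placebo arm's).
#' @param multipliers Positive ED50 multipliers (default `2^(-3:3)`).
#' @param target_power Crossing level to interpolate (default 0.80).
#' @return Data frame of class `ed50_sweep` (`multiplier`, `power`, `se`)
#'   with attribute `crossing` (interpolated multiplier or `NA`).
#' @export
sweep_ed50 <- function(cohort, model, design, n_per_arm = 100L,
                       multipliers = 2^(-3:3), replicates = 500L, seed = 1L,
                       drug = NULL, target_power = 0.80) {
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  if (is.null(drug)) {
    kinds <- vapply(design$arms, `[[`, character(1), "kind")
    drug <- design$arms[[which(kinds != "placebo")[1]]]$drug
  }
  rows <- lapply(seq_along(multipliers), function(i) {
    m <- multipliers[i]
    co <- lapply(cohort, function(r) {
      r$pkpd$drugs[[drug]]$ed50 <- r$pkpd$drugs[[drug]]$ed50 * m
      r
    })
    class(co) <- "ea_cohort"
    est <- estimate_power(co, model, design, n_per_arm = n_per_arm,
                          replicates = replicates, seed = seed)
    data.frame(multiplier = m, power = est$power, se = est$se)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$multiplier), , drop = FALSE]
  crossing <- NA_real_
  pw <- out$power; mu <- log(out$multiplier)
  for (i in seq_len(nrow(out) - 1)) {
    if ((pw[i] - target_power) * (pw[i + 1] - target_power) <= 0 &&
        pw[i] != pw[i + 1]) {
      crossing <- exp(mu[i] + (target_power - pw[i]) *
                        (mu[i + 1] - mu[i]) / (pw[i + 1] - pw[i]))
      break
    }
  }
  class(out) <- c("ed50_sweep", "data.frame")
  attr(out, "crossing") <- crossing
  attr(out, "n_per_arm") <- n_per_arm
  out
}
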