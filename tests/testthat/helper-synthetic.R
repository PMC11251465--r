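# Shared synthetic fixtures, all generated in code under explicit seeds.

# Minimal patient record with controllable PK/PD parameters.
make_test_patient <- function(id = "T001", b0 = 0.6, lam = 0,
                              lev_ed50 = 12, lev_hill = 2, lev_k_e = 0.099,
                              prop_ed50 = 0.2, prop_hill = 2, prop_k_e = 0.69,
                              eeg_duration = 120, doses = dose_events(),
                              mrs = 4) {
  list(id = id,
       covariates = list(age = 61, sex = "F", hunt_hess = 3, fisher = 3,
                         time_to_eeg = 24, eeg_duration = eeg_duration,
                         weight = 75),
       pkpd = list(b0 = b0, lam = lam, drugs = list(
         levetiracetam = list(k_e = lev_k_e, V = 0.6, ed50 = lev_ed50,
                              hill = lev_hill),
         propofol = list(k_e = prop_k_e, V = 4, ed50 = prop_ed50,
                         hill = prop_hill))),
       doses = doses, treated = nrow(doses) > 0, mrs = mrs)
}

# Cohort drawn from a known partially linear (linear-probability) outcome
# model with confounded exposures: the ground truth for effect-recovery and
# calibration checks. `weight` is noise unused by the outcome generator.
make_plm_cohort <- function(n, theta_emax = 0.135, gamma_conc = 0.03,
                            seed = 1) {
  set.seed(seed)
  age <- rnorm(n, 61, 15)
  hh <- sample(1:5, n, TRUE)
  fi <- sample(2:4, n, TRUE)
  sex <- ifelse(runif(n) < 0.79, "F", "M")
  weight <- rnorm(n, 75, 10)
  z1 <- (age - 61) / 15
  z2 <- hh - 3
  e_max <- pmin(pmax(0.35 + 0.08 * z1 + 0.06 * z2 + rnorm(n, 0, 0.25),
                     0.01), 0.99)
  mean_conc <- pmax(0.6 + 0.25 * z2 + rnorm(n, 0, 0.4), 0)
  p <- pmin(pmax(0.20 + theta_emax * e_max + gamma_conc * mean_conc +
                   0.08 * z1 + 0.05 * z2 + 0.03 * (fi - 3), 0.01), 0.99)
  y <- rbinom(n, 1, p)
  co <- lapply(seq_len(n), function(i) {
    r <- make_test_patient(sprintf("S%05d", i), mrs = if (y[i] == 1) 5 else 2)
    r$covariates$age <- age[i]
    r$covariates$sex <- sex[i]
    r$covariates$hunt_hess <- hh[i]
    r$covariates$fisher <- fi[i]
    r$covariates$weight <- weight[i]
    r
  })
  list(cohort = structure(co, class = "ea_cohort"),
       exposures = data.frame(e_max = e_max, mean_conc = mean_conc),
       p_true = p, y = y)
}

# Two-arm design with fixed poor-outcome probabilities (degenerate arms).
fixed_design <- function(p1, p2, n_per_arm = 100L) {
  trial_design(list(regimen(kind = "fixed", p = p1),
                    regimen(kind = "fixed", p = p2)),
               n_per_arm = n_per_arm)
}

# Any cohort works for fixed-probability designs; keep one tiny one around.
tiny_cohort <- function(n = 4) {
  structure(lapply(seq_len(n), function(i)
    make_test_patient(sprintf("C%03d", i))), class = "ea_cohort")
}
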