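# Virtual-patient trials: resampling, regimen pharmacology, Welch testing,
# power estimation, sample-size search, analytic oracle, ED50 sweep.

test_that("virtual patients are uniform draws with replacement", {
  one <- tiny_cohort(1)
  set.seed(1)
  for (i in 1:5) expect_identical(sample_virtual_patient(one)$id, "C001")
  expect_error(sample_virtual_patient(list()), "empty")
  co <- tiny_cohort(10)
  for (i in seq_along(co)) co[[i]]$covariates$age <- 40 + i * 4
  set.seed(2)
  ages <- vapply(sample_virtual_patient(co, 10000), function(r)
    r$covariates$age, numeric(1))
  pop <- vapply(co, function(r) r$covariates$age, numeric(1))
  mc_se <- sd(pop) / sqrt(10000)
  expect_lt(abs(mean(ages) - mean(pop)), 3 * mc_se)
  set.seed(33); a <- sample_virtual_patient(co, 5)
  set.seed(33); b <- sample_virtual_patient(co, 5)
  expect_identical(vapply(a, `[[`, "", "id"), vapply(b, `[[`, "", "id"))
})

test_that("placebo without background care exposes the bare baseline", {
  pt <- make_test_patient(b0 = 0.55, lam = 0)
  res <- apply_regimen(pt, regimen(kind = "placebo"))
  expect_equal(res$exposure$e_max, 0.55, tolerance = 1e-12)
  expect_equal(res$exposure$mean_conc, 0)
  expect_error(apply_regimen(list(covariates = list()), regimen(kind = "placebo")),
               "PK/PD")
})

test_that("higher dose never increases simulated e_max", {
  set.seed(14)
  for (i in 1:5) {
    pt <- make_test_patient(b0 = runif(1, 0.3, 0.9), lam = runif(1, 0, 0.01),
                            lev_ed50 = runif(1, 4, 25),
                            lev_hill = runif(1, 0.8, 4))
    e3 <- apply_regimen(pt, regimen("levetiracetam", "bolus_q", 3))$exposure
    e7 <- apply_regimen(pt, regimen("levetiracetam", "bolus_q", 7))$exposure
    e14 <- apply_regimen(pt, regimen("levetiracetam", "bolus_q", 14))$exposure
    expect_lte(e7$e_max, e3$e_max + 1e-12)
    expect_lte(e14$e_max, e7$e_max + 1e-12)
    expect_gte(e7$mean_conc, e3$mean_conc)
  }
})

test_that("the Welch p-value matches stats::t.test on binary outcomes", {
  set.seed(6)
  for (i in 1:10) {
    y1 <- rbinom(sample(5:80, 1), 1, runif(1, 0.2, 0.8))
    y2 <- rbinom(sample(5:80, 1), 1, runif(1, 0.2, 0.8))
    if (var(y1) == 0 || var(y2) == 0) next
    expect_equal(eatrialsim:::welch_p(y1, y2),
                 t.test(y1, y2)$p.value, tolerance = 1e-12)
  }
  expect_equal(eatrialsim:::welch_p(c(0, 0, 0), c(1, 1, 1)), 0)
  expect_equal(eatrialsim:::welch_p(c(1, 1), c(1, 1)), 1)
})

test_that("simulated trials are reproducible and detect maximal separation", {
  co <- tiny_cohort(6)
  des <- fixed_design(0.5, 0.5, n_per_arm = 30)
  probs <- arm_outcome_probs(co, NULL, des)
  t1 <- simulate_trial(co, NULL, des, seed = 4, probs = probs)
  t2 <- simulate_trial(co, NULL, des, seed = 4, probs = probs)
  expect_identical(t1, t2)
  expect_true(t1$p_value >= 0 && t1$p_value <= 1)
  # forced 0 vs 1 outcome probabilities: rejection from n = 5 on
  des01 <- fixed_design(0, 1, n_per_arm = 5)
  probs01 <- arm_outcome_probs(co, NULL, des01, clip = c(0, 1))
  t01 <- simulate_trial(co, NULL, des01, seed = 1, probs = probs01)
  expect_lt(t01$p_value, 0.05)
  expect_error(trial_design(list(regimen(kind = "placebo"),
                                 regimen(kind = "placebo")), n_per_arm = 1),
               "n_per_arm")
})

test_that("rejection rate under an identical-arm null is near alpha", {
  co <- tiny_cohort(4)
  des <- fixed_design(0.45, 0.45, n_per_arm = 100)
  est <- estimate_power(co, NULL, des, replicates = 1000, seed = 5)
  expect_lt(abs(est$power - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
  expect_equal(est$se, sqrt(est$power * (1 - est$power) / 1000))
})

test_that("power grows with n and with effect size (within MC error)", {
  co <- tiny_cohort(4)
  des <- fixed_design(0.60, 0.45)
  p1 <- estimate_power(co, NULL, des, n_per_arm = 50, replicates = 600, seed = 9)
  p2 <- estimate_power(co, NULL, des, n_per_arm = 200, replicates = 600, seed = 10)
  joint_se <- sqrt(p1$se^2 + p2$se^2)
  expect_gt(p2$power, p1$power - 3 * joint_se)
  des_big <- fixed_design(0.70, 0.35)
  p3 <- estimate_power(co, NULL, des_big, n_per_arm = 50, replicates = 600,
                       seed = 9)
  expect_gt(p3$power, p1$power - 3 * joint_se)
})

test_that("two_proportion_n matches its closed form and the field oracle", {
  # independent reference: stats::power.prop.test solves the same normal
  # approximation without the pooled/unpooled split
  ours <- two_proportion_n(0.60, 0.45)
  ref <- ceiling(power.prop.test(p1 = 0.60, p2 = 0.45, power = 0.80)$n)
  expect_lt(abs(ours - ref), 6)
  expect_equal(ours, 173L)  # frozen from the closed form
  expect_identical(two_proportion_n(0.45, 0.60), ours)  # symmetry
  expect_gt(two_proportion_n(0.5, 0.501), 1e6)          # divergence
  expect_error(two_proportion_n(0.5, 0.5), "differ")
  expect_error(two_proportion_n(0, 0.5), "in \\(0, 1\\)")
})

test_that("find_sample_size is deterministic and returns a sentinel under null", {
  co <- tiny_cohort(4)
  null_des <- fixed_design(0.5, 0.5)
  r0 <- find_sample_size(co, NULL, null_des, n_max = 400, replicates = 300,
                         seed = 3)
  expect_false(r0$reached)
  expect_true(is.na(r0$n))
  expect_lt(r0$power_at_n_max, 0.2)
  des <- fixed_design(0.60, 0.45)
  r1 <- find_sample_size(co, NULL, des, n_max = 1000, replicates = 300, seed = 3)
  r2 <- find_sample_size(co, NULL, des, n_max = 1000, replicates = 300, seed = 3)
  expect_identical(r1, r2)
  expect_true(r1$reached)
})

test_that("ED50 sweep: power decays to alpha as the drug loses potency", {
  skip_if_not_installed("xgboost")
  d <- make_plm_cohort(48, seed = 30)
  # give patients heterogeneous pharmacology and background doses
  set.seed(31)
  co <- lapply(d$cohort, function(r) {
    r$pkpd$b0 <- runif(1, 0.3, 0.9)
    r$pkpd$drugs$levetiracetam$ed50 <- rlnorm(1, log(12), 0.4)
    r
  })
  class(co) <- "ea_cohort"
  m <- fit_outcome_model(co, d$exposures, seed = 1)
  des <- trial_design(standard_arms("levetiracetam"), contrast = c(1L, 4L))
  sw <- sweep_ed50(co, m, des, n_per_arm = 60, multipliers = c(0.25, 100),
                   replicates = 150, seed = 2)
  expect_equal(nrow(sw), 2)
  expect_true(all(sw$power >= 0 & sw$power <= 1))
  # hopeless drug: power within MC noise of the significance level
  expect_lt(sw$power[sw$multiplier == 100], 0.05 + 3 * sqrt(0.05 * 0.95 / 150) + 0.02)
})
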