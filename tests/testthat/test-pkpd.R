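# One-compartment PK closed form, Hill PD, forward simulation, label
# sampling, and MSE parameter estimation.

test_that("bolus concentration follows D/V and the half-life", {
  pk <- pk_params(k_e = 0.2, V = 0.5)
  d <- dose_events("levetiracetam", 0, "bolus", 7)
  expect_equal(concentration_profile(d, pk, 0), 14)
  expect_equal(concentration_profile(d, pk, log(2) / 0.2), 7)
  # zero before the first dose
  d2 <- dose_events("levetiracetam", 5, "bolus", 7)
  expect_equal(concentration_profile(d2, pk, c(0, 4.9)), c(0, 0))
})

test_that("infusion approaches R/(k_e V) steady state and decays after stop", {
  pk <- pk_params(k_e = 0.2, V = 2)
  d <- doses_infusion("propofol", 1, 0, 1000)
  expect_equal(concentration_profile(d, pk, 1000), 2.5, tolerance = 1e-10)
  d2 <- doses_infusion("propofol", 1, 0, 10)
  c10 <- concentration_profile(d2, pk, 10)
  expect_equal(concentration_profile(d2, pk, 10 + log(2) / 0.2),
               c10 / 2, tolerance = 1e-10)
})

test_that("closed-form profiles match numeric ODE integration", {
  set.seed(11)
  pk <- pk_params(k_e = 0.15, V = 0.6)
  times <- seq(0, 48, by = 0.5)
  for (i in 1:10) {
    doses <- random_schedule()
    cf <- concentration_profile(doses, pk, times)
    num <- ode_oracle(doses, pk, times)
    denom <- pmax(cf, max(cf) * 1e-3)
    expect_lt(max(abs(cf - num) / denom), 1e-3)
  }
})

test_that("superposed schedules give the sum of individual profiles", {
  set.seed(5)
  pk <- pk_params(k_e = 0.3, V = 1)
  times <- seq(0, 60, by = 1 / 6)
  a <- random_schedule()
  b <- doses_bolus_q("levetiracetam", 4, 8, 48)
  ab <- rbind(a, b)
  ab <- ab[order(ab$time_h), ]
  class(ab) <- c("dose_events", "data.frame")
  expect_equal(concentration_profile(ab, pk, times),
               concentration_profile(a, pk, times) +
                 concentration_profile(b, pk, times),
               tolerance = 1e-12)
})

test_that("dose validation catches bad schedules", {
  expect_error(pk_params(0, 1), "k_e")
  expect_error(dose_events("levetiracetam", 0, "bolus", -1), "positive")
  expect_error(dose_events(rep("propofol", 2), c(0, 1),
                           c("infusion_stop", "infusion_start"), c(NA, 1)),
               "without")
  expect_error(dose_events(rep("propofol", 2), c(0, 1),
                           rep("infusion_start", 2), c(1, 1)),
               "overlap")
})

test_that("Hill suppression halves at ED50, is monotone, saturates at 1", {
  pd <- pd_params(ed50 = 2, hill = 1, b0 = 0.8)
  expect_identical(hill_suppression(2, pd), 0.5)
  expect_identical(hill_suppression(0, pd), 0)
  expect_equal(hill_suppression(6, pd), 0.75)
  expect_error(hill_suppression(-1, pd), ">= 0")
  for (hill in c(0.5, 1, 3, 8)) {
    pdh <- pd_params(ed50 = 5, hill = hill, b0 = 0.5)
    cc <- sort(runif(50, 0, 100))
    expect_identical(hill_suppression(5, pdh), 0.5)
    expect_true(all(diff(hill_suppression(cc, pdh)) >= 0))
    expect_gt(hill_suppression(1e8, pdh), 0.999)
  }
})

test_that("simulated burden follows baseline decay and suppression", {
  tt <- seq(0, 100, by = 1 / 6)
  pd0 <- pd_params(ed50 = 2, hill = 1.5, b0 = 0.6, lam = 0)
  expect_equal(simulate_burden(pd0, rep(0, length(tt)), tt)$burden,
               rep(0.6, length(tt)))
  expect_equal(simulate_burden(pd0, rep(2, length(tt)), tt)$burden,
               rep(0.3, length(tt)))
  pd1 <- pd_params(ed50 = 2, hill = 1.5, b0 = 0.8, lam = 0.01)
  expect_equal(simulate_burden(pd1, c(0, 0), c(0, 100))$burden[2],
               0.8 * exp(-1), tolerance = 1e-12)
  # higher concentration never increases burden
  set.seed(3)
  for (i in 1:5) {
    pd <- pd_params(runif(1, 1, 20), runif(1, 0.5, 4), runif(1), runif(1, 0, 0.02))
    cc <- runif(60, 0, 30)
    b1 <- simulate_burden(pd, cc)$burden
    b2 <- simulate_burden(pd, cc + runif(60, 0, 10))$burden
    expect_true(all(b2 <= b1 + 1e-12))
    expect_true(all(b1 >= 0 & b1 <= 1))
  }
})

test_that("label sampling is seeded Bernoulli per 10-min window", {
  b <- burden_series(c(0, 1, 0.5))
  l1 <- sample_labels(b, seed = 9)
  l2 <- sample_labels(b, seed = 9)
  expect_identical(l1$labels, l2$labels)
  expect_identical(l1$labels[1:300], rep(0L, 300))
  expect_identical(l1$labels[301:600], rep(1L, 300))
  frac <- mean(l1$labels[601:900])
  expect_lt(abs(frac - 0.5), 0.09)  # 3 sigma binomial bound
})

test_that("fit_pkpd recovers parameters exactly from noise-free data", {
  true_pk <- pk_params(k_e = 0.12, V = 0.6)
  true_pd <- pd_params(ed50 = 10, hill = 2.5, b0 = 0.7, lam = 0.008)
  doses <- doses_bolus_q("levetiracetam", 7, 8, 240)
  tt <- (0:1439) / 6
  obs <- simulate_burden(true_pd, concentration_profile(doses, true_pk, tt), tt)
  f <- fit_pkpd(obs, doses, seed = 1)
  expect_lt(f$mse, 1e-10)
  est <- c(f$pk$k_e, f$pd$ed50, f$pd$hill, f$pd$b0, f$pd$lam)
  tru <- c(0.12, 10, 2.5, 0.7, 0.008)
  expect_lt(max(abs(est - tru) / tru), 0.01)
  expect_true(f$identifiable)
  # reported objective equals the recomputed MSE of the returned parameters
  sim <- simulate_burden(f$pd,
                         concentration_profile(doses, f$pk, tt), tt)$burden
  expect_equal(f$mse, mean((sim - obs$burden)^2), tolerance = 1e-12)
})

test_that("untreated records yield a baseline-only, flagged fit", {
  obs <- burden_series(rep(0.4, 72))
  f <- fit_pkpd(obs, dose_events(), drug = "levetiracetam")
  expect_false(f$identifiable)
  expect_match(f$flags, "non_identifiable")
  expect_equal(f$pd$b0, 0.4, tolerance = 0.01)
  expect_lt(f$pd$lam, 1e-3)
  expect_error(fit_pkpd(burden_series(rep(0.4, 10)), dose_events()),
               "too short")
})
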