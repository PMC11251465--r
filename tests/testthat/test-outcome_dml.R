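# Cross-fitted doubly robust outcome model: dichotomization, partialling-out
# effect estimation, leakage safety, prediction contracts.

test_that("mRS dichotomizes at the 3/4 boundary", {
  expect_equal(as.character(dichotomize_mrs(c(0, 3, 4, 6))),
               c("good", "good", "poor", "poor"))
  expect_error(dichotomize_mrs(7), "0..6")
  expect_error(dichotomize_mrs(2.5), "0..6")
})

test_that("with identical confounders theta reduces to residual regression", {
  set.seed(21)
  n <- 120
  e_max <- runif(n, 0.1, 0.9)
  mean_conc <- runif(n, 0, 2)
  y <- rbinom(n, 1, pmin(pmax(0.2 + 0.3 * e_max, 0.01), 0.99))
  co <- structure(lapply(seq_len(n), function(i)
    make_test_patient(sprintf("I%04d", i), mrs = if (y[i] == 1) 5 else 1)),
    class = "ea_cohort")
  ex <- data.frame(e_max = e_max, mean_conc = mean_conc)
  fold_id <- rep(1:5, length.out = n)
  m <- fit_outcome_model(co, ex, fold_id = fold_id, seed = 1)
  # constant features force constant nuisances = fold-training means
  for (k in 1:5) {
    expect_equal(unique(round(m$nuisance$yhat[fold_id == k], 6)),
                 round(mean(y[fold_id != k]), 6), tolerance = 1e-3)
  }
  ytil <- y - m$nuisance$yhat
  Ttil <- as.matrix(ex) - m$nuisance$That
  ref <- coef(lm(ytil ~ Ttil - 1))
  expect_equal(unname(m$theta), unname(ref), tolerance = 1e-8)
})

test_that("cross-fitting never leaks fold rows into fold nuisances", {
  d <- make_plm_cohort(150, seed = 3)
  fold_id <- rep(1:5, length.out = 150)
  m1 <- fit_outcome_model(d$cohort, d$exposures, fold_id = fold_id, seed = 1)
  # poison fold 1: flip outcomes and shift exposures of its rows
  co2 <- d$cohort
  ex2 <- d$exposures
  poisoned <- which(fold_id == 1)
  for (i in poisoned) co2[[i]]$mrs <- if (co2[[i]]$mrs >= 4) 0 else 6
  ex2$e_max[poisoned] <- 0.99
  m2 <- fit_outcome_model(co2, ex2, fold_id = fold_id, seed = 1)
  expect_equal(m1$nuisance$yhat[poisoned], m2$nuisance$yhat[poisoned],
               tolerance = 1e-12)
  expect_equal(m1$nuisance$That[poisoned, ], m2$nuisance$That[poisoned, ],
               tolerance = 1e-12)
})

test_that("theta is invariant to affine rescaling of confounders", {
  d <- make_plm_cohort(150, seed = 8)
  fold_id <- rep(1:5, length.out = 150)
  m1 <- fit_outcome_model(d$cohort, d$exposures, fold_id = fold_id, seed = 1)
  co2 <- lapply(d$cohort, function(r) {
    r$covariates$age <- 100 * r$covariates$age - 40
    r$covariates$weight <- r$covariates$weight / 7 + 2
    r
  })
  class(co2) <- "ea_cohort"
  m2 <- fit_outcome_model(co2, d$exposures, fold_id = fold_id, seed = 1)
  expect_equal(m1$theta, m2$theta, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected or flagged", {
  d <- make_plm_cohort(60, seed = 5)
  co_all_poor <- lapply(d$cohort, function(r) { r$mrs <- 5; r })
  class(co_all_poor) <- "ea_cohort"
  expect_error(fit_outcome_model(co_all_poor, d$exposures), "degenerate")
  ex_const <- d$exposures
  ex_const$mean_conc <- 1
  m <- fit_outcome_model(d$cohort, ex_const, seed = 1)
  expect_match(m$flags, "non_identifiable.*mean_conc")
  expect_true(is.na(m$theta[["mean_conc"]]))
  expect_false(is.na(m$theta[["e_max"]]))
})

test_that("predictions are probabilities and calibrated in the large", {
  d <- make_plm_cohort(400, seed = 13)
  m <- fit_outcome_model(d$cohort, d$exposures, seed = 2)
  X <- t(vapply(d$cohort, eatrialsim:::patient_features,
                eatrialsim:::patient_features(d$cohort[[1]])))
  p <- predict_outcome(m, d$exposures, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(abs(mean(p) - mean(d$y)), 0.05)
  # random/extreme inputs stay in [0, 1]
  set.seed(99)
  p2 <- predict_outcome(m, list(e_max = runif(20), mean_conc = runif(20, 0, 50)),
                        X[sample(400, 20), ])
  expect_true(all(p2 >= 0 & p2 <= 1))
  expect_error(predict_outcome(list(), list(e_max = 0.5, mean_conc = 1),
                               X[1, ]), "not a fitted")
})

test_that("predictions respond more to e_max than to an unused covariate", {
  d <- make_plm_cohort(400, theta_emax = 0.4, seed = 17)
  m <- fit_outcome_model(d$cohort, d$exposures, seed = 2)
  X <- t(vapply(d$cohort, eatrialsim:::patient_features,
                eatrialsim:::patient_features(d$cohort[[1]])))
  p0 <- predict_outcome(m, d$exposures, X)
  set.seed(1)
  ex_perm <- d$exposures
  ex_perm$e_max <- sample(ex_perm$e_max)
  p_emax <- predict_outcome(m, ex_perm, X)
  X_perm <- X
  X_perm[, "weight"] <- sample(X_perm[, "weight"])  # unused by the generator
  p_wt <- predict_outcome(m, d$exposures, X_perm)
  expect_lt(mean(abs(p_wt - p0)), mean(abs(p_emax - p0)))
})
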