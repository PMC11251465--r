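# Doubly robust (double-ML, partialling-out) estimation of the effect of EA
# burden and drug exposure on dichotomized discharge mRS, with
# gradient-boosted nuisance models and cross-fitting.

#' Dichotomize a modified Rankin Scale score
#'
#' @param mrs Integer vector with values 0-6.
#' @return Factor with levels `good` (mRS 0-3) and `poor` (mRS 4-6).
#' @export
dichotomize_mrs <- function(mrs) {
  if (any(!is.finite(mrs) | mrs != round(mrs) | mrs < 0 | mrs > 6))
    stop("mrs must be integers in 0..6")
  factor(ifelse(mrs >= 4, "poor", "good"), levels = c("good", "poor"))
}

# Flat numeric feature vector of baseline covariates + PK/PD confounders.
patient_features <- function(record) {
  cv <- record$covariates
  pp <- record$pkpd
  c(age = cv$age, sex_f = as.numeric(cv$sex == "F"),
    hunt_hess = cv$hunt_hess, fisher = cv$fisher,
    time_to_eeg = cv$time_to_eeg, eeg_duration = cv$eeg_duration,
    weight = cv$weight,
    b0 = pp$b0, lam = pp$lam,
    lev_k_e = pp$drugs$levetiracetam$k_e,
    lev_ed50 = pp$drugs$levetiracetam$ed50,
    lev_hill = pp$drugs$levetiracetam$hill,
    prop_k_e = pp$drugs$propofol$k_e,
    prop_ed50 = pp$drugs$propofol$ed50,
    prop_hill = pp$drugs$propofol$hill)
}

# Confounder matrix for a cohort (list of patient records).
cohort_features <- function(cohort) {
  t(vapply(cohort, patient_features, patient_features(cohort[[1]])))
}

xgb_fit <- function(x, y, objective, nrounds, max_depth, eta) {
  dtrain <- xgboost::xgb.DMatrix(data = as.matrix(x), label = y)
  xgboost::xgb.train(
    params = list(objective = objective, max_depth = max_depth, eta = eta,
                  nthread = 1, seed = 0),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

xgb_pred <- function(model, x) {
  as.numeric(stats::predict(model, xgboost::xgb.DMatrix(as.matrix(x))))
}

#' Fit the doubly robust discharge-outcome model
#'
#' Estimates the effect of the exposure vector `(e_max, mean_conc)` on the
#' probability of a poor discharge outcome (mRS 4-6) in a partially linear
#' model, adjusting for baseline covariates and per-patient PK/PD parameters
#' as confounders. Nuisance functions `E[Y|X]` and `E[T_j|X]` are fit with
#' gradient-boosted trees under K-fold cross-fitting; the effects `theta` are
#' obtained by regressing cross-fitted outcome residuals on cross-fitted
#' exposure residuals (partialling-out), with heteroskedasticity-robust
#' standard errors. A separate gradient-boosted classifier `g_hat` of
#' `P(poor | e_max, mean_conc, X)` is fit on the full data for arm-level
#' outcome prediction in simulated trials.
#'
#' @param cohort List of patient records (see [generate_cohort]).
#' @param exposures Data frame with columns `e_max` and `mean_conc`, one row
#'   per patient, aligned with `cohort`; computed by [cohort_exposures] when
#'   omitted.
#' @param folds Number of cross-fitting folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @param fold_id Optional integer vector of fold labels overriding the
#'   random assignment (useful for leakage diagnostics).
#' @param nrounds,max_depth,eta Gradient-boosting hyperparameters
#'   (defaults 200 trees, depth 3, learning rate 0.05).
#' @return An object of class `outcome_model` with elements `theta`
#'   (named effect estimates), `se`, `vcov`, `nuisance` (cross-fitted
#'   predictions), `fold_id`, `g_hat` (booster), `feature_names`, `flags`.
#' @export
fit_outcome_model <- function(cohort, exposures = NULL, folds = 5L, seed = 1L,
                              fold_id = NULL, nrounds = 200L, max_depth = 3L,
                              eta = 0.05) {
  if (is.null(exposures)) exposures <- cohort_exposures(cohort)
  n <- length(cohort)
  stopifnot(nrow(exposures) == n)
  if (n < 2L * folds) stop("cohort too small for ", folds, "-fold cross-fitting")
  y <- as.numeric(dichotomize_mrs(vapply(cohort, function(r) r$mrs,
                                         numeric(1))) == "poor")
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: all patients in the same mRS class")
  X <- cohort_features(cohort)
  Tm <- as.matrix(exposures[, c("e_max", "mean_conc")])

  flags <- character()
  active <- apply(Tm, 2, function(t) stats::sd(t) > 1e-12)
  if (!all(active))
    flags <- c(flags, paste0("non_identifiable:",
                             paste(colnames(Tm)[!active], collapse = ",")))

  if (is.null(fold_id)) {
    withr::local_seed(as.integer(seed))
    fold_id <- sample(rep(seq_len(folds), length.out = n))
  }
  stopifnot(length(fold_id) == n)

  yhat <- numeric(n)
  That <- matrix(0, n, ncol(Tm), dimnames = list(NULL, colnames(Tm)))
  for (k in sort(unique(fold_id))) {
    tr <- fold_id != k
    te <- !tr
    my <- xgb_fit(X[tr, , drop = FALSE], y[tr], "reg:squarederror",
                  nrounds, max_depth, eta)
    yhat[te] <- xgb_pred(my, X[te, , drop = FALSE])
    for (j in which(active)) {
      mt <- xgb_fit(X[tr, , drop = FALSE], Tm[tr, j], "reg:squarederror",
                    nrounds, max_depth, eta)
      That[te, j] <- xgb_pred(mt, X[te, , drop = FALSE])
    }
  }
  ytil <- y - yhat
  Ttil <- Tm - That

  theta <- stats::setNames(rep(NA_real_, ncol(Tm)), colnames(Tm))
  se <- theta
  vc <- matrix(NA_real_, sum(active), sum(active))
  if (any(active)) {
    df <- data.frame(ytil = ytil, Ttil[, active, drop = FALSE])
    fit <- stats::lm(ytil ~ . - 1, data = df)
    vc <- sandwich::vcovHC(fit, type = "HC1")
    theta[active] <- stats::coef(fit)
    se[active] <- sqrt(diag(vc))
  }

  g_hat <- xgb_fit(cbind(Tm, X), y, "binary:logistic", nrounds, max_depth, eta)

  structure(list(
    theta = theta, se = se, vcov = vc,
    nuisance = list(yhat = yhat, That = That, y = y, T = Tm),
    fold_id = fold_id, seed = seed,
    hyper = list(nrounds = nrounds, max_depth = max_depth, eta = eta,
                 folds = folds),
    g_hat = g_hat, feature_names = c(colnames(Tm), colnames(X)),
    flags = flags), class = "outcome_model")
}

#' Predict the probability of a poor discharge outcome
#'
#' Evaluates the fitted gradient-boosted outcome predictor at an exposure
#' summary and covariate/confounder vector.
#'
#' @param model A fitted [fit_outcome_model] object.
#' @param exposure List or data frame with `e_max` and `mean_conc` (may be
#'   vectorised).
#' @param x Named numeric confounder vector(s) as produced internally from a
#'   patient record, or a patient record / list of records.
#' @return Probability (vector) of poor outcome, clipped to `[0, 1]`.
#' @export
predict_outcome <- function(model, exposure, x) {
  if (!inherits(model, "outcome_model")) stop("model is not a fitted outcome_model")
  if (is.list(x) && !is.null(x$covariates)) x <- patient_features(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  ex <- cbind(e_max = exposure$e_max, mean_conc = exposure$mean_conc)
  if (nrow(ex) == 1L && nrow(x) > 1L) ex <- ex[rep(1L, nrow(x)), , drop = FALSE]
  if (nrow(x) == 1L && nrow(ex) > 1L) x <- x[rep(1L, nrow(ex)), , drop = FALSE]
  feat <- cbind(ex, x)[, model$feature_names, drop = FALSE]
  pmin(pmax(xgb_pred(model$g_hat, feat), 0), 1)
}

#' Exposure summaries for every patient in a cohort
#'
#' Computes each patient's observed `e_max` (6-h sliding-window maximum of
#' the burden series) and `mean_conc` (ED50-standardized mean drug exposure
#' over the monitoring record, summed over drugs).
#'
#' @param cohort List of patient records.
#' @return Data frame with columns `patient_id`, `e_max`, `mean_conc`.
#' @export
cohort_exposures <- function(cohort) {
  out <- lapply(cohort, function(r) {
    data.frame(patient_id = r$id,
               e_max = compute_emax(r$burden),
               mean_conc = mean_std_exposure(r, r$doses,
                                             r$burden$window_start_hour))
  })
  do.call(rbind, out)
}

# ED50-standardized mean exposure: mean_t sum_d C_d(t) / ED50_d.
mean_std_exposure <- function(record, doses, times) {
  if (!length(times)) return(0)
  total <- numeric(length(times))
  for (dr in DRUGS) {
    dd <- record$pkpd$drugs[[dr]]
    if (is.null(dd)) next
    cc <- concentration_profile(doses, pk_params(dd$k_e, dd$V), times, drug = dr)
    total <- total + cc / dd$ed50
  }
  mean(total)
}
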