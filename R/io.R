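# Cohort readers/writers (validated CSV schemas), run manifest, and the
# top-level pipeline driver chaining generate -> fit-pkpd -> fit-outcome ->
# power analyses.

#' Write a cohort to a directory of CSV files
#'
#' Writes `patients.csv` (covariates, outcome, PK/PD parameters),
#' `doses.csv`, `burden.csv` and, when ground truth is present,
#' `truth.csv`.
#'
#' @param cohort Cohort from [generate_cohort] or [read_cohort].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pat <- do.call(rbind, lapply(cohort, function(r) {
    cv <- r$covariates; pp <- r$pkpd
    data.frame(patient_id = r$id, age = cv$age, sex = cv$sex,
               hunt_hess = cv$hunt_hess, fisher = cv$fisher,
               time_to_eeg = cv$time_to_eeg, eeg_duration = cv$eeg_duration,
               weight = cv$weight, treated = isTRUE(r$treated),
               mrs = if (is.null(r$mrs)) NA_integer_ else r$mrs,
               b0 = pp$b0, lam = pp$lam,
               lev_k_e = pp$drugs$levetiracetam$k_e,
               lev_V = pp$drugs$levetiracetam$V,
               lev_ed50 = pp$drugs$levetiracetam$ed50,
               lev_hill = pp$drugs$levetiracetam$hill,
               prop_k_e = pp$drugs$propofol$k_e,
               prop_V = pp$drugs$propofol$V,
               prop_ed50 = pp$drugs$propofol$ed50,
               prop_hill = pp$drugs$propofol$hill)
  }))
  utils::write.csv(pat, file.path(dir, "patients.csv"), row.names = FALSE)
  doses <- do.call(rbind, lapply(cohort, function(r) {
    if (!nrow(r$doses)) return(NULL)
    cbind(patient_id = r$id, as.data.frame(r$doses))
  }))
  if (is.null(doses))
    doses <- data.frame(patient_id = character(), drug = character(),
                        time_h = numeric(), route = character(),
                        amount = numeric())
  utils::write.csv(doses, file.path(dir, "doses.csv"), row.names = FALSE)
  burden <- do.call(rbind, lapply(cohort, function(r) {
    if (is.null(r$burden)) return(NULL)
    data.frame(patient_id = r$id,
               window_start_hour = r$burden$window_start_hour,
               burden = r$burden$burden)
  }))
  if (!is.null(burden))
    utils::write.csv(burden, file.path(dir, "burden.csv"), row.names = FALSE)
  if (!is.null(cohort[[1]]$truth))
    export_ground_truth(cohort, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Read a cohort from a directory of CSV files
#'
#' Validates schemas and invariants (ordinal ranges, mRS range, burden in
#' `[0, 1]`, positive weights, duplicated ids); violations are reported with
#' offending row numbers or patient ids.
#'
#' @param dir Directory written by [write_cohort].
#' @param require_burden Error if a patient lacks burden rows (default TRUE).
#' @return Cohort (list of patient records, class `ea_cohort`).
#' @export
read_cohort <- function(dir, require_burden = TRUE) {
  pfile <- file.path(dir, "patients.csv")
  if (!file.exists(pfile)) stop("missing ", pfile)
  pat <- utils::read.csv(pfile, stringsAsFactors = FALSE)
  need <- c("patient_id", "age", "sex", "hunt_hess", "fisher", "time_to_eeg",
            "eeg_duration", "weight", "treated", "mrs", "b0", "lam",
            "lev_k_e", "lev_V", "lev_ed50", "lev_hill",
            "prop_k_e", "prop_V", "prop_ed50", "prop_hill")
  miss <- setdiff(need, names(pat))
  if (length(miss)) stop("patients.csv missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(pat$patient_id))
    stop("duplicated patient ids: ",
         paste(unique(pat$patient_id[duplicated(pat$patient_id)]),
               collapse = ", "))
  check_range <- function(col, lo, hi, integer = FALSE) {
    v <- pat[[col]]
    bad <- which(!is.finite(v) | v < lo | v > hi |
                   (integer & v != round(v)))
    if (length(bad))
      stop("patients.csv: invalid ", col, " at row(s) ",
           paste(bad, collapse = ", "))
  }
  check_range("hunt_hess", 1, 5, integer = TRUE)
  check_range("fisher", 1, 4, integer = TRUE)
  ok_mrs <- is.na(pat$mrs) | (pat$mrs >= 0 & pat$mrs <= 6 &
                                pat$mrs == round(pat$mrs))
  if (any(!ok_mrs))
    stop("patients.csv: invalid mrs at row(s) ",
         paste(which(!ok_mrs), collapse = ", "))
  check_range("weight", 1e-9, Inf)
  check_range("b0", 0, 1)

  dfile <- file.path(dir, "doses.csv")
  doses <- if (file.exists(dfile)) utils::read.csv(dfile, stringsAsFactors = FALSE)
           else data.frame(patient_id = character(), drug = character(),
                           time_h = numeric(), route = character(),
                           amount = numeric())
  bfile <- file.path(dir, "burden.csv")
  burden <- if (file.exists(bfile)) utils::read.csv(bfile) else NULL
  bad_b <- if (!is.null(burden))
    which(!is.finite(burden$burden) | burden$burden < 0 | burden$burden > 1)
    else integer()
  if (length(bad_b))
    stop("burden.csv: burden outside [0, 1] at row(s) ",
         paste(bad_b, collapse = ", "))

  cohort <- lapply(seq_len(nrow(pat)), function(i) {
    p <- pat[i, ]
    dd <- doses[doses$patient_id == p$patient_id,
                c("drug", "time_h", "route", "amount"), drop = FALSE]
    bb <- if (!is.null(burden))
      burden[burden$patient_id == p$patient_id, , drop = FALSE] else NULL
    if (require_burden && (is.null(bb) || !nrow(bb)))
      stop("no burden series found for patient ", p$patient_id)
    rec <- list(
      id = p$patient_id,
      covariates = list(age = p$age, sex = p$sex, hunt_hess = p$hunt_hess,
                        fisher = p$fisher, time_to_eeg = p$time_to_eeg,
                        eeg_duration = p$eeg_duration, weight = p$weight),
      pkpd = list(b0 = p$b0, lam = p$lam, drugs = list(
        levetiracetam = list(k_e = p$lev_k_e, V = p$lev_V, ed50 = p$lev_ed50,
                             hill = p$lev_hill),
        propofol = list(k_e = p$prop_k_e, V = p$prop_V, ed50 = p$prop_ed50,
                        hill = p$prop_hill))),
      doses = do.call(dose_events, dd),
      treated = p$treated,
      mrs = if (is.na(p$mrs)) NULL else p$mrs)
    if (!is.null(bb) && nrow(bb))
      rec$burden <- burden_series(bb$burden, bb$window_start_hour[1])
    rec
  })
  structure(cohort, class = "ea_cohort")
}

config_hash <- function(config) {
  # stable content hash of the (ordered) config for resumable stages
  x <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  f <- tempfile(); on.exit(unlink(f))
  writeLines(as.character(x), f)
  unname(tools::md5sum(f))
}

#' Run the full simulation pipeline
#'
#' Chains the stages `generate` (optional), `fit-pkpd`, `fit-outcome` and
#' the requested power analyses. Each stage writes its artifacts under
#' `out_dir` and is skipped on a rerun when its output exists and the config
#' hash is unchanged (resumability). A run manifest with the config hash,
#' per-stage seeds and status is written to `manifest.json` before any
#' results.
#'
#' @param config Named list (or path to a YAML/JSON file) with optional
#'   entries: `seed` (master seed, default 1), `cohort` (arguments to
#'   [cohort_config]; omit to reuse an existing cohort in `out_dir`), `drug`
#'   (default `"levetiracetam"`), `contrast` (default `c(2, 4)`: median dose
#'   vs placebo), `fit` (overrides for [fit_pkpd]: `n_starts`, `maxit`),
#'   `outcome` (overrides for [fit_outcome_model]), `analyses` (subset of
#'   `"power"`, `"sample-size"`, `"sweep-ed50"`), `n_grid`, `replicates`,
#'   `n_max`, `n_per_arm_sweep`.
#' @param out_dir Output directory.
#' @return The run manifest (list), invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                                 simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  drug <- config$drug %||% "levetiracetam"
  analyses <- config$analyses %||% "power"
  replicates <- config$replicates %||% 500L
  hash <- config_hash(config)

  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(config_hash = hash, created = format(Sys.time(), tz = "UTC"),
                   seeds = list(master = seed, generate = seed,
                                fit_pkpd = seed + 1L, fit_outcome = seed + 2L,
                                analyses = seed + 3L),
                   stages = list())
  prev <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else NULL
  resumable <- !is.null(prev) && identical(prev$config_hash, hash)
  write_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  write_manifest()

  cohort_dir <- file.path(out_dir, "cohort")
  if (!is.null(config$cohort) &&
      !(resumable && file.exists(file.path(cohort_dir, "patients.csv")))) {
    cfg <- do.call(cohort_config,
                   utils::modifyList(config$cohort, list(seed = seed)))
    cohort <- generate_cohort(cfg)
    write_cohort(cohort, cohort_dir)
    manifest$stages$generate <- "done"
  } else {
    cohort <- read_cohort(cohort_dir)
    manifest$stages$generate <- if (is.null(config$cohort)) "external" else "skipped"
  }
  write_manifest()

  fits_path <- file.path(out_dir, "pkpd_fits.csv")
  if (resumable && file.exists(fits_path)) {
    fits <- utils::read.csv(fits_path)
    manifest$stages$fit_pkpd <- "skipped"
  } else {
    fit_args <- config$fit %||% list()
    fits <- fit_cohort_pkpd(cohort, seed = seed + 1L,
                            n_starts = fit_args$n_starts %||% 8L,
                            maxit = fit_args$maxit %||% 500L)
    utils::write.csv(fits, fits_path, row.names = FALSE)
    manifest$stages$fit_pkpd <- "done"
  }
  cohort <- apply_pkpd_fits(cohort, fits)
  write_manifest()

  model_path <- file.path(out_dir, "outcome_model.json")
  out_args <- config$outcome %||% list()
  model <- do.call(fit_outcome_model,
                   c(list(cohort = cohort, seed = seed + 2L), out_args))
  jsonlite::write_json(
    list(theta = as.list(model$theta), se = as.list(model$se),
         folds = model$hyper$folds, seed = model$seed,
         hyper = model$hyper, flags = model$flags),
    model_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$stages$fit_outcome <- "done"
  write_manifest()

  design <- trial_design(standard_arms(drug),
                         contrast = config$contrast %||% c(2L, 4L))
  probs <- arm_outcome_probs(cohort, model, design)
  utils::write.csv(
    data.frame(arm = colnames(probs),
               expected_poor_rate = colMeans(probs)),
    file.path(out_dir, "arm_outcomes.csv"), row.names = FALSE)

  if ("power" %in% analyses) {
    n_grid <- config$n_grid %||% c(50L, 100L, 200L, 400L)
    pc <- power_curve(cohort, model, design, n_grid, replicates = replicates,
                      seed = seed + 3L, probs = probs)
    utils::write.csv(pc, file.path(out_dir, "power_curve.csv"),
                     row.names = FALSE)
    manifest$stages$power <- "done"
  }
  if ("sample-size" %in% analyses) {
    ss <- find_sample_size(cohort, model, design,
                           n_max = config$n_max %||% 5000L,
                           replicates = replicates, seed = seed + 3L,
                           probs = probs)
    jsonlite::write_json(list(n = ss$n, reached = ss$reached,
                              power_at_n = ss$power_at_n,
                              power_at_n_max = ss$power_at_n_max,
                              trace = ss$trace),
                         file.path(out_dir, "sample_size.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$stages$sample_size <- "done"
  }
  if ("sweep-ed50" %in% analyses) {
    sw <- sweep_ed50(cohort, model, design,
                     n_per_arm = config$n_per_arm_sweep %||% 100L,
                     replicates = replicates, seed = seed + 3L, drug = drug)
    utils::write.csv(sw, file.path(out_dir, "ed50_sweep.csv"),
                     row.names = FALSE)
    manifest$stages$sweep_ed50 <- "done"
  }
  write_manifest()
  invisible(manifest)
}

#' Fit PK/PD parameters for every patient in a cohort
#'
#' Fits each drug the patient actually received; untreated patients get a
#' baseline-only fit. Returns one row per patient-drug combination.
#'
#' @param cohort Cohort with observed burden series and dose histories.
#' @param seed,n_starts,maxit Passed to [fit_pkpd].
#' @return Data frame of fitted parameters with `mse` and `identifiable`.
#' @export
fit_cohort_pkpd <- function(cohort, seed = 1L, n_starts = 8L, maxit = 500L) {
  rows <- list()
  for (r in cohort) {
    drugs <- unique(r$doses$drug)
    if (!length(drugs)) drugs <- NA_character_
    for (dr in drugs) {
      f <- fit_pkpd(r$burden, r$doses,
                    drug = if (is.na(dr)) NULL else dr,
                    seed = seed, n_starts = n_starts, maxit = maxit)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = r$id, drug = f$drug, k_e = f$pk$k_e, V = f$pk$V,
        ed50 = f$pd$ed50, hill = f$pd$hill, b0 = f$pd$b0, lam = f$pd$lam,
        mse = f$mse, identifiable = f$identifiable,
        flags = paste(f$flags, collapse = ";"))
    }
  }
  do.call(rbind, rows)
}

# Replace generator/loaded PK/PD parameters with fitted values where fits
# are identifiable; baseline (b0, lam) always taken from the fit.
apply_pkpd_fits <- function(cohort, fits) {
  out <- lapply(cohort, function(r) {
    ff <- fits[fits$patient_id == r$id, , drop = FALSE]
    if (!nrow(ff)) return(r)
    r$pkpd$b0 <- ff$b0[1]
    r$pkpd$lam <- ff$lam[1]
    for (i in seq_len(nrow(ff))) {
      if (!isTRUE(ff$identifiable[i])) next
      dr <- ff$drug[i]
      r$pkpd$drugs[[dr]]$k_e <- ff$k_e[i]
      r$pkpd$drugs[[dr]]$V <- ff$V[i]
      r$pkpd$drugs[[dr]]$ed50 <- ff$ed50[i]
      r$pkpd$drugs[[dr]]$hill <- ff$hill[i]
    }
    r
  })
  structure(out, class = "ea_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
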