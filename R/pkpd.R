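# One-compartment pharmacokinetics (closed-form superposition), Hill
# pharmacodynamic suppression of EA burden, forward simulation, and
# per-patient parameter estimation by MSE minimisation.

DRUGS <- c("levetiracetam", "propofol")

# Literature anchors used for fixed volumes and elimination-rate priors:
# levetiracetam V 0.6 L/kg, t1/2 ~7 h; propofol effective V 4 L/kg, t1/2 ~1 h.
# Plasma concentrations are not observed, so V is fixed per drug and only
# k_e is estimated (D/V and ED50 are jointly non-identifiable from burden).
PK_DEFAULTS <- list(
  levetiracetam = list(V = 0.6, k_e = log(2) / 7),
  propofol      = list(V = 4.0, k_e = log(2) / 1)
)

#' Default one-compartment PK parameters per drug
#'
#' Fixed distribution volume and literature-based elimination-rate starting
#' value for each supported drug.
#'
#' @param drug `"levetiracetam"` or `"propofol"`.
#' @return A [pk_params] object.
#' @export
pk_defaults <- function(drug = DRUGS) {
  drug <- match.arg(drug)
  d <- PK_DEFAULTS[[drug]]
  pk_params(k_e = d$k_e, V = d$V)
}

#' One-compartment pharmacokinetic parameters
#'
#' @param k_e Elimination rate constant (1/h), > 0.
#' @param V Distribution volume (L/kg), > 0.
#' @return Object of class `pk_params`.
#' @export
pk_params <- function(k_e, V) {
  if (!is.finite(k_e) || k_e <= 0) stop("k_e must be a positive finite number")
  if (!is.finite(V) || V <= 0) stop("V must be a positive finite number")
  structure(list(k_e = k_e, V = V), class = "pk_params")
}

#' Hill pharmacodynamic parameters with untreated-baseline trajectory
#'
#' `ed50` is the drug concentration that halves the EA burden in a 10-minute
#' window relative to its untreated level; `hill` sets the steepness of the
#' concentration-effect curve. The untreated baseline burden is modeled as
#' `b0 * exp(-lam * t)` (set `lam = 0` for a constant baseline).
#'
#' @param ed50 Half-suppression concentration (mg/L), > 0.
#' @param hill Hill coefficient, > 0.
#' @param b0 Baseline burden fraction at t = 0, in `[0, 1]`.
#' @param lam Baseline decay rate (1/h), >= 0.
#' @return Object of class `pd_params`.
#' @export
pd_params <- function(ed50, hill, b0, lam = 0) {
  if (!is.finite(ed50) || ed50 <= 0) stop("ed50 must be positive")
  if (!is.finite(hill) || hill <= 0) stop("hill must be positive")
  if (!is.finite(b0) || b0 < 0 || b0 > 1) stop("b0 must lie in [0, 1]")
  if (!is.finite(lam) || lam < 0) stop("lam must be non-negative")
  structure(list(ed50 = ed50, hill = hill, b0 = b0, lam = lam),
            class = "pd_params")
}

#' Dose-event table
#'
#' Validates a dosing schedule. Routes are `bolus` (IV push, `amount` in
#' mg/kg), `infusion_start` (`amount` = rate in mg/kg/h) and `infusion_stop`
#' (no amount). Per drug, infusion starts and stops must alternate; an
#' unterminated infusion is treated as running to the end of the evaluation
#' grid.
#'
#' @param drug Character vector of drug names.
#' @param time_h Event times in hours from t = 0, >= 0.
#' @param route One of `"bolus"`, `"infusion_start"`, `"infusion_stop"`.
#' @param amount mg/kg (bolus) or mg/kg/h (infusion_start); `NA` for stops.
#' @return A `dose_events` data frame sorted by time.
#' @export
dose_events <- function(drug = character(), time_h = numeric(),
                        route = character(), amount = numeric()) {
  d <- data.frame(drug = as.character(drug), time_h = as.numeric(time_h),
                  route = as.character(route), amount = as.numeric(amount))
  if (nrow(d)) {
    if (!all(d$drug %in% DRUGS))
      stop("unknown drug(s): ", paste(setdiff(d$drug, DRUGS), collapse = ", "))
    if (!all(d$route %in% c("bolus", "infusion_start", "infusion_stop")))
      stop("invalid route")
    if (any(!is.finite(d$time_h) | d$time_h < 0))
      stop("dose times must be finite and >= 0")
    dosed <- d$route %in% c("bolus", "infusion_start")
    if (any(!is.finite(d$amount[dosed]) | d$amount[dosed] <= 0))
      stop("bolus/infusion_start amounts must be positive")
    d <- d[order(d$time_h), , drop = FALSE]
    for (dr in unique(d$drug)) {           # starts/stops must alternate
      r <- d$route[d$drug == dr]
      r <- r[r != "bolus"]
      open <- FALSE
      for (ev in r) {
        if (ev == "infusion_start") {
          if (open) stop("overlapping infusions for ", dr)
          open <- TRUE
        } else {
          if (!open) stop("infusion_stop without infusion_start for ", dr)
          open <- FALSE
        }
      }
    }
    rownames(d) <- NULL
  }
  class(d) <- c("dose_events", "data.frame")
  d
}

#' Repeated-bolus dosing schedule
#'
#' @param drug Drug name.
#' @param dose Bolus dose (mg/kg).
#' @param interval_h Dosing interval in hours (e.g. 8 for q8h).
#' @param duration_h Length of the dosing period; boluses are given at
#'   `start_h, start_h + interval_h, ...` strictly before `start_h + duration_h`.
#' @param start_h Time of the first bolus.
#' @return A [dose_events] table.
#' @export
doses_bolus_q <- function(drug, dose, interval_h = 8, duration_h, start_h = 0) {
  times <- seq(start_h, start_h + duration_h - 1e-9, by = interval_h)
  dose_events(drug = rep(drug, length(times)), time_h = times,
              route = rep("bolus", length(times)),
              amount = rep(dose, length(times)))
}

#' Constant-rate infusion schedule
#'
#' @param drug Drug name.
#' @param rate Infusion rate (mg/kg/h).
#' @param start_h,stop_h Infusion window in hours.
#' @return A [dose_events] table.
#' @export
doses_infusion <- function(drug, rate, start_h = 0, stop_h) {
  dose_events(drug = c(drug, drug), time_h = c(start_h, stop_h),
              route = c("infusion_start", "infusion_stop"),
              amount = c(rate, NA))
}

#' Closed-form one-compartment concentration profile
#'
#' Superposition solution of `dC/dt = input(t)/V - k_e * C`: a bolus `D` at
#' `t_i` contributes `(D/V) exp(-k_e (t - t_i))` for `t >= t_i`; an infusion
#' at rate `R` on `[t_a, t_b]` contributes `R/(k_e V) (1 - exp(-k_e (t - t_a)))`
#' during the infusion and its end-of-infusion value decayed by
#' `exp(-k_e (t - t_b))` afterwards. Contributions over events sum.
#'
#' @param doses A [dose_events] table; only rows matching `drug` are used
#'   when `drug` is given.
#' @param pk A [pk_params] object.
#' @param times Numeric vector of evaluation times (hours), typically the
#'   10-minute burden grid.
#' @param drug Optional drug name filter.
#' @return Numeric vector of concentrations (mg/L), one per time point.
#' @export
concentration_profile <- function(doses, pk, times, drug = NULL) {
  if (!inherits(pk, "pk_params")) stop("pk must be a pk_params object")
  if (!inherits(doses, "dose_events")) doses <- do.call(dose_events, doses)
  if (!is.null(drug)) doses <- doses[doses$drug == drug, , drop = FALSE]
  conc <- numeric(length(times))
  if (!nrow(doses)) return(conc)
  k <- pk$k_e; V <- pk$V
  tmax <- max(times)
  i <- 1L
  n <- nrow(doses)
  while (i <= n) {
    ev <- doses[i, ]
    if (ev$route == "bolus") {
      dt <- times - ev$time_h
      conc <- conc + ifelse(dt >= 0, (ev$amount / V) * exp(-k * dt), 0)
      i <- i + 1L
    } else if (ev$route == "infusion_start") {
      # find matching stop for the same drug (validated to alternate)
      stop_t <- tmax
      j <- i + 1L
      while (j <= n) {
        if (doses$drug[j] == ev$drug && doses$route[j] == "infusion_stop") {
          stop_t <- doses$time_h[j]
          break
        }
        j <- j + 1L
      }
      css <- ev$amount / (k * V)
      rising <- times >= ev$time_h & times <= stop_t
      after <- times > stop_t
      add <- numeric(length(times))
      add[rising] <- css * (1 - exp(-k * (times[rising] - ev$time_h)))
      c_end <- css * (1 - exp(-k * (stop_t - ev$time_h)))
      add[after] <- c_end * exp(-k * (times[after] - stop_t))
      conc <- conc + add
      i <- i + 1L
    } else {
      i <- i + 1L  # stops are consumed by their start
    }
  }
  conc
}

#' Hill suppression of EA burden
#'
#' Fractional reduction of EA burden at concentration `c`:
#' `S(c) = c^hill / (ed50^hill + c^hill)`, so `S(0) = 0`, `S(ed50) = 0.5`,
#' and `S -> 1` as `c -> Inf`.
#'
#' @param conc Concentration(s), mg/L, >= 0.
#' @param pd A [pd_params] object.
#' @return Suppression fraction(s) in `[0, 1]`.
#' @export
hill_suppression <- function(conc, pd) {
  if (any(!is.finite(conc) | conc < 0)) stop("concentrations must be finite and >= 0")
  # work on the log-ratio scale to avoid overflow for large hill coefficients
  r <- (conc / pd$ed50)^pd$hill
  ifelse(is.infinite(r), 1, r / (1 + r))
}

#' Forward-simulate an expected EA burden trajectory
#'
#' Deterministic (expected-burden) trajectory under a concentration profile:
#' `b(t) = clip(b0 exp(-lam t), 0, 1) * (1 - S(C(t)))` evaluated on the
#' 10-minute burden grid.
#'
#' @param pd A [pd_params] object.
#' @param conc Numeric concentration vector on the grid `times`.
#' @param times Grid times in hours (defaults to consecutive 10-min bins
#'   starting at 0).
#' @return A [burden_series].
#' @export
simulate_burden <- function(pd, conc, times = (seq_along(conc) - 1) / 6) {
  stopifnot(length(conc) == length(times))
  base <- pmin(pmax(pd$b0 * exp(-pd$lam * times), 0), 1)
  burden_series(base * (1 - hill_suppression(conc, pd)),
                start_hour = times[1])
}

#' Sample 2-sec EA labels from a burden series
#'
#' Stochastic observation model: within each 10-minute window, 300
#' independent Bernoulli draws at that window's burden fraction.
#'
#' @param burden A [burden_series].
#' @param seed Integer seed for reproducibility.
#' @return An [ea_labels] object of `300 * nrow(burden)` labels.
#' @export
sample_labels <- function(burden, seed = 1L) {
  stopifnot(inherits(burden, "burden_series"))
  withr::local_seed(as.integer(seed))
  p <- rep(burden$burden, each = SEGMENTS_PER_WINDOW)
  ea_labels(stats::rbinom(length(p), 1L, p),
            start_hour = burden$window_start_hour[1])
}
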