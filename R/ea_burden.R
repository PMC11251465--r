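# EA burden quantification: 2-sec labels -> 10-min burden -> 6-h sliding E_max.

SEGMENTS_PER_WINDOW <- 300L   # 10 min / 2 sec
WINDOW_HOURS <- 1 / 6         # one burden bin

#' Epileptiform-activity label series
#'
#' Container for a dense series of binary epileptiform-activity (EA) labels,
#' one per consecutive 2-second EEG segment, as produced by an upstream EEG
#' pattern classifier. Labels are assumed gap-free; artifact handling is the
#' caller's responsibility.
#'
#' @param labels Integer (or logical) vector of 0/1 EA labels, one per 2-sec
#'   segment, in temporal order.
#' @param start_hour Time of the first segment in hours from the first EA
#'   measurement (t = 0).
#' @return An object of class `ea_labels`: a list with elements `labels`,
#'   `start_hour` and `segment_seconds` (fixed at 2).
#' @examples
#' x <- ea_labels(rbinom(600, 1, 0.2))
#' compute_burden(x)
#' @export
ea_labels <- function(labels, start_hour = 0) {
  labels <- as.integer(labels)
  if (length(labels) < 1L) stop("label series must contain at least one segment")
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1 with no missing values")
  if (!is.finite(start_hour) || start_hour < 0)
    stop("start_hour must be a non-negative finite number")
  structure(list(labels = labels, start_hour = start_hour, segment_seconds = 2L),
            class = "ea_labels")
}

#' EA burden series
#'
#' A burden series holds the fraction of EA-positive 2-sec segments in
#' consecutive non-overlapping 10-minute windows.
#'
#' @param values Numeric vector of per-window EA fractions, each in `[0, 1]`.
#' @param start_hour Start time (hours) of the first window.
#' @return A data frame of class `burden_series` with columns
#'   `window_start_hour` and `burden`.
#' @export
burden_series <- function(values, start_hour = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("burden series must be non-empty")
  if (anyNA(values) || any(values < 0 | values > 1))
    stop("burden values must lie in [0, 1]")
  out <- data.frame(
    window_start_hour = start_hour + (seq_along(values) - 1L) * WINDOW_HOURS,
    burden = values
  )
  class(out) <- c("burden_series", "data.frame")
  attr(out, "window_minutes") <- 10L
  out
}

#' Aggregate 2-sec EA labels into a 10-minute burden series
#'
#' Each complete non-overlapping 10-minute window (300 segments) contributes
#' one value: the proportion of segments labeled EA-positive. A trailing
#' partial window is dropped.
#'
#' @param labels An [ea_labels] object.
#' @return A [burden_series].
#' @export
compute_burden <- function(labels) {
  if (!inherits(labels, "ea_labels")) labels <- ea_labels(labels)
  x <- labels$labels
  n_win <- length(x) %/% SEGMENTS_PER_WINDOW
  if (n_win < 1L)
    stop("record too short: need at least one complete 10-min window (",
         SEGMENTS_PER_WINDOW, " segments), got ", length(x))
  x <- x[seq_len(n_win * SEGMENTS_PER_WINDOW)]
  frac <- colMeans(matrix(x, nrow = SEGMENTS_PER_WINDOW))
  burden_series(frac, start_hour = labels$start_hour)
}

#' Maximum EA burden over 6-hour sliding windows (E_max)
#'
#' Slides a `window_hours` window over the burden series in steps of one
#' 10-minute bin and returns the maximum window mean. Records shorter than
#' the window collapse to a single degenerate window spanning the whole
#' record, so the value is then the overall mean.
#'
#' @param burden A [burden_series] (or bare numeric vector of fractions).
#' @param window_hours Sliding-window length in hours; default 6.
#' @return Maximum sliding-window mean burden, in `[0, 1]`.
#' @export
compute_emax <- function(burden, window_hours = 6) {
  v <- if (inherits(burden, "burden_series")) burden$burden else as.numeric(burden)
  if (length(v) < 1L) stop("burden series must be non-empty")
  if (anyNA(v)) stop("burden series contains missing values")
  w <- as.integer(round(window_hours / WINDOW_HOURS))
  if (length(v) <= w) return(mean(v))
  # trailing moving average; entries w..n are the complete-window means
  win_means <- stats::filter(v, rep(1 / w, w), sides = 1)
  max(win_means[w:length(v)])
}

#' Mean EA burden of a series
#'
#' @param burden A [burden_series] (or bare numeric vector).
#' @return Arithmetic mean of the per-window burden fractions.
#' @export
mean_burden <- function(burden) {
  v <- if (inherits(burden, "burden_series")) burden$burden else as.numeric(burden)
  if (length(v) < 1L) stop("burden series must be non-empty")
  mean(v)
}

#' Exposure summary of a burden record
#'
#' Convenience wrapper returning both the 6-h sliding-window maximum
#' (`e_max`) and the overall mean burden.
#'
#' @inheritParams compute_emax
#' @return A list with elements `e_max` and `mean_burden`.
#' @export
ea_summary <- function(burden, window_hours = 6) {
  list(e_max = compute_emax(burden, window_hours), mean_burden = mean_burden(burden))
}
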