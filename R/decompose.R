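#' Tonic (multi-minute) concentration levels
#'
#' Summarises a concentration series into slowly varying tonic levels:
#' the arithmetic mean of each analyte over sliding windows of
#' `window_length` seconds advanced by `step` seconds (default equal to
#' the window length, i.e. non-overlapping ~4-minute windows).  Only
#' windows lying fully inside the recording are returned.
#'
#' @param series A [concentration_series()].
#' @param window_length Window length in seconds (default 240).
#' @param step Step between window starts, seconds.
#' @return An object of class `tonic_series`: data frame with
#'   `window_start`, `window_center`, `window_end`, `tonic_da`,
#'   `tonic_sert`; attributes `window_length`, `step`.
#' @export
compute_tonic <- function(series, window_length = 240,
                          step = window_length) {
  stopifnot(inherits(series, "concentration_series"))
  ts <- series$timestamps
  dt <- if (length(ts) > 1) ts[2] - ts[1] else 1
  t_end <- ts[length(ts)] + dt
  if (window_length <= 0 || step <= 0) {
    stopf("window_length and step must be positive")
  }
  if (window_length > t_end - ts[1]) {
    stopf("window_length (%.1f s) exceeds recording length (%.1f s)",
          window_length, t_end - ts[1])
  }
  starts <- seq(ts[1], t_end - window_length + 1e-9, by = step)
  rows <- lapply(starts, function(s) {
    in_w <- ts >= s - 1e-9 & ts < s + window_length - 1e-9
    if (!any(in_w)) stopf("empty tonic window at %.1f s", s)
    data.frame(window_start = s, window_center = s + window_length / 2,
               window_end = s + window_length,
               tonic_da = mean(series$da[in_w]),
               tonic_sert = mean(series$sert[in_w]))
  })
  out <- do.call(rbind, rows)
  structure(out, window_length = window_length, step = step,
            class = c("tonic_series", "data.frame"))
}

#' Assign trials to tonic windows
#'
#' @param tonic A [compute_tonic()] result.
#' @param onsets Trial onset times, seconds.
#' @return Integer window index per onset (`NA` when the onset falls in
#'   no window; with overlapping windows the earliest matching window is
#'   used).
#' @export
assign_tonic_window <- function(tonic, onsets) {
  vapply(onsets, function(o) {
    w <- which(o >= tonic$window_start & o < tonic$window_end)
    if (length(w)) w[1] else NA_integer_
  }, integer(1))
}

#' Extract stimulus-locked epochs
#'
#' Cuts the concentration series into per-trial epochs on a fixed grid of
#' times relative to stimulus onset (default -0.5 to +1.1 s at the series
#' sample rate), resampling by linear interpolation, and applies
#' per-trial baseline correction: the mean over `baseline` (default
#' `[-0.5, 0)` s, pre-stimulus) is subtracted (`mode = "baseline"`), or
#' the epoch is z-scored against the baseline mean and SD
#' (`mode = "zscore"`).  Trials whose epoch extends beyond the recording
#' are dropped with a warning.
#'
#' @param series A [concentration_series()].
#' @param trials Trial table with `onset_s` (see [generate_session()]).
#' @param window Epoch span relative to onset, seconds (length-2).
#' @param baseline Baseline interval relative to onset, seconds
#'   (length-2, `[b0, b1)`).
#' @param mode Baseline handling: subtract the baseline mean, or z-score.
#' @return An object of class `epoch_set`: matrices `da` and `sert`
#'   (`n_trials` x `n_timepoints`), `epoch_times`, `trial_index` (rows of
#'   `trials` retained), `n_dropped`, and the baseline description.
#' @export
extract_epochs <- function(series, trials, window = c(-0.5, 1.1),
                           baseline = c(-0.5, 0),
                           mode = c("baseline", "zscore")) {
  stopifnot(inherits(series, "concentration_series"))
  mode <- match.arg(mode)
  ts <- series$timestamps
  dt <- ts[2] - ts[1]
  epoch_times <- seq(window[1], window[2], by = dt)
  if (!any(abs(epoch_times) < dt / 2)) {
    stopf("epoch grid must include time 0")
  }
  onsets <- trials$onset_s
  ok <- onsets + epoch_times[1] >= ts[1] - 1e-9 &
    onsets + epoch_times[length(epoch_times)] <= ts[length(ts)] + 1e-9
  if (any(!ok)) {
    warnf("dropping %d trial(s) whose epochs exceed the recording bounds",
          sum(!ok))
  }
  if (!any(ok)) stopf("no trial epoch lies inside the recording")
  keep <- which(ok)

  cut_one <- function(x) {
    t(vapply(onsets[keep], function(o) {
      stats::approx(ts, x, xout = o + epoch_times, rule = 1)$y
    }, numeric(length(epoch_times))))
  }
  ep <- list(da = cut_one(series$da), sert = cut_one(series$sert))

  base_idx <- which(epoch_times >= baseline[1] - 1e-9 &
                      epoch_times < baseline[2] - 1e-9)
  if (!length(base_idx)) stopf("baseline window contains no samples")
  for (an in names(ep)) {
    mu <- rowMeans(ep[[an]][, base_idx, drop = FALSE])
    ep[[an]] <- ep[[an]] - mu
    if (mode == "zscore") {
      sdv <- apply(ep[[an]][, base_idx, drop = FALSE], 1, stats::sd)
      sdv[sdv == 0] <- 1
      ep[[an]] <- ep[[an]] / sdv
    }
  }

  structure(
    list(da = ep$da, sert = ep$sert, epoch_times = epoch_times,
         trial_index = keep, n_dropped = sum(!ok),
         baseline = baseline, mode = mode),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "Epoch set: %d trials x %d timepoints (%.2f to %.2f s), %d dropped, %s-corrected\n",
    nrow(x$da), length(x$epoch_times), min(x$epoch_times),
    max(x$epoch_times), x$n_dropped, x$mode))
  invisible(x)
}

#' Per-trial mean concentration in a post-onset window
#'
#' Computes, per trial, the mean epoch value over `[t0, t1]` seconds after
#' stimulus onset.  Because analysis windows (e.g. the 625-670 ms cluster
#' window) need not align with the sampling grid, each sample is treated
#' as covering `[t - dt/2, t + dt/2)` and enters the mean weighted by the
#' fraction of `[t0, t1]` it covers (`method = "overlap"`); this reduces
#' to the plain sample mean for grid-aligned windows.
#' `method = "nearest"` instead averages the samples whose centres fall
#' inside the window (nearest-sample fallback).
#'
#' @param epochs An [extract_epochs()] result.
#' @param t0,t1 Window bounds, seconds post-onset; default the 625-670 ms
#'   cluster window.
#' @param analyte `"da"` or `"sert"`.
#' @param method Overlap-weighted (default) or nearest-sample averaging.
#' @return An object of class `window_summary`: numeric vector, one value
#'   per retained trial, with the window stored in attributes.
#' @export
window_mean <- function(epochs, t0 = 0.625, t1 = 0.670,
                        analyte = c("da", "sert"),
                        method = c("overlap", "nearest")) {
  stopifnot(inherits(epochs, "epoch_set"))
  analyte <- match.arg(analyte)
  method <- match.arg(method)
  if (t1 <= t0) stopf("t1 must exceed t0")
  tt <- epochs$epoch_times
  dt <- tt[2] - tt[1]
  if (t0 < tt[1] - dt / 2 || t1 > tt[length(tt)] + dt / 2) {
    stopf("window [%g, %g] exceeds the epoch span", t0, t1)
  }
  if (method == "overlap") {
    lo <- pmax(tt - dt / 2, t0)
    hi <- pmin(tt + dt / 2, t1)
    w <- pmax(hi - lo, 0)
  } else {
    w <- as.numeric(tt >= t0 & tt <= t1)
  }
  if (sum(w) <= 0) stopf("window [%g, %g] overlaps no samples", t0, t1)
  w <- w / sum(w)
  out <- as.numeric(epochs[[analyte]] %*% w)
  structure(out, t0 = t0, t1 = t1, analyte = analyte, method = method,
            trial_index = epochs$trial_index, class = "window_summary")
}

#' @export
print.window_summary <- function(x, ...) {
  cat(sprintf("Window summary (%s, [%g, %g] s, %s): %d trials, mean %.4g\n",
              attr(x, "analyte"), attr(x, "t0"), attr(x, "t1"),
              attr(x, "method"), length(x), mean(x)))
  invisible(x)
}
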