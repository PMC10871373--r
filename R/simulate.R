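#' Generate an in-vitro style calibration set
#'
#' Produces labelled voltammetric sweeps for decoder training.  Labels are
#' the full factorial of `conc_grid` for dopamine and serotonin, cycled to
#' `n_samples`; each sweep is the label-weighted sum of the two analyte
#' templates plus i.i.d. Gaussian feature noise of SD `neuro$noise_sd`.
#'
#' @param neuro A [neurochem_params()].
#' @param n_samples Number of labelled sweeps.
#' @param conc_grid Non-negative concentrations (µM) used for both
#'   analytes.
#' @param seed Integer seed for the noise draw.
#' @return An object of class `calibration_set`: list with `sweeps`
#'   (`n_samples` x `n_features` matrix), `labels_da`, `labels_sert`.
#' @examples
#' cal <- generate_calibration_set(neurochem_params(), 64, c(0, 1), seed = 1)
#' dim(cal$sweeps)
#' @export
generate_calibration_set <- function(neuro, n_samples = 500,
                                     conc_grid = c(0, 0.5, 1, 2),
                                     seed = 1) {
  stopifnot(inherits(neuro, "neurochem_params"))
  if (length(conc_grid) == 0) stopf("conc_grid must be non-empty")
  if (any(conc_grid < 0)) stopf("conc_grid must be non-negative")
  if (n_samples < 1) stopf("n_samples must be positive")

  fact <- expand.grid(da = conc_grid, sert = conc_grid,
                      KEEP.OUT.ATTRS = FALSE)
  idx <- rep_len(seq_len(nrow(fact)), n_samples)
  labels_da <- fact$da[idx]
  labels_sert <- fact$sert[idx]

  clean <- outer(labels_da, neuro$template_da) +
    outer(labels_sert, neuro$template_sert)
  noise <- with_seed(substream(seed, 11), {
    matrix(stats::rnorm(n_samples * neuro$n_features, 0, neuro$noise_sd),
           n_samples, neuro$n_features)
  })
  structure(
    list(sweeps = clean + noise,
         labels_da = labels_da, labels_sert = labels_sert,
         neuro = neuro, seed = as.integer(seed)),
    class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("Calibration set: %d sweeps x %d features, DA %.3g-%.3g uM, 5-HT %.3g-%.3g uM\n",
              nrow(x$sweeps), ncol(x$sweeps),
              min(x$labels_da), max(x$labels_da),
              min(x$labels_sert), max(x$labels_sert)))
  invisible(x)
}

# Allocate n_trials over n_levels as evenly as possible; the remainder is
# distributed symmetrically about the midpoint: middle level first when
# the remainder is odd, then outermost pairs inward.
allocate_levels <- function(n_trials, n_levels) {
  counts <- rep(n_trials %/% n_levels, n_levels)
  rem <- n_trials %% n_levels
  if (rem > 0) {
    order_idx <- integer(0)
    if (rem %% 2 == 1) {
      if (n_levels %% 2 == 0) {
        stopf("cannot allocate %d trials symmetrically over %d levels",
              n_trials, n_levels)
      }
      order_idx <- (n_levels + 1) %/% 2
    }
    lo <- 1; hi <- n_levels
    while (length(order_idx) < rem) {
      order_idx <- c(order_idx, lo, hi)
      lo <- lo + 1; hi <- hi - 1
    }
    counts[order_idx[seq_len(rem)]] <- counts[order_idx[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' Simulate a recording session with behaviour
#'
#' Generates one participant-session: a tonic dopamine/serotonin random
#' walk (reflected at 0 µM), per-trial phasic transients
#' \eqn{a \exp(-(t - onset - latency)/\tau)}, the resulting sweep matrix
#' (templates weighted by the true concentrations, plus uniform sensor
#' drift and feature noise), and bisection responses from the
#' cumulative-Gaussian observer described in [observer_params()].
#'
#' All ground truth is retained, so every downstream stage can be tested
#' by parameter recovery.  Each stochastic component (trial schedule,
#' tonic walks, transient amplitudes, sweep noise, responses) draws from
#' its own deterministic sub-stream of `seed`, so e.g. disabling sweep
#' generation does not change the behavioural draw.
#'
#' @param task A [task_config()].
#' @param observer An [observer_params()].
#' @param neuro A [neurochem_params()].
#' @param seed Integer master seed.
#' @param include_sweeps If `FALSE`, skip generating the sweep matrix
#'   (ground truth and behaviour only); useful for behaviour-only
#'   simulations.
#' @return An object of class `session_recording`: timestamps, `sweeps`,
#'   true concentration series (`truth_da`, `truth_sert`) and their tonic
#'   components, and the trial table (`onset_s`, `duration_s`, `response`,
#'   `truth_phasic_amp`).
#' @examples
#' s <- generate_session(task_config(n_trials = 21), observer_params(),
#'                       neurochem_params(), seed = 1,
#'                       include_sweeps = FALSE)
#' head(s$trials)
#' @export
generate_session <- function(task = task_config(),
                             observer = observer_params(),
                             neuro = neurochem_params(),
                             seed = 1, include_sweeps = TRUE) {
  stopifnot(inherits(task, "task_config"),
            inherits(observer, "observer_params"),
            inherits(neuro, "neurochem_params"))
  fs <- task$sample_rate
  n_trials <- task$n_trials
  t_total <- n_trials * task$iti_mean
  lead_in <- 1            # s before the first onset (epoch baseline room)
  tail_pad <- 2           # s after the last onset (epoch + transient room)
  if (t_total < lead_in + tail_pad + (n_trials - 1) * 1.7) {
    stopf("session of %.1f s is too short for %d trials (need >= %.1f s)",
          t_total, n_trials, lead_in + tail_pad + (n_trials - 1) * 1.7)
  }
  n_t <- as.integer(round(t_total * fs))
  timestamps <- (seq_len(n_t) - 1) / fs

  # trial schedule: jittered ITIs rescaled to span the session exactly
  sched <- with_seed(substream(seed, 1), {
    gaps <- stats::runif(n_trials - 1, 0.8, 1.2) * task$iti_mean
    onsets <- lead_in + c(0, cumsum(gaps))
    onsets <- lead_in + (onsets - lead_in) *
      (t_total - lead_in - tail_pad) / max(onsets - lead_in, 1e-9)
    levels <- duration_levels(task)
    counts <- allocate_levels(n_trials, task$n_levels)
    durations <- sample(rep(levels, counts))
    list(onsets = onsets, durations = durations)
  })

  walk <- function(comp) {
    with_seed(substream(seed, comp), {
      abs(neuro$tonic_mean +
            cumsum(stats::rnorm(n_t, 0, neuro$tonic_walk_sd)))
    })
  }
  tonic_da <- walk(2)
  tonic_sert <- walk(3)

  amps_da <- with_seed(substream(seed, 4), {
    pmax(stats::rnorm(n_trials, neuro$transient_amp_mean,
                      neuro$transient_amp_sd), 0)
  })
  amps_sert <- with_seed(substream(seed, 5), {
    pmax(stats::rnorm(n_trials, neuro$transient_amp_mean_sert,
                      neuro$transient_amp_sd_sert), 0)
  })

  add_transients <- function(base, amps) {
    x <- base
    horizon <- min(ceiling(neuro$transient_tau * 14 * fs), n_t)
    for (i in seq_len(n_trials)) {
      if (amps[i] <= 0) next
      t0 <- sched$onsets[i] + neuro$transient_latency
      i0 <- max(1L, as.integer(ceiling(t0 * fs)) + 1L)
      ii <- i0:min(n_t, i0 + horizon)
      x[ii] <- x[ii] +
        amps[i] * exp(-(timestamps[ii] - t0) / neuro$transient_tau)
    }
    x
  }
  truth_da <- add_transients(tonic_da, amps_da)
  truth_sert <- add_transients(tonic_sert, amps_sert)

  sweeps <- NULL
  if (include_sweeps) {
    clean <- outer(truth_da, neuro$template_da) +
      outer(truth_sert, neuro$template_sert) +
      neuro$drift_slope * timestamps
    sweeps <- clean + with_seed(substream(seed, 6), {
      matrix(stats::rnorm(n_t * neuro$n_features, 0, neuro$noise_sd),
             n_t, neuro$n_features)
    })
  }

  # observer: trial-wise PF centre and spread, then Bernoulli responses
  onset_idx <- pmin(n_t, as.integer(floor(sched$onsets * fs)) + 1L)
  z_amp <- zscore(amps_da)
  z_tonic <- zscore(tonic_da[onset_idx])
  # Positive phasic coupling shifts the trial's PF centre rightward on
  # high-transient trials: the probe is more likely to be judged "short"
  # (temporal underestimation).
  bp_trial <- observer$bp_true + observer$phasic_coupling * z_amp
  sigma0 <- observer$weber_true * observer$bp_true / 0.6745
  sigma_trial <- sigma0 * exp(-observer$tonic_coupling * z_tonic)
  p_long <- observer$lapse / 2 + (1 - observer$lapse) *
    stats::pnorm((sched$durations - bp_trial) / sigma_trial)
  response <- with_seed(substream(seed, 7), {
    ifelse(stats::runif(n_trials) < p_long, "long", "short")
  })

  trials <- data.frame(
    onset_s = sched$onsets,
    duration_s = sched$durations,
    response = response,
    truth_phasic_amp = amps_da,
    stringsAsFactors = FALSE)

  structure(
    list(timestamps = timestamps, sweeps = sweeps,
         truth_da = truth_da, truth_sert = truth_sert,
         truth_tonic_da = tonic_da, truth_tonic_sert = tonic_sert,
         trials = trials, task = task, observer = observer, neuro = neuro,
         seed = as.integer(seed)),
    class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "Session recording: %.0f s at %g Hz (%d sweeps%s), %d trials, seed %d\n",
    max(x$timestamps) + 1 / x$task$sample_rate, x$task$sample_rate,
    length(x$timestamps),
    if (is.null(x$sweeps)) ", sweep matrix omitted" else
      sprintf(" x %d features", ncol(x$sweeps)),
    nrow(x$trials), x$seed))
  invisible(x)
}

#' Read or write a trial table
#'
#' Trial tables are exchanged as comma-delimited text with the header
#' `onset_s,duration_s,response,truth_phasic_amp`; `response` is
#' `"short"` or `"long"`.  The ground-truth amplitude column is present
#' only for generated data and may be `NA` for real recordings.
#'
#' @param trials A trial-table `data.frame`.
#' @param path File path.
#' @return `read_trial_table` returns the trial-table `data.frame`;
#'   `write_trial_table` returns `path` invisibly.
#' @export
write_trial_table <- function(trials, path) {
  stopifnot(all(c("onset_s", "duration_s", "response") %in% names(trials)))
  if (is.null(trials$truth_phasic_amp)) trials$truth_phasic_amp <- NA_real_
  utils::write.csv(
    trials[, c("onset_s", "duration_s", "response", "truth_phasic_amp")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "response")
  if (!all(need %in% names(tr))) {
    stopf("trial table %s lacks columns: %s", path,
          paste(setdiff(need, names(tr)), collapse = ", "))
  }
  bad <- setdiff(unique(tr$response), c("short", "long"))
  if (length(bad)) stopf("invalid response values: %s",
                         paste(bad, collapse = ", "))
  tr
}

#' Write or read a session recording as delimited text
#'
#' The sweep matrix and truth series go to `sweeps.csv` / `series.csv`,
#' the trial table to `trials.csv`, and a JSON sidecar (`session.json`)
#' records the sample rate, seed and configurations.
#'
#' @param session A `session_recording`.
#' @param dir Output directory (created if needed).
#' @return `write_session` returns `dir` invisibly; `read_session`
#'   returns a `session_recording` (configs restored from the sidecar).
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series <- data.frame(timestamp_s = session$timestamps,
                       truth_da = session$truth_da,
                       truth_sert = session$truth_sert,
                       truth_tonic_da = session$truth_tonic_da,
                       truth_tonic_sert = session$truth_tonic_sert)
  utils::write.csv(series, file.path(dir, "series.csv"), row.names = FALSE)
  if (!is.null(session$sweeps)) {
    utils::write.table(session$sweeps, file.path(dir, "sweeps.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  write_trial_table(session$trials, file.path(dir, "trials.csv"))
  sidecar <- list(sample_rate = session$task$sample_rate,
                  seed = session$seed,
                  task = unclass(session$task),
                  observer = unclass(session$observer),
                  neuro = unclass(session$neuro))
  jsonlite::write_json(sidecar, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "session.json"),
                                 simplifyVector = TRUE)
  task <- do.call(task_config, sidecar$task[names(formals(task_config))])
  observer <- do.call(observer_params,
                      sidecar$observer[names(formals(observer_params))])
  nn <- sidecar$neuro
  neuro <- neurochem_params(
    template_da = nn$template_da, template_sert = nn$template_sert,
    tonic_mean = nn$tonic_mean, tonic_walk_sd = nn$tonic_walk_sd,
    transient_amp_mean = nn$transient_amp_mean,
    transient_amp_sd = nn$transient_amp_sd,
    transient_amp_mean_sert = nn$transient_amp_mean_sert,
    transient_amp_sd_sert = nn$transient_amp_sd_sert,
    transient_latency = nn$transient_latency,
    transient_tau = nn$transient_tau,
    noise_sd = nn$noise_sd, drift_slope = nn$drift_slope)
  series <- utils::read.csv(file.path(dir, "series.csv"))
  sweeps <- NULL
  sweep_path <- file.path(dir, "sweeps.csv")
  if (file.exists(sweep_path)) {
    sweeps <- as.matrix(utils::read.table(sweep_path, sep = ","))
    dimnames(sweeps) <- NULL
  }
  structure(
    list(timestamps = series$timestamp_s, sweeps = sweeps,
         truth_da = series$truth_da, truth_sert = series$truth_sert,
         truth_tonic_da = series$truth_tonic_da,
         truth_tonic_sert = series$truth_tonic_sert,
         trials = read_trial_table(file.path(dir, "trials.csv")),
         task = task, observer = observer, neuro = neuro,
         seed = as.integer(sidecar$seed)),
    class = "session_recording")
}
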