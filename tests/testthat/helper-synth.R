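# Shared fixtures, built in code.  Expensive objects (the default decoder)
# are memoised for the duration of the test run.

.fixtures <- new.env(parent = emptyenv())

default_decoder <- function() {
  if (is.null(.fixtures$decoder)) {
    cal <- generate_calibration_set(neurochem_params(), 500, seed = 99)
    .fixtures$decoder <- fit_decoder(cal, seed = 99)
  }
  .fixtures$decoder
}

# Ground-truth concentration series of a session (bypasses the decoder
# where a test targets downstream stages only).
truth_series <- function(session) {
  concentration_series(session$timestamps, session$truth_da,
                       session$truth_sert)
}

truth_tonic_series <- function(session) {
  concentration_series(session$timestamps, session$truth_tonic_da,
                       session$truth_tonic_sert)
}

# Behaviour-only sessions (no sweep matrix) for seed-loop simulations.
quick_session <- function(seed, observer = observer_params(),
                          task = task_config(), ...) {
  generate_session(task, observer, neurochem_params(), seed = seed,
                   include_sweeps = FALSE, ...)
}

# Epochs + labels + participant ids for a cohort, from ground-truth series.
cohort_epochs <- function(seeds, observer = observer_params(),
                          n_trials = 300) {
  task <- task_config(n_trials = n_trials)
  ss <- lapply(seeds, function(i) {
    generate_session(task, observer, neurochem_params(), seed = i,
                     include_sweeps = FALSE)
  })
  E <- do.call(rbind, lapply(ss, function(x) {
    extract_epochs(truth_series(x), x$trials)$da
  }))
  list(E = E,
       labels = unlist(lapply(ss, function(x) x$trials$response == "short")),
       participants = rep(seq_along(seeds), each = n_trials),
       sessions = ss)
}

# Minimal hand-built epoch_set for window arithmetic tests.
manual_epoch_set <- function(values, epoch_times = seq(-0.5, 1.1, by = 0.1)) {
  m <- matrix(values, nrow = 1)
  if (is.matrix(values)) m <- values
  structure(
    list(da = m, sert = m, epoch_times = epoch_times,
         trial_index = seq_len(nrow(m)), n_dropped = 0L,
         baseline = c(-0.5, 0), mode = "baseline"),
    class = "epoch_set")
}
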