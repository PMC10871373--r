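#' Pipeline run configuration
#'
#' Bundles every stage's configuration with a master seed, cohort size,
#' stage toggles and an optional output directory.  The object
#' round-trips through JSON ([write_run_config()] / [read_run_config()])
#' and is fingerprinted into every stage output.
#'
#' @param n_participants Cohort size (default 6 patients).
#' @param seed Master seed; per-participant and per-stage seeds are
#'   derived deterministically from it.
#' @param task,observer,neuro Stage configurations (see
#'   [task_config()], [observer_params()], [neurochem_params()]).
#' @param calibration List: `n_samples`, `conc_grid`.
#' @param decoder List: `l1_grid`, `lambda_grid`, `n_folds`.
#' @param decompose List: `tonic_window`, `tonic_step`, `epoch_window`,
#'   `baseline`, `summary_window` (the phasic analysis window, default
#'   the 625-670 ms cluster window).
#' @param cluster List: `n_perm`, `alpha`.
#' @param prevalence List: `alpha` (per-participant test level).
#' @param stages Named logical vector toggling the stages
#'   `simulate`, `calibrate`, `decode`, `decompose`, `psychometrics`,
#'   `cluster`, `infer`, `prevalence`.
#' @param out Optional output directory for delimited-text and JSON
#'   artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_participants = 6, seed = 1,
                       task = task_config(),
                       observer = observer_params(),
                       neuro = neurochem_params(),
                       calibration = list(n_samples = 500,
                                          conc_grid = c(0, 0.5, 1, 2)),
                       decoder = list(l1_grid = c(0.1, 0.5, 0.9),
                                      lambda_grid =
                                        10^seq(1, -5, length.out = 13),
                                      n_folds = 10),
                       decompose = list(tonic_window = 240,
                                        tonic_step = 240,
                                        epoch_window = c(-0.5, 1.1),
                                        baseline = c(-0.5, 0),
                                        summary_window = c(0.625, 0.670)),
                       cluster = list(n_perm = 1000, alpha = 0.05),
                       prevalence = list(alpha = 0.05),
                       stages = NULL, out = NULL) {
  all_stages <- c("simulate", "calibrate", "decode", "decompose",
                  "psychometrics", "cluster", "infer", "prevalence")
  st <- stats::setNames(rep(TRUE, length(all_stages)), all_stages)
  if (!is.null(stages)) {
    bad <- setdiff(names(stages), all_stages)
    if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
    st[names(stages)] <- as.logical(stages)
  }
  # normalise: JSON round-trips can turn a NULL output dir into an
  # empty container or NA
  if (length(out) != 1 || is.na(out)) out <- NULL else
    out <- as.character(out)
  structure(
    list(n_participants = as.integer(n_participants),
         seed = as.integer(seed),
         task = task, observer = observer, neuro = neuro,
         calibration = calibration, decoder = decoder,
         decompose = decompose, cluster = cluster,
         prevalence = prevalence, stages = st, out = out),
    class = "run_config")
}

config_to_list <- function(config) {
  x <- unclass(config)
  x$task <- unclass(x$task)
  x$observer <- unclass(x$observer)
  x$neuro <- unclass(x$neuro)
  x$stages <- as.list(x$stages)
  x
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    n_participants = x$n_participants, seed = x$seed,
    task = do.call(task_config, x$task[names(formals(task_config))]),
    observer = do.call(observer_params,
                       x$observer[names(formals(observer_params))]),
    neuro = do.call(neurochem_params,
                    x$neuro[setdiff(names(x$neuro), "n_features")]),
    calibration = x$calibration, decoder = x$decoder,
    decompose = x$decompose, cluster = x$cluster,
    prevalence = x$prevalence,
    stages = unlist(x$stages), out = x$out)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Pipeline run config: %d participants, seed %d, stages: %s\n",
              x$n_participants, x$seed,
              paste(names(x$stages)[x$stages], collapse = " ")))
  invisible(x)
}

config_hash <- function(config) {
  fnv1a(jsonlite::toJSON(config_to_list(config), auto_unbox = TRUE,
                         digits = NA))
}

require_stage <- function(have, stage, needed_by) {
  if (!have) {
    stopf("stage '%s' requires output of stage '%s', which is disabled",
          needed_by, stage)
  }
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the enabled stages in dependency order — simulate sessions,
#' calibrate the decoder, decode concentration series, decompose into
#' tonic levels and stimulus-locked epochs, fit psychometric functions
#' (overall and by dopamine tercile), run the response-conditioned
#' cluster permutation test, fit the trial-level, tercile and
#' tonic-outcome mixed models, and estimate the Bayesian prevalence of
#' the within-participant phasic effect — and aggregates everything into
#' a run report.  Re-running with the same configuration reproduces all
#' stochastic outputs exactly.
#'
#' @param config A [run_config()].
#' @return An object of class `pipeline_report`: per-participant results,
#'   the inferential end-products (`cluster`, `trial_model`,
#'   `tercile_model`, `tonic_precision`, `tonic_accuracy`,
#'   `prevalence`), dropped-trial and convergence bookkeeping, and the
#'   config hash + seed stamp.  If `config$out` is set, trial tables,
#'   fits and the report are also written there.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  stamp <- list(config_hash = config_hash(config), seed = config$seed)
  report <- list(stamp = stamp, participants = list())
  pids <- sprintf("P%02d", seq_len(config$n_participants))

  require_stage(st["simulate"], "simulate", "any analysis stage")
  sessions <- lapply(seq_along(pids), function(i) {
    generate_session(config$task, config$observer, config$neuro,
                     seed = substream(config$seed, 100 + i))
  })
  names(sessions) <- pids

  decoders <- series <- NULL
  if (st["calibrate"]) {
    decoders <- lapply(seq_along(pids), function(i) {
      cal <- generate_calibration_set(
        config$neuro, config$calibration$n_samples,
        config$calibration$conc_grid,
        seed = substream(config$seed, 200 + i))
      fit_decoder(cal, config$decoder$l1_grid, config$decoder$lambda_grid,
                  config$decoder$n_folds,
                  seed = substream(config$seed, 300 + i))
    })
    names(decoders) <- pids
  }
  if (st["decode"]) {
    require_stage(st["calibrate"], "calibrate", "decode")
    series <- lapply(pids, function(p) decode(decoders[[p]], sessions[[p]]))
    names(series) <- pids
  }

  tonic <- epochs <- summaries <- NULL
  if (st["decompose"]) {
    require_stage(st["decode"], "decode", "decompose")
    dc <- config$decompose
    tonic <- lapply(series, compute_tonic,
                    window_length = dc$tonic_window, step = dc$tonic_step)
    epochs <- lapply(pids, function(p) {
      extract_epochs(series[[p]], sessions[[p]]$trials,
                     window = dc$epoch_window, baseline = dc$baseline)
    })
    names(epochs) <- pids
    summaries <- lapply(pids, function(p) {
      window_mean(epochs[[p]], dc$summary_window[1], dc$summary_window[2])
    })
    names(summaries) <- pids
  }

  trials_kept <- function(p) {
    sessions[[p]]$trials[epochs[[p]]$trial_index, , drop = FALSE]
  }

  if (st["psychometrics"]) {
    for (p in pids) {
      report$participants[[p]]$pf <- suppressWarnings(
        fit_pf(sessions[[p]]$trials))
    }
    if (st["decompose"]) {
      for (p in pids) {
        part <- partition_terciles(summaries[[p]])
        report$participants[[p]]$tercile_pf <- suppressWarnings(
          indices_by_group(trials_kept(p), part))
      }
    }
  }

  if (st["cluster"]) {
    require_stage(st["decompose"], "decompose", "cluster")
    E <- do.call(rbind, lapply(pids, function(p) epochs[[p]]$da))
    lab <- unlist(lapply(pids, function(p) trials_kept(p)$response))
    pp <- rep(pids, vapply(pids, function(p) nrow(epochs[[p]]$da),
                           integer(1)))
    report$cluster <- cluster_permutation_test(
      E, labels = lab == "short", participants = pp,
      n_perm = config$cluster$n_perm,
      cluster_alpha = config$cluster$alpha,
      seed = substream(config$seed, 400))
    report$cluster$epoch_times <- epochs[[1]]$epoch_times
  }

  if (st["infer"]) {
    require_stage(st["decompose"], "decompose", "infer")
    all_trials <- do.call(rbind, lapply(pids, trials_kept))
    all_sum <- unlist(summaries)
    all_pid <- rep(pids, vapply(pids, function(p) length(summaries[[p]]),
                                integer(1)))
    report$trial_model <- fit_trial_logistic(all_trials, all_sum, all_pid)
    part <- partition_terciles(all_sum, all_pid)
    report$tercile_model <- fit_tercile_model(all_trials, part, all_pid)

    tw <- lapply(pids, function(p) {
      tonic_window_indices(series[[p]], sessions[[p]]$trials,
                           config$decompose$tonic_window,
                           config$decompose$tonic_step)
    })
    tonic_vals <- unlist(lapply(tw, `[[`, "tonic"))
    tonic_fits <- do.call(c, lapply(tw, `[[`, "fits"))
    tonic_pid <- rep(pids, vapply(tw, function(x) length(x$tonic),
                                  integer(1)))
    report$tonic_windows_per_participant <-
      stats::setNames(vapply(tw, function(x) length(x$tonic), integer(1)),
                      pids)
    report$tonic_precision <- suppressWarnings(
      fit_tonic_outcome(tonic_vals, tonic_fits, tonic_pid, "precision"))
    report$tonic_accuracy <- suppressWarnings(
      fit_tonic_outcome(tonic_vals, tonic_fits, tonic_pid, "accuracy"))
  }

  if (st["prevalence"]) {
    require_stage(st["decompose"], "decompose", "prevalence")
    alpha <- config$prevalence$alpha
    sig <- vapply(pids, function(p) {
      fit <- fit_trial_logistic(trials_kept(p), summaries[[p]])
      tab <- fit$coefficients
      tab$p[tab$term == "z_summary"] < alpha
    }, logical(1))
    report$prevalence <- prevalence_posterior(sum(sig), length(sig), alpha)
  }

  report$dropped_trials <- if (st["decompose"]) {
    stats::setNames(vapply(pids, function(p) epochs[[p]]$n_dropped,
                           integer(1)), pids)
  }
  report$decoder_r2 <- if (st["calibrate"]) {
    stats::setNames(vapply(decoders, function(d) d$cv_r2_da, numeric(1)),
                    pids)
  }
  class(report) <- "pipeline_report"

  if (!is.null(config$out)) {
    write_pipeline_outputs(report, sessions, config)
  }
  report
}

write_pipeline_outputs <- function(report, sessions, config) {
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(config$out, "run_config.json"))
  for (p in names(sessions)) {
    write_trial_table(sessions[[p]]$trials,
                      file.path(config$out, sprintf("trials_%s.csv", p)))
  }
  jsonlite::write_json(report_to_list(report),
                       file.path(config$out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out)
}

# Strip model objects down to JSON-serialisable summaries.
report_to_list <- function(report) {
  pf_list <- function(f) {
    list(bp = unname(f$coefficients[["bp"]]),
         sigma = unname(f$coefficients[["sigma"]]),
         lapse = unname(f$coefficients[["lapse"]]),
         jnd = f$jnd, weber = f$weber, loglik = f$logLik,
         converged = f$converged, n_trials = f$n_trials)
  }
  mm_list <- function(m) {
    if (is.null(m)) return(NULL)
    list(coefficients = m$coefficients, re_var = m$re_var,
         n_obs = m$n_obs, converged = m$converged, model = m$model)
  }
  out <- list(stamp = report$stamp)
  out$participants <- lapply(report$participants, function(pp) {
    r <- list()
    if (!is.null(pp$pf)) r$pf <- pf_list(pp$pf)
    if (!is.null(pp$tercile_pf)) r$tercile_pf <- lapply(pp$tercile_pf,
                                                        pf_list)
    r
  })
  if (!is.null(report$cluster)) {
    out$cluster <- list(clusters = report$cluster$clusters,
                        n_perm = report$cluster$n_perm,
                        cluster_alpha = report$cluster$cluster_alpha,
                        seed = report$cluster$seed,
                        stat_series = report$cluster$stat_series)
  }
  out$trial_model <- mm_list(report$trial_model)
  out$tercile_model <- mm_list(report$tercile_model)
  out$tonic_precision <- mm_list(report$tonic_precision)
  out$tonic_accuracy <- mm_list(report$tonic_accuracy)
  if (!is.null(report$prevalence)) {
    pv <- report$prevalence
    out$prevalence <- list(k = pv$k, n = pv$n, alpha = pv$alpha,
                           gamma_map = pv$gamma_map,
                           hpdi_low = pv$hpdi_low,
                           hpdi_high = pv$hpdi_high, level = pv$level)
  }
  out$dropped_trials <- as.list(report$dropped_trials)
  out$decoder_r2 <- as.list(report$decoder_r2)
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report (config %s, seed %d)\n",
              x$stamp$config_hash, x$stamp$seed))
  if (!is.null(x$participants) && length(x$participants)) {
    cat(sprintf("  %d participant(s)\n", length(x$participants)))
  }
  if (!is.null(x$cluster)) {
    sig <- x$cluster$clusters$p_value < x$cluster$cluster_alpha
    cat(sprintf("  cluster test: %d cluster(s), %d significant\n",
                nrow(x$cluster$clusters), sum(sig)))
  }
  for (nm in c("trial_model", "tercile_model", "tonic_precision",
               "tonic_accuracy")) {
    if (!is.null(x[[nm]])) {
      tab <- x[[nm]]$coefficients
      key <- tab[nrow(tab), ]
      cat(sprintf("  %s: %s beta %.4g (p = %.3g)\n", nm, key$term,
                  key$beta, key$p))
    }
  }
  if (!is.null(x$prevalence)) {
    cat(sprintf("  prevalence MAP %.3f (%d/%d)\n",
                x$prevalence$gamma_map, x$prevalence$k, x$prevalence$n))
  }
  invisible(x)
}
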