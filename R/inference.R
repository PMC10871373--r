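#' Within-participant tercile partition
#'
#' Splits each participant's trials into low / medium / high terciles of
#' a per-trial summary (e.g. mean dopamine in the cluster window).  The
#' split is rank-based with ties broken by trial order (stable); group
#' sizes differ by at most one, with larger groups at the low end (e.g.
#' 5 values give sizes 2, 2, 1).
#'
#' @param summary Numeric per-trial summary (a [window_mean()] result or
#'   plain vector).
#' @param participants Participant id per trial (default: one
#'   participant).
#' @return An ordered factor (`low < medium < high`) per trial, with the
#'   per-participant group boundaries in attribute `boundaries`.
#' @export
partition_terciles <- function(summary, participants = NULL) {
  x <- as.numeric(summary)
  if (is.null(participants)) participants <- rep(1L, length(x))
  if (length(participants) != length(x)) {
    stopf("participants must have one entry per trial")
  }
  out <- character(length(x))
  bounds <- list()
  for (p in unique(participants)) {
    rows <- which(participants == p)
    n <- length(rows)
    if (n < 3) stopf("participant %s has %d trial(s); need >= 3", p, n)
    if (length(unique(x[rows])) == 1) {
      warnf("participant %s: all summaries equal; split is by trial order", p)
    }
    r <- rank(x[rows], ties.method = "first")
    sizes <- n %/% 3 + (1:3 <= n %% 3)
    lab <- rep(c("low", "medium", "high"), sizes)
    out[rows] <- lab[r]
    bounds[[as.character(p)]] <- c(
      low_max = max(x[rows][lab[r] == "low"]),
      medium_max = max(x[rows][lab[r] == "medium"]))
  }
  structure(factor(out, levels = c("low", "medium", "high"),
                   ordered = TRUE),
            boundaries = bounds)
}

mm_coef_table <- function(fit, mixed) {
  if (mixed) {
    sm <- summary(fit)$coefficients
    beta <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    re <- as.data.frame(lme4::VarCorr(fit))$vcov[1]
    # a singular (zero-variance) random intercept is a valid boundary
    # estimate, not a convergence failure
    msgs <- fit@optinfo$conv$lme4$messages %||% character(0)
    conv <- length(grep("singular", msgs, invert = TRUE, value = TRUE)) == 0
  } else {
    sm <- summary(fit)$coefficients
    beta <- sm[, 1]; se <- sm[, 2]
    re <- 0
    conv <- if (!is.null(fit$converged)) fit$converged else TRUE
  }
  z <- beta / se
  tab <- data.frame(term = rownames(sm), beta = unname(beta),
                    se = unname(se), z = unname(z),
                    p = unname(2 * stats::pnorm(-abs(z))),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, re_var = re, converged = conv)
}

new_mixed_fit <- function(fit, mixed, n_obs, model_name) {
  ct <- mm_coef_table(fit, mixed)
  structure(
    list(coefficients = ct$table, re_var = ct$re_var,
         n_obs = as.integer(n_obs), converged = ct$converged,
         mixed = mixed, model = model_name, fit = fit,
         logLik = as.numeric(stats::logLik(fit)),
         n_params = attr(stats::logLik(fit), "df")),
    class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s (%s, n = %d%s)\n", x$model,
              if (x$mixed) "participant random intercepts" else
                "single participant: plain fit",
              x$n_obs,
              if (x$converged) "" else ", NOT converged"))
  tab <- x$coefficients
  tab$beta <- signif(tab$beta, digits); tab$se <- signif(tab$se, digits)
  tab$z <- signif(tab$z, digits); tab$p <- signif(tab$p, digits)
  print(tab, row.names = FALSE)
  if (x$mixed) cat(sprintf("  random-intercept variance %.4g\n", x$re_var))
  invisible(x)
}

#' @export
coef.mixed_model_fit <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

glmm_or_glm <- function(formula_mixed, formula_plain, data, family) {
  mixed <- length(unique(data$pid)) > 1
  fit <- if (mixed) {
    if (identical(family, "gaussian")) {
      lme4::lmer(formula_mixed, data = data, REML = FALSE)
    } else {
      lme4::glmer(formula_mixed, data = data, family = stats::binomial())
    }
  } else {
    if (identical(family, "gaussian")) {
      stats::lm(formula_plain, data = data)
    } else {
      stats::glm(formula_plain, data = data, family = stats::binomial())
    }
  }
  list(fit = fit, mixed = mixed)
}

#' Trial-level logistic model of judgements on phasic dopamine
#'
#' Mixed-effects logistic regression of the binary judgement
#' (long = 1) on standardised probe duration and the standardised
#' single-trial dopamine summary, with participant random intercepts
#' (Laplace approximation via `lme4::glmer`).  With this coding a
#' negative summary coefficient means higher phasic dopamine makes
#' "long" judgements less likely, i.e. temporal underestimation.  A
#' single participant reduces to ordinary logistic regression.
#'
#' @param trials Trial table with `duration_s` and `response`
#'   (`"short"`/`"long"`).
#' @param summary Per-trial numeric summary (e.g. [window_mean()] in the
#'   cluster window).
#' @param participants Participant id per trial.
#' @return An object of class `mixed_model_fit` with the standardized
#'   coefficient table (`term`, `beta`, `se`, `z`, `p`; p-values from
#'   the two-sided normal reference), the random-intercept variance, and
#'   the underlying fit in `$fit`.
#' @export
fit_trial_logistic <- function(trials, summary, participants = NULL) {
  if (is.null(participants)) participants <- rep(1L, nrow(trials))
  d <- data.frame(
    long = response_to_long(trials$response),
    z_duration = zscore(trials$duration_s),
    z_summary = zscore(as.numeric(summary)),
    pid = factor(participants))
  if (any(!is.finite(d$z_summary))) stopf("summary must be finite")
  res <- glmm_or_glm(long ~ z_duration + z_summary + (1 | pid),
                     long ~ z_duration + z_summary, d, "binomial")
  new_mixed_fit(res$fit, res$mixed, nrow(d),
                "Trial-level judgement model (logistic)")
}

#' Tercile psychometric-shift model
#'
#' Mixed-effects logistic regression of the judgement on standardised
#' duration and the dopamine tercile coded as an ordered numeric
#' predictor (low = -1, medium = 0, high = +1), with participant random
#' intercepts.  A negative tercile coefficient corresponds to a leftward
#' psychometric shift (underestimation) in higher-dopamine terciles.
#'
#' @param trials Trial table (see [fit_trial_logistic()]).
#' @param partition A [partition_terciles()] factor per trial.
#' @param participants Participant id per trial.
#' @return A `mixed_model_fit`.
#' @export
fit_tercile_model <- function(trials, partition, participants = NULL) {
  if (is.null(participants)) participants <- rep(1L, nrow(trials))
  terc <- as.integer(factor(partition,
                            levels = c("low", "medium", "high"))) - 2L
  if (any(is.na(terc))) stopf("partition must be low/medium/high labels")
  d <- data.frame(
    long = response_to_long(trials$response),
    z_duration = zscore(trials$duration_s),
    tercile = terc,
    pid = factor(participants))
  res <- glmm_or_glm(long ~ z_duration + tercile + (1 | pid),
                     long ~ z_duration + tercile, d, "binomial")
  new_mixed_fit(res$fit, res$mixed, nrow(d),
                "Tercile psychometric-shift model (logistic)")
}

#' Tonic dopamine and behavioural outcome model
#'
#' Linear mixed model relating per-window behavioural indices to the
#' standardised tonic dopamine level of the window, with participant
#' random intercepts.  Outcomes: `"precision"` = -log Weber fraction
#' (so a positive coefficient means higher tonic dopamine goes with
#' better temporal precision) or `"accuracy"` = bisection point.
#'
#' @param tonic Numeric tonic dopamine level, one value per
#'   (participant, window) row.
#' @param fits List of per-window [fit_pf()] objects, same length.
#' @param participants Participant id per row.
#' @param outcome `"precision"` or `"accuracy"`.
#' @return A `mixed_model_fit`.
#' @export
fit_tonic_outcome <- function(tonic, fits, participants = NULL,
                              outcome = c("precision", "accuracy")) {
  outcome <- match.arg(outcome)
  tonic <- as.numeric(tonic)
  if (is.null(participants)) participants <- rep(1L, length(tonic))
  if (length(fits) != length(tonic) ||
      length(participants) != length(tonic)) {
    stopf("tonic, fits and participants must have equal length")
  }
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!conv)) {
    warnf("dropping %d non-converged window fit(s)", sum(!conv))
  }
  tonic <- tonic[conv]; fits <- fits[conv]
  participants <- participants[conv]
  counts <- table(participants)
  if (any(counts < 2)) {
    stopf("participants with < 2 tonic windows: %s",
          paste(names(counts)[counts < 2], collapse = ", "))
  }
  if (stats::sd(tonic) == 0) {
    stopf("tonic predictor has zero variance; coefficient undefined")
  }
  y <- vapply(fits, function(f) {
    if (outcome == "precision") -log(f$weber) else f$coefficients[["bp"]]
  }, numeric(1))
  d <- data.frame(y = y, z_tonic = zscore(tonic),
                  pid = factor(participants))
  res <- glmm_or_glm(y ~ z_tonic + (1 | pid), y ~ z_tonic, d, "gaussian")
  new_mixed_fit(res$fit, res$mixed, nrow(d),
                sprintf("Tonic dopamine ~ %s model (linear)", outcome))
}

#' Per-window psychometric indices against tonic levels
#'
#' Convenience builder for [fit_tonic_outcome()]: assigns one
#' participant's trials to tonic windows, fits a psychometric function
#' per window, and returns the paired (tonic level, fit) rows.
#'
#' @param series A [concentration_series()] for the participant.
#' @param trials The participant's trial table.
#' @param window_length,step Tonic window parameters, seconds (see
#'   [compute_tonic()]).
#' @param min_trials Windows with fewer trials are skipped.
#' @return A list with `tonic` (numeric), `fits` (list of `pf_fit`),
#'   `window` (window index), one entry per usable window.
#' @export
tonic_window_indices <- function(series, trials, window_length = 240,
                                 step = window_length, min_trials = 20) {
  tonic <- compute_tonic(series, window_length, step)
  idx <- assign_tonic_window(tonic, trials$onset_s)
  out <- list(tonic = numeric(0), fits = list(), window = integer(0))
  for (w in seq_len(nrow(tonic))) {
    rows <- which(idx == w)
    sub <- trials[rows, , drop = FALSE]
    if (length(rows) < min_trials ||
        length(unique(response_to_long(sub$response))) < 2 ||
        length(unique(sub$duration_s)) < 2) {
      next
    }
    f <- tryCatch(suppressWarnings(fit_pf(sub)), error = function(e) NULL)
    if (is.null(f)) next
    out$tonic <- c(out$tonic, tonic$tonic_da[w])
    out$fits <- c(out$fits, list(f))
    out$window <- c(out$window, w)
  }
  out
}
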