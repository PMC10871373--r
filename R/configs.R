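#' Temporal bisection task configuration
#'
#' Describes the bisection task: the two learned anchor durations, the grid
#' of test durations between them, the number of trials, the mean
#' inter-trial interval, and the recording sample rate.
#'
#' The defaults mirror the study design this package emulates: anchors of
#' 0.5 s and 1.1 s, 300 trials per session, and voltammetric sweeps at
#' 10 Hz.  Test durations are linearly spaced across the anchor range;
#' trials are allocated to duration levels as evenly as possible, with any
#' remainder distributed symmetrically about the midpoint (outermost level
#' pairs first, middle level first when the remainder is odd), so the
#' generated duration multiset is always symmetric about the arithmetic
#' midpoint of the anchors.
#'
#' @param anchor_short Short anchor duration in seconds.
#' @param anchor_long Long anchor duration in seconds; must exceed
#'   `anchor_short`.
#' @param n_levels Number of test durations, linearly spaced from
#'   `anchor_short` to `anchor_long` inclusive.
#' @param n_trials Total number of trials per session.
#' @param iti_mean Mean interval between consecutive stimulus onsets,
#'   seconds.
#' @param sample_rate Recording sample rate, Hz.
#' @return An object of class `task_config`.
#' @examples
#' task_config()
#' @export
task_config <- function(anchor_short = 0.5, anchor_long = 1.1,
                        n_levels = 7, n_trials = 300,
                        iti_mean = 5, sample_rate = 10) {
  if (!(anchor_short < anchor_long)) {
    stopf("anchor_short (%.3f) must be < anchor_long (%.3f)",
          anchor_short, anchor_long)
  }
  if (n_levels < 2) stopf("n_levels must be at least 2")
  if (n_trials < n_levels) stopf("n_trials must be >= n_levels")
  if (sample_rate <= 0) stopf("sample_rate must be positive")
  if (iti_mean <= 0) stopf("iti_mean must be positive")
  structure(
    list(anchor_short = anchor_short, anchor_long = anchor_long,
         n_levels = as.integer(n_levels), n_trials = as.integer(n_trials),
         iti_mean = iti_mean, sample_rate = sample_rate),
    class = "task_config")
}

#' Duration grid of a task configuration
#'
#' @param task A [task_config()].
#' @return Numeric vector of the `n_levels` test durations in seconds.
#' @export
duration_levels <- function(task) {
  seq(task$anchor_short, task$anchor_long, length.out = task$n_levels)
}

#' Bisection observer parameters
#'
#' Generative parameters of the cumulative-Gaussian observer that produces
#' "short"/"long" judgements.  The probability of a "long" response to a
#' probe of duration d is
#' \deqn{P(long) = \lambda/2 + (1-\lambda)\,\Phi((d - bp)/\sigma)}
#' where the trial-wise bisection point is shifted by `phasic_coupling`
#' seconds per z-unit of that trial's phasic dopamine transient
#' amplitude.  A positive coupling raises the bisection point on
#' high-transient trials, making "short" judgements more likely there —
#' the temporal-underestimation direction (note that on the P(long) axis
#' underestimation is a rightward PF shift / higher BP).  The trial-wise
#' spread is
#' \eqn{\sigma = \sigma_0 \exp(-\kappa z_{tonic})} with
#' \eqn{\sigma_0 = weber \cdot bp / 0.6745} and \eqn{\kappa} =
#' `tonic_coupling` (higher tonic dopamine gives a steeper, more precise
#' psychometric function).
#'
#' @param bp_true Generative bisection point (PF centre), seconds.
#' @param weber_true Generative Weber fraction (JND/BP), dimensionless.
#' @param lapse Lapse probability in `[0, 0.5]`.
#' @param phasic_coupling Bisection-point shift towards "short"
#'   judgements, seconds per z-unit of phasic transient amplitude.
#'   0 disables the coupling.
#' @param tonic_coupling Log-scale precision change per z-unit of tonic
#'   dopamine level at stimulus onset.  0 disables the coupling.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(bp_true = 0.8, weber_true = 0.1, lapse = 0,
                            phasic_coupling = 0, tonic_coupling = 0) {
  if (weber_true <= 0) stopf("weber_true must be positive")
  if (lapse < 0 || lapse > 0.5) stopf("lapse must be in [0, 0.5]")
  if (bp_true <= 0) stopf("bp_true must be positive")
  structure(
    list(bp_true = bp_true, weber_true = weber_true, lapse = lapse,
         phasic_coupling = phasic_coupling, tonic_coupling = tonic_coupling),
    class = "observer_params")
}

# Default voltammogram templates: smooth, unit-norm pseudo-voltammograms
# with oxidation/reduction features at distinct pseudo-potentials, so the
# two analytes are linearly independent but share a realistic degree of
# overlap.
default_templates <- function(n_features) {
  x <- seq(0, 1, length.out = n_features)
  bump <- function(c, w) exp(-0.5 * ((x - c) / w)^2)
  da <- bump(0.35, 0.08) - 0.35 * bump(0.75, 0.10)
  se <- bump(0.55, 0.09) - 0.35 * bump(0.90, 0.10)
  list(da = da / sqrt(sum(da^2)), sert = se / sqrt(sum(se^2)))
}

#' Neurochemical signal parameters
#'
#' Parameters of the synthetic voltammetric signal model: each sweep is a
#' linear mixture of a dopamine and a serotonin template weighted by the
#' instantaneous concentrations, plus a slow additive sensor drift and
#' i.i.d. Gaussian feature noise.  Concentrations are a reflected Gaussian
#' random walk (tonic component) plus stimulus-locked single-exponential
#' transients (phasic component).
#'
#' @param n_features Number of features per sweep (ignored when both
#'   templates are supplied).
#' @param template_da,template_sert Unit-norm template vectors; defaults
#'   are smooth pseudo-voltammograms with distinct peak positions.  The
#'   pair must be linearly independent.
#' @param tonic_mean Starting tonic concentration, µM.
#' @param tonic_walk_sd Random-walk innovation SD, µM per sample.
#' @param transient_amp_mean,transient_amp_sd Mean and SD of per-trial
#'   dopamine transient amplitude, µM (negative draws truncated at 0).
#' @param transient_amp_mean_sert,transient_amp_sd_sert As above for
#'   serotonin transients; default 0 (none).
#' @param transient_latency Transient onset latency after stimulus onset,
#'   seconds.
#' @param transient_tau Single-exponential decay constant, seconds.
#' @param noise_sd Feature noise SD, µM-equivalent.
#' @param drift_slope Additive sensor drift, feature-units per second,
#'   applied uniformly across features.
#' @return An object of class `neurochem_params`.
#' @export
neurochem_params <- function(n_features = 32,
                             template_da = NULL, template_sert = NULL,
                             tonic_mean = 1.0, tonic_walk_sd = 0.005,
                             transient_amp_mean = 0.15,
                             transient_amp_sd = 0.05,
                             transient_amp_mean_sert = 0,
                             transient_amp_sd_sert = 0,
                             transient_latency = 0.64, transient_tau = 0.2,
                             noise_sd = 0.02, drift_slope = 2e-4) {
  if (is.null(template_da) || is.null(template_sert)) {
    tpl <- default_templates(n_features)
    template_da <- template_da %||% tpl$da
    template_sert <- template_sert %||% tpl$sert
  }
  if (length(template_da) != length(template_sert)) {
    stopf("templates must have equal length")
  }
  n_features <- length(template_da)
  # collinear templates make the mixture unidentifiable
  cs <- sum(template_da * template_sert) /
    sqrt(sum(template_da^2) * sum(template_sert^2))
  if (!is.finite(cs) || abs(cs) > 1 - 1e-6) {
    stopf("analyte templates are collinear (|cos| = %.6f); decoding would be unidentifiable",
          abs(cs))
  }
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (transient_tau <= 0) stopf("transient_tau must be positive")
  if (tonic_walk_sd < 0) stopf("tonic_walk_sd must be non-negative")
  structure(
    list(n_features = as.integer(n_features),
         template_da = template_da, template_sert = template_sert,
         tonic_mean = tonic_mean, tonic_walk_sd = tonic_walk_sd,
         transient_amp_mean = transient_amp_mean,
         transient_amp_sd = transient_amp_sd,
         transient_amp_mean_sert = transient_amp_mean_sert,
         transient_amp_sd_sert = transient_amp_sd_sert,
         transient_latency = transient_latency,
         transient_tau = transient_tau,
         noise_sd = noise_sd, drift_slope = drift_slope),
    class = "neurochem_params")
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(
    "Bisection task: anchors %.3g-%.3g s, %d levels, %d trials, ITI %.3g s, %g Hz\n",
    x$anchor_short, x$anchor_long, x$n_levels, x$n_trials,
    x$iti_mean, x$sample_rate))
  invisible(x)
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "Observer: bp %.3g s, weber %.3g, lapse %.3g, phasic coupling %.3g s/z, tonic coupling %.3g /z\n",
    x$bp_true, x$weber_true, x$lapse, x$phasic_coupling, x$tonic_coupling))
  invisible(x)
}

#' @export
print.neurochem_params <- function(x, ...) {
  cat(sprintf(
    "Neurochemistry: %d features, tonic %.3g uM (walk sd %.3g), DA transients %.3g+/-%.3g uM, noise %.3g\n",
    x$n_features, x$tonic_mean, x$tonic_walk_sd, x$transient_amp_mean,
    x$transient_amp_sd, x$noise_sd))
  invisible(x)
}
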