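# neurochron

Simulation and analysis of how striatal dopamine dynamics, measured by
fast-scan cyclic voltammetry (FSCV) at 10 Hz, relate to human time
perception in the temporal bisection task.

The package is aimed at researchers analysing (or planning) concurrent
neurochemistry + psychophysics experiments. It implements the full
analysis chain as tested R functions:

* **Synthetic data with ground truth** — voltammetric calibration sets,
  10 Hz session recordings (tonic random-walk concentrations plus
  stimulus-locked exponential transients mixed into sweep features with
  drift and noise), and bisection responses from a cumulative-Gaussian
  observer whose bias and precision can be coupled to the phasic and
  tonic dopamine signal, respectively. Everything is seeded and
  bit-reproducible.
* **Concentration decoding** — per-analyte elastic-net regression
  (dopamine, serotonin) trained on calibration data, hyperparameters
  shared across analytes and chosen by cross-validation.
* **Tonic/phasic decomposition** — multi-minute sliding-window means,
  stimulus-locked baseline-corrected epochs, and overlap-weighted
  window summaries (default the 625–670 ms post-onset window).
* **Psychometrics** — maximum-likelihood cumulative-Gaussian fits with
  the standard bisection indices. With anchors *s* and *l*, the
  probability of a "long" judgement of probe duration *d* is

  P(long | d) = λ/2 + (1 − λ) Φ((d − BP)/σ),

  with bisection point BP (the PSE), JND = 0.6745 σ (half the 25–75%
  span) and Weber fraction = JND/BP.
* **Inference** — cluster-based permutation tests of response-conditioned
  epoch timeseries (Welch t per participant and timepoint, Stouffer
  combination, max-cluster-mass null); within-participant tercile
  partitions; mixed-effects trial-level, tercile and tonic-outcome
  models (`lme4`); Bayesian prevalence of within-participant effects and
  JZS / BIC Bayes factors.
* **Pipeline** — `run_pipeline()` chains all stages for a seeded cohort
  and emits a reproducible report; a thin CLI lives in
  `inst/cli/neurochron.R`.

See the vignette (`vignettes/striatal-dopamine-timing.Rmd`) for the
models, parameter meanings, defaults and numerical choices.

## Worked example

One coupled patient-session, decoded and analysed end to end:

```r
library(neurochron)

obs <- observer_params(phasic_coupling = 0.05, tonic_coupling = 0.2)
session <- generate_session(observer = obs, seed = 1)

cal <- generate_calibration_set(neurochem_params(), 500, seed = 1)
decoder <- fit_decoder(cal, seed = 1)
series <- decode(decoder, session)

epochs <- extract_epochs(series, session$trials)
summary_da <- window_mean(epochs)      # mean decoded DA, 625-670 ms

fit_pf(session$trials)
#> Temporal bisection psychometric fit (cumulative Gaussian)
#>   BP 0.8122 s, sigma 0.1252 s, lapse 0
#>   JND 0.08444 s, Weber fraction 0.104
#>   logLik -95.8593 on 300 trials; converged: TRUE
```

The fitted bisection point sits at the generative 0.8 s midpoint of the
0.5/1.1 s anchors, and the Weber fraction recovers the generative 0.1.
Higher phasic dopamine in the cluster window makes "short" judgements
more likely (negative summary coefficient, long = 1):

```r
fit_trial_logistic(session$trials, summary_da)
#> Trial-level judgement model (logistic) (single participant: plain fit, n = 300)
#>         term    beta     se      z         p
#>  (Intercept) -0.1860 0.1858 -1.001 3.169e-01
#>   z_duration  2.9110 0.3212  9.065 1.243e-19
#>    z_summary -0.2752 0.1961 -1.404 1.604e-01
```

while higher tonic dopamine predicts better temporal precision
(positive coefficient for −log Weber on the window's tonic level):

```r
tw <- tonic_window_indices(series, session$trials)
fit_tonic_outcome(tw$tonic, tw$fits, outcome = "precision")
#> Tonic dopamine ~ precision model (linear) (single participant: plain fit, n = 6)
#>         term   beta     se      z         p
#>  (Intercept) 2.4040 0.1430 16.810 2.223e-63
#>      z_tonic 0.2778 0.1567  1.773 7.626e-02
```

(single sessions are noisy; the cohort-level tests aggregate 25 seeded
cohorts). Prevalence of a within-participant effect seen in 5 of 6
patients at α = .05:

```r
prevalence_posterior(5, 6, 0.05)
#> Bayesian prevalence: 5/6 significant at alpha = 0.05
#>   MAP 0.8246; 96% HPDI [0.4238, 0.9868]
```

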