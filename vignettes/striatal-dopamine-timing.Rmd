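---
title: "Models and methods: striatal dopamine dynamics and temporal bisection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: striatal dopamine dynamics and temporal bisection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurochron)
```

## The scientific problem

Striatal dopamine is implicated in interval timing on two very different
timescales: sub-second, stimulus-locked *phasic* transients and
multi-minute *tonic* background levels. With fast-scan cyclic
voltammetry (FSCV) it is possible to record both at 10 Hz in the human
caudate during behaviour, decode dopamine and serotonin concentrations
from the voltammetric sweeps, and relate them to performance on a
temporal bisection task: after learning a short (0.5 s) and a long
(1.1 s) anchor, the participant judges whether each probe duration is
closer to the short or the long anchor.

`neurochron` implements that analysis chain as a tested, reusable
pipeline. Because patient recordings of this kind are not publicly
available, the package pairs the analysis with a synthetic-data
generator whose ground truth is fully known, so that every stage can be
validated by parameter recovery and calibration properties rather than
by eyeballing. The generator is a first-class module: its defaults *are*
the study conditions the analysis assumes (300 trials per session, 10 Hz
sweeps, 0.5/1.1 s anchors, a 6-patient cohort), and tests simulate from
it under controlled couplings.

## Generative model

### Neurochemistry

Per session the true dopamine concentration is

* a **tonic component**: a Gaussian random walk reflected at 0 µM
  (start 1 µM, innovation SD 0.005 µM per 100 ms sample). Over a ~25 min
  session this wanders by a few tenths of a µM — slow enough to be
  summarised by multi-minute windows, fast enough that windows differ;
* a **phasic component**: one transient per trial,
  $a\,e^{-(t-t_0-\ell)/\tau}$ for $t \ge t_0+\ell$, with amplitude
  $a \sim \mathcal N(0.15, 0.05^2)$ µM truncated at 0, onset latency
  $\ell = 0.64$ s and decay $\tau = 0.2$ s. The latency places the
  transient peak inside the 625–670 ms post-onset analysis window used
  by the phasic analyses; a latency much shorter than that window would
  leave almost no transient signal where the window summaries are taken,
  which is the point of modelling an event-locked transient at all.

Serotonin has its own tonic walk and (by default) no transients;
serotonin transients can be switched on to probe decoder cross-talk.

A voltammetric sweep at time $t$ is a linear mixture
$x_t = c_{DA}(t)\,u_{DA} + c_{5HT}(t)\,u_{5HT} + s\,t\,\mathbf 1 +
\varepsilon_t$, with unit-norm analyte templates (smooth
pseudo-voltammograms with distinct peak pseudo-potentials), a uniform
sensor drift $s = 2\times10^{-4}$ feature-units/s, and i.i.d. Gaussian
feature noise (SD 0.02 µM-equivalent). Calibration sets use the same
mixture with known labels on the full factorial of a concentration grid.
Electrochemical realism beyond mixture + drift + noise (pH transients,
fouling, background subtraction) is deliberately out of scope.

### Behaviour

Responses come from a lapse-adjusted cumulative-Gaussian observer:

$$P(\text{"long"} \mid d) = \frac{\lambda}{2} +
  (1-\lambda)\,\Phi\!\left(\frac{d - bp}{\sigma}\right)$$

with generative bisection point $bp = 0.8$ s (the arithmetic midpoint of
the anchors), Weber fraction 0.1 (so $\sigma_0 = w\,bp/0.6745$), and
$\lambda = 0$ by default. Two couplings tie behaviour to
neurochemistry:

* **phasic**: $bp_{trial} = bp + \kappa_p\, z(a)$. A positive
  $\kappa_p$ makes high-transient trials more likely to be judged
  "short" — temporal underestimation. On the $P(\text{long})$ axis this
  is a *rightward* PF shift (higher BP); we use this coherent
  convention throughout, since "underestimation" must mean more "short"
  judgements at the midpoint.
* **tonic**: $\sigma_{trial} = \sigma_0\,
  e^{-\kappa_t\, z(\text{tonic at onset})}$. A positive $\kappa_t$ makes
  high-tonic periods more precise (steeper PF). The log-linear form
  keeps $\sigma$ positive and makes $-\log(\text{Weber})$ linear in the
  tonic z-score, which is why the precision outcome below is modelled on
  that scale.

Couplings default to 0 (a null observer). Coupled simulations in the
tests use $\kappa_p = 0.03$ s/z — which yields trial-level logistic
slopes of roughly $-0.2$ to $-0.35$, the same order as the effects the
analysis is designed to detect — and $\kappa_t = 0.2$; property tests
that need high per-seed power inject larger values (0.05–0.08, 0.4) and
say so.

Durations sit on a 7-level linear grid spanning the anchors. 300 trials
do not divide evenly by 7, so allocation is as equal as possible with
the remainder placed symmetrically (outermost level pairs first, middle
level first for odd remainders); the duration multiset is therefore
always symmetric about 0.8 s and contains both anchors. Inter-trial
intervals are jittered uniformly (±20% of the 5 s mean) and rescaled to
span the session exactly.

All randomness derives from one master seed through fixed per-component
sub-streams (schedule, each tonic walk, amplitudes, sweep noise,
responses), so identical seeds give bit-identical sessions, and skipping
sweep generation (`include_sweeps = FALSE`) leaves the behavioural draw
untouched — which the behaviour-only simulations in the tests exploit.

## Decoding

`fit_decoder()` trains one elastic-net regression per analyte on a
calibration set, with a single `(l1_ratio, lambda)` pair shared across
the two analytes, selected by 10-fold cross-validation on the summed
per-analyte MSE; features are standardised with training-fold statistics
only and the final model is refit on everything. Defaults: mixing ratios
{0.1, 0.5, 0.9} and a six-decade logarithmic lambda grid. The penalty
follows the `glmnet` gaussian convention; at `l1_ratio = 0` the
coefficients equal the closed-form ridge solution, which the tests check
to 1e-8 on a small exactly-solvable problem. `decode()` is a pure affine
map per timepoint; negative concentration estimates are retained because
all downstream analyses use relative changes.

## Tonic/phasic decomposition

*Tonic*: sliding-window means (default 240 s, non-overlapping; the
window length is exposed and swept over 120/240/360 s in tests because
the tonic conclusions should not hinge on it).

*Phasic*: stimulus-locked epochs on a fixed grid from −0.5 to +1.1 s
around onset, resampled by linear interpolation, baseline-corrected by
subtracting the pre-stimulus ([−0.5, 0) s) mean. A z-scoring mode is
available since event-locked "normalisation" can mean either; baseline
subtraction is the default. Window summaries (default 625–670 ms)
average samples weighted by the overlap of each sample's 100 ms coverage
interval with the window — the 625–670 ms window does not align with the
10 Hz grid, and overlap weighting is deterministic and reduces to plain
sample means for grid-aligned windows (a nearest-sample mode is provided
as a fallback).

## Psychometric fitting

`fit_pf()` is the package's classic modelling function: maximum
likelihood for the cumulative-Gaussian PF by bounded L-BFGS-B
(bp ∈ [0.4, 1.2] s, σ ∈ [1 ms, 0.6 s], lapse fixed at 0 unless freed),
five deterministic starts, ties broken by convergence then smaller σ.
It returns a classed object with `print`, `summary`, `coef`, `predict`,
`plot`, `simulate`, `residuals`, `logLik` and `vcov` methods. Derived
indices use the conventional bisection definitions: JND = half the
25–75% span = $0.6745\,\sigma$; Weber fraction = JND/BP. Near-separable
response patterns drive σ to its lower bound and are flagged
non-converged rather than silently returned.

## Cluster-based permutation test

Per participant and epoch timepoint, a Welch t contrasts the two
response groups across trials; each t is mapped to a signed
standard-normal deviate (probit of its tail probability, numerically
stable in the far tails) and participants are combined by Stouffer's
method with equal weights — a combination that tolerates unequal trial
counts across a handful of patients and is permutation-compatible.
Clusters are maximal runs with $|z|$ above the two-sided 5% threshold,
scored by mass (sum of $|z|$); the null is the maximum cluster mass
under within-participant label permutation, and p-values use the
add-one rule $(1 + \#\{null \ge mass\})/(1 + n_{perm})$, so they are
valid at finite permutation counts. The tests verify exactness-style
calibration (type-I ≤ 0.075 at nominal 0.05 over 200 null cohorts),
power against an injected coupling, sign anti-symmetry under label
swaps, and determinism given a seed.

## Trial-level and tonic models

Terciles of the per-trial window summary are formed within participant
by ranks, ties broken by trial order, larger groups at the low end (5
values split 2/2/1). Three regression models mirror the inferential
end-products:

* `fit_trial_logistic()`: judgement (long = 1) on standardised duration
  and standardised window summary, participant random intercepts
  (`lme4::glmer`, Laplace). Negative summary coefficient = higher phasic
  dopamine → more "short" judgements.
* `fit_tercile_model()`: tercile as an ordered numeric (−1/0/+1)
  predictor; negative coefficient = underestimation in higher terciles.
* `fit_tonic_outcome()`: per tonic window, a PF is fitted to the
  window's trials; the outcome (precision = $-\log$ Weber, or
  accuracy = BP) is regressed on the standardised tonic level with
  participant random intercepts. Precision is modelled on the negative
  log scale so that "better precision" is increasing and the generative
  coupling is linear in expectation.

Random intercepts only: six participants cannot support richer random
effects. With a single participant each model reduces to the
corresponding `glm`/`lm`, which doubles as the closed-form check of the
mixed path. p-values use the two-sided normal reference on $\beta/se$ —
a small-sample approximation, stated as such in the outputs. Singular
random-intercept fits (expected when synthetic participants share
parameters) are boundary estimates, not failures.

## Bayesian prevalence and Bayes factors

`prevalence_posterior(k, n, alpha)` treats each participant's
within-participant test as significant with probability
$\theta = \alpha + \gamma(1-\alpha)$ given population prevalence
$\gamma$, puts a uniform prior on $\gamma$, and reports the closed-form
MAP $\max(0, (k/n - \alpha)/(1-\alpha))$ plus the shortest 96% HPD
interval from a $10^{-4}$-step grid (96% is the reporting level
conventional for this estimator; both level and grid step are
arguments). `jzs_ttest_bf10()` integrates the JZS Cauchy-prior Bayes
factor numerically (checked against a $10^6$-point trapezoid oracle and
an independent implementation during development);
`bic_bf10()` provides the Schwarz approximation for nested regression
comparisons and labels itself as such in its output, since full Bayesian
mixed-model machinery is out of scope.

## Pipeline

`run_pipeline()` chains simulate → calibrate → decode → decompose →
psychometrics → cluster test → inference → prevalence for an
`n`-participant cohort (default 6), with per-participant decoders, stage
toggles that fail fast when a downstream stage lacks its input, and a
report stamped with a config hash and the master seed. Identical
configurations reproduce every stochastic output bit-identically. A thin
command-line wrapper (`inst/cli/neurochron.R`) exposes `simulate`, `run`
and `prevalence`; everything else is the R API.

## Numerical choices and edge cases

* Collinear analyte templates are rejected at construction (the mixture
  would be unidentifiable).
* All-constant sweep features are dropped with a warning before fitting;
  non-finite features abort decoding with the offending timepoint named.
* Zero within-group variance in the Welch statistic maps to z = 0 for
  equal means and a saturated ±38 otherwise (beyond which normal tail
  probabilities underflow).
* Epochs exceeding the recording are dropped with a logged count; an
  epoch grid that misses time 0 is an error.
* PF fits on perfectly separable data return σ at its bound with
  `converged = FALSE`.
* `window_mean` refuses windows that overlap no sample coverage.

## Problem sizes used by the test-suite simulations

Recovery and calibration suites use: 50–100 behaviour-only sessions for
PF recovery; 400 two-participant null cohorts of 100 trials for
cluster-test type-I (the calibration property does not depend on cohort
size, and the permutation test's exact per-cohort level of
25/501 ≈ 0.0499 needs a few hundred cohorts to estimate within a
percentage point); 15–25 seeds for power and sign-recovery loops; 25 three-participant
decoded cohorts for the end-to-end sign check; 500 replicates for
prevalence coverage. These sizes were chosen as the smallest that leave
the binary pass criteria far from their thresholds under binomial noise.

## What passing tests do and do not show

The generator emulates the *statistical structure* the analysis assumes:
linear-mixture sweeps, slow tonic drift, event-locked transients, and a
psychometric observer whose bias/precision are coupled to them. Passing
recovery tests show the pipeline correctly inverts data of that
structure at realistic noise levels. They do not certify performance on
real FSCV recordings — real sweeps have non-linear backgrounds, pH and
motion artifacts, electrode-specific calibration drift, and behaviour
has sequential dependencies the observer model omits. Reported
real-data effect sizes are likewise not reproducible here, because the
original recordings are under embargo; the package instead anchors its
checks to the task constants and group-level values that are printed
(anchors, trial counts, the 0.8 s midpoint, group JNDs of 0.14/0.09 s),
used as generative ground truth.

## A worked example

```{r example, eval = FALSE}
library(neurochron)

# one coupled patient-session with full ground truth
obs <- observer_params(phasic_coupling = 0.03, tonic_coupling = 0.2)
session <- generate_session(observer = obs, seed = 1)

# decode concentrations with a calibration-trained elastic net
cal <- generate_calibration_set(neurochem_params(), 500, seed = 1)
decoder <- fit_decoder(cal, seed = 1)
series <- decode(decoder, session)

# decompose, summarise the cluster window, fit the psychometric function
epochs <- extract_epochs(series, session$trials)
summary_da <- window_mean(epochs)          # 625-670 ms window
fit <- fit_pf(session$trials)
print(fit)

# trial-level model: does phasic dopamine predict "short" judgements?
fit_trial_logistic(session$trials, summary_da)
```
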