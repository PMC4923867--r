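---
title: "Modelling central tendency in time-interval reproduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling central tendency in time-interval reproduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timeprior)
```

# The observer model

`timeprior` treats the reproduction of a time interval as Bayesian
inference. On each trial the observer receives a noisy measurement
$t \sim N(S_i, \sigma_L^2)$ of the presented duration $S_i$ and combines it
with a Gaussian prior $N(\mu_P, \sigma_P^2)$ over durations. Both
distributions being Gaussian, the posterior is Gaussian with mean

$$\mu_R = \frac{\mu_P\,\sigma_L^2 + t\,\sigma_P^2}{\sigma_P^2 + \sigma_L^2},
\qquad
\sigma_R = \frac{\sigma_P\,\sigma_L}{\sqrt{\sigma_P^2 + \sigma_L^2}},$$

and the reproduced interval is $\mu_R$ plus zero-mean Gaussian motor noise.
Averaged over measurements, reproduced durations fall on a line through the
prior mean with slope $\sigma_P^2 / (\sigma_P^2 + \sigma_L^2)$ — this is the
model's account of central tendency. The regression index $r$ is one minus
that slope; solving for the prior width gives
$\sigma_P = \sigma_L \sqrt{(1 - r)/r}$, defined only for $r \in (0, 1)$
(zero or complete regression has no finite inverse, and
`prior_width_from_regression()` refuses those inputs).

Model assumptions worth keeping in view:

* **Stationarity.** The prior is centred on the session mean stimulus and
  fixed within a session. Real sessions show a build-up of regression from
  first to second half (which `split_half_regression()` measures), so the
  stationary model is a deliberate simplification.
* **Session-level likelihood width.** $\sigma_L = \mathrm{WF} \cdot
  \bar{t}_s$ uses the *session mean* stimulus, not each trial's duration.
  This follows the model's defining equation rather than a scalar-timing
  variant in which noise grows with each stimulus.
* **Transferable Weber fraction.** The WF estimated from a 500 ms 2AFC
  discrimination task is assumed to describe sensory noise in the
  reproduction task's 1.0–1.8 s range.

# Parameters

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| `prior_width_ms` ($\sigma_P$) | ms | — | The quantity under study; the prediction-grid curves use 100–400 ms. |
| `weber_fraction` (WF) | – | — | Temporal resolution; plausible observers lie in (0, 1], and measured values outside [0, 1] are flagged for exclusion. |
| `motor_noise_coef` | fraction | 0.05 | Response noise at a 5% level. |
| `constant_bias_ms` | ms | 0 | Optional additive offset emulating the general underestimation seen in empirical data; 0 keeps the pure model. |
| `prior_mean_ms` | ms | `"session-mean"` | Stationary prior centred on $\bar{t}_s$; a number pins it instead. |
| `trials_per_duration` | – | 7 | 11 durations × 7 = 77 trials per session, the task's design. |
| 2AFC `reference_ms` | ms | 500 | Discrimination reference; WF = fitted psychometric SD / 500. |

The motor-noise level is specified only as "5%", which leaves open what the
5% is *of*. The default anchors it on the trial's noise-free posterior mean
(the produced interval's expected value), which affects response
variability but not the slope; `motor_noise_on = "stimulus"` anchors it on
the presented duration instead, so the choice is testable rather than
baked in.

# What the synthetic data emulate — and what they do not

`build_paradigm()` reproduces the task design exactly: 11 linearly spaced
durations per session (1006–1536 ms and 1270–1800 ms, 53 ms spacing), seven
presentations each, randomised order. `generate_cohort()` adds observer
heterogeneity: per-participant WF and prior width drawn from
normals truncated at zero, an optional constant bias, and a shared motor
coefficient. The heterogeneity distributions are a modelling convenience —
empirical studies report only group means and SDs of derived measures, so
the truncated-normal shape (and any correlation structure between WF and
prior width, here none) is invented. Specs whose untruncated mass is mostly
negative are refused rather than silently reshaped by truncation.

The 2AFC generator replaces the adaptive staircase used experimentally with
a fixed symmetric grid of 9 comparison levels spanning ±3 psychometric SDs
around the 500 ms reference. The estimand (the psychometric SD) is
unchanged and the placement is fully specified; the span is capped at ±90%
of the reference so every comparison stays a positive duration — for
WF ≥ 0.33 the nominal ±3 SD span would otherwise cross zero. A fixed grid
is statistically less efficient than an adaptive placement, so recovery
studies here use longer blocks than the 54 experimental trials when they
need tight per-participant estimates.

Consequently, passing tests show that the *estimators recover the
generative model's parameters* under the task's design; they cannot show
that real children behave like the generative model (no prior learning, no
lapses, no reaction-time or block structure, no attention drift).

# Estimators and their conventions

* **Reproduction line / regression index.** Ordinary least squares of
  reproduced on presented duration; $r = 1 -$ slope. Adding a constant to
  all responses changes the intercept only, so systematic under-estimation
  does not contaminate $r$.
* **BIAS / CV.** BIAS is the RMS over stimuli of (mean reproduction −
  stimulus); CV is the RMS over stimuli of the within-stimulus response SD;
  both are divided by a normaliser, and
  $\mathrm{total}^2 = \mathrm{BIAS}^2 + \mathrm{CV}^2$ holds identically.
  The exact published formulas live in supplementary material that is not
  available, so these definitions were chosen to satisfy every stated
  property: orthogonal accuracy/reliability components, quadratic
  additivity, and inflation under a smaller normaliser. The normaliser
  defaults to the session mean stimulus and is configurable
  (`normaliser_ms`) precisely because the published "interval value" is
  ambiguous.
* **Weber fraction.** Maximum-likelihood cumulative-Gaussian fit via a
  probit GLM; WF = fitted SD / reference. The lapse rate is fixed at zero
  (none is specified for the task); perfect separation — a step-function
  responder — is reported as WF 0 with a `separation` flag rather than as a
  divergent fit. At 54 trials the ML width estimate carries a small
  downward bias (~5% at WF 0.36) that vanishes by a few hundred trials.
* **Context dependency.** The overlapping duration grids of the two
  sessions are offset by 1 ms (1271 vs 1270 ms and so on), so common
  stimuli are matched within a 5 ms tolerance (configurable).
* **Split halves** are formed by presentation order, the extra trial of an
  odd count going to the first half.
* **Averaging.** A participant's regression index "across sessions" is the
  mean of the two per-session indices (not a pooled-trials fit), matching
  how group values are reported.

# Monte-Carlo machinery and numerical choices

`predict_measures_grid()` simulates each (prior width, WF) cell at 100
replicates by default — the printed simulation setting — averaging measures
across the two sessions per replicate before averaging replicates.
`relative_error_landscape()` does the same for total error; "relative"
error is normalised within each WF row, min–max to $[0, 1]$ by default
(each row attains 0 at its best prior and 1 at its worst), with
ratio-to-minimum available since the published normalisation is ambiguous.
Each cell records its Monte-Carlo standard error, and the tests require
cell stability under replicate doubling within 3 such SEs. The landscape
default of 1,000 replicates (the original analysis used 10,000) and the
test grids of a few dozen cells were chosen so a full run completes
comfortably at a desk; all replicate counts scale by argument.

`optimal_prior_width()` minimises session-averaged total error with common
random numbers: every candidate prior is evaluated on identical noise
draws, making the objective smooth enough for a coarse grid pass plus
golden-section refinement. A flat objective (notably WF = 0, where the
likelihood is exact and any prior yields veridical responses) returns the
upper search bound flagged `flat`.

One property of the model deserves emphasis because it is easy to
mis-guess: minimising the expected total error in closed form shows the
optimal prior width is approximately the population SD of the stimulus set
($\approx 168$ ms for these sessions, shrunk slightly by the finite
trials-per-duration and the motor term), *nearly independent of the Weber
fraction*. What changes with WF is the curvature: at low WF the error
surface is almost flat in $\sigma_P$ (any prior does), while at high WF
deviating from the optimum is costly. A group with a broad ~400 ms prior
and a high WF therefore sits far up its row of the relative-error surface
even though the same prior would be innocuous at low WF. The tests check
`optimal_prior_width()` against both a brute-force grid search through the
trial-level simulator and this closed form.

Degenerate inputs are governed by explicit rules: responses below 1 ms are
clamped to a 1 ms floor with a warning (physically impossible productions
must not propagate); a zero likelihood width gives full weight to the
measurement; estimator preconditions (two distinct stimuli for a slope, two
trials per stimulus for CV, both response types for a psychometric fit) are
errors with classed conditions, and the pipeline surfaces them as
machine-parsable `ERR_*` codes with non-zero exits.

# Problem sizes

The shipped tests simulate cohorts of up to 23 participants × 2 sessions ×
77 trials, recovery blocks of up to 500 2AFC trials per participant,
landscapes of up to 18 cells at 1,000–2,000 replicates, and a 500-observer
run for the headline regression-index check; `scripts/acceptance.R` uses
the same 500-observer setting. These sizes put every Monte-Carlo tolerance
at 3–5 estimated standard errors.

# Limitations

* No trial-by-trial prior updating; the stationary model cannot reproduce
  the split-half build-up it is used to measure.
* Gaussian prior and likelihood only; no lapse/guess modelling beyond the
  separation flag.
* The heterogeneity distributions and the fixed-grid 2AFC placement are
  package inventions standing in for unavailable experimental detail, and
  are labelled as such above.
* Group placement on the landscape inherits the assumptions of the
  inversion formula — in particular WF transfer across tasks — so a
  misestimated WF moves a group diagonally, not just horizontally.
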