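---
title: "Data-informed event models for task fMRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-informed event models for task fMRI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmrievents)
```

## The modelling problem

In task-based fMRI, the BOLD signal of a region of interest (ROI) is
commonly analysed with a general linear model (GLM): the measured series is
regressed on predictors built by convolving a hypothesised neural time
course with a haemodynamic response function (HRF). The neural time course
for an event with onset $o_e$ and duration $d_e$ (seconds) is the boxcar

$$ n_e(t) = \mathbf{1}\{ o_e \le t < o_e + d_e \}, $$

and the predictor is $x_e(t) = (n_e * h)(t)$ where $h$ is the HRF. Per ROI
$r$ the package fits, by ordinary least squares,

$$ y_r(t) = \beta_{0r} + \sum_e \beta_{er}\, x_e(t) + \varepsilon_r(t), $$

and scores the fit with the coefficient of determination
$R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ (TSS about the mean) and a
Gaussian-likelihood BIC. Because the appropriate onsets and durations of
the cognitive events are often uncertain, the package also searches for
them: given per-event windows and duration bounds, an elitist genetic
algorithm looks for the timing that maximises the ROI-weight-averaged
$R^2$.

The package operates on parcellated long tables (`roi`, `t`, `y`) such as
trial-averaged or residualised ROI time courses. It does not read imaging
formats, model drift or autocorrelated noise, or perform group statistics;
series should be detrended before evaluation.

## HRF kernels

Two canonical shapes are provided.

* **Double gamma** (`method = "spm"`): the difference of two gamma
  densities,
  $h(t) = g(t; a_1, s_1) - g(t; a_2, s_2)/c$, with shape $a_i$ =
  delay/dispersion and scale $s_i$ = dispersion. Defaults: peak delay 6 s,
  undershoot delay 16 s, both dispersions 1 s, peak:undershoot ratio
  $c = 6$, kernel length 32 s. The analytic mode of the positive lobe is
  `peak_delay - peak_disp` = 5 s, the default time-to-peak.
* **Single gamma** (`method = "boynton"`): a gamma density with integer
  shape $n = 3$, time scale $\tau = 1.2$ s and a pure onset delay
  (default 0 s), mode at $\delta + (n-1)\tau$.

Kernels are sampled on the grid $0, \mathrm{TR}/f, 2\,\mathrm{TR}/f,
\dots$ up to the kernel length and **peak-normalised** so
$\max h = 1$. Peak (rather than unit-area) normalisation only rescales the
$\beta$ estimates — $R^2$ and BIC are unaffected — and makes a $\beta$
read as "response amplitude at the HRF peak". `shift_time_to_peak()`
retargets a spec at a requested time-to-peak by moving the peak delay
(double gamma) or the onset delay (single gamma); the sampled argmax then
lands within one grid step of the target.

The exact default dispersions and the undershoot ratio were design choices
calibrated so that the double-gamma kernel peaks at 5 s; all of them are
exposed through `p_spm` / `p_boynton`.

## Regressor construction and numerical choices

Regressors are built at the up-sampled resolution $\mathrm{TR}/f$
(default $f = 100$), convolved, truncated to the scan, then **decimated**
at indices $0, f, 2f, \dots$ — frame $i$ is anchored at $t = i\,
\mathrm{TR}$, with the first frame at $t = 0$. Down-sampling is
decimation, not block averaging, so results are bit-reproducible and easy
to reason about. The convolution is scaled by the sample step
$\mathrm{TR}/f$ (a Riemann approximation of the continuous convolution),
which makes regressors invariant to the choice of $f$ and keeps simulated
signals on an interpretable scale.

Internally, boxcar regressors are read off a cumulative sum of the kernel:
the discrete convolution of an indicator on samples $[i_0, i_1)$ with a
kernel $K$ satisfies $z[n] = C[n-i_0] - C[n-i_1]$, $C = \operatorname{cumsum}(K)$.
Only the decimated frame samples are materialised, which makes a fitness
evaluation inside the search cost $O(\text{frames})$ per event instead of
an FFT per candidate. The test suite verifies this path against the
explicit `build_neural_matrix()` + `convolve_downsample()` pipeline and
against a direct convolution sum.

Further conventions:

* events are half-open in time ($o \le t < o + d$) and truncated at the
  scan end; an event starting at or after the scan end is an error, and a
  positive duration shorter than one sample still occupies one
  high-resolution sample;
* every per-ROI regression includes an intercept, and TSS is computed
  about the mean — necessary for a meaningful $R^2$ on non-zero-mean
  series;
* $\mathrm{BIC} = n \ln(\mathrm{RSS}/n) + k \ln n$ with $k$ = number of
  event regressors + 1 (intercept). This is the standard Gaussian BIC up
  to an additive constant; only comparisons between models fitted to the
  same series are meaningful. On exactly noiseless data RSS can be 0 and
  the BIC is $-\infty$;
* overlapping events are allowed; rank-deficient designs (e.g. duplicated
  events) are an error in `evaluate_model()`, naming the collinear
  regressors. Inside the search an occasional degenerate candidate is
  instead scored through the rank-reduced projection so one bad candidate
  cannot abort a run;
* a constant ROI series (zero TSS) is an error, not $R^2 = 0$.

Aggregates over ROIs are the mean, median, minimum, and the weighted mean
$\sum_r w_r s_r / \sum_r w_r$; unlisted ROIs have weight 1, and weights
must not all be zero.

## The genetic algorithm

Candidate solutions encode each event as an (onset, offset) pair;
duration = offset − onset. The search, run independently per constraint
set:

1. draw `population` solutions uniformly inside the constraints (onset
   uniform in the feasible onset range, duration uniform given the onset);
2. score each candidate by weighted $R^2$;
3. copy the best `elitism` fraction unchanged (stable sort, ties broken by
   population index, at least one elite whenever `elitism > 0`);
4. refill the population with children: two parents drawn
   fitness-proportionally (roulette wheel on $\max(\text{fitness}, 0)$,
   uniform fallback when no fitness is positive, since weighted $R^2$ can
   be non-positive on residualised data), single-point crossover on the
   event list (first $\lceil n/2 \rceil$ events from the first parent),
   then mutation;
5. repeat for `iter` iterations; the best-of-population trace per
   iteration is retained for convergence diagnostics (`plot_fitness()`),
   and is nondecreasing whenever `elitism > 0`.

**Mutation.** Each endpoint (onset and offset of each event) is perturbed
independently with probability `mutation_rate` by a Gaussian step with SD
equal to `mutation_sd_frac` (default 0.1) of that event's constraint
window width, then clipped to the window. If a duration bound is violated,
the endpoint that was *not* mutated is shifted minimally to restore
feasibility, so every candidate in every generation satisfies its
constraints by construction. Where a `min_duration` is not specified, the
floor is one high-resolution sample, $\mathrm{TR}/f$.

**Defaults.** `population = 100` and `iter = 100` follow common practice
for this search; `mutation_rate = 0.1` and `elitism = 0.1` were chosen as
conventional genetic-algorithm settings giving a good
exploration/exploitation balance at those sizes, and are recorded in every
result. Fitness is deterministic, so identical candidates within a run are
evaluated once (a pure optimisation).

**Reproducibility and resumption.** A `seed` makes the whole search
deterministic. Results carry the final population, so a run can be
continued with `optimize_events(resume = ...)` (also from a `search.json`
written earlier, via `read_search_results()`); traces are appended across
resumptions.

## The synthetic-data generator

`simulate_bold()` produces the study conditions under which the package is
validated: for ROI $r$,

$$ y_r(t) = \sum_e A_{re}\, x_e(t) + \varepsilon_{rt}, \qquad
   \varepsilon_{rt} \sim N(0, \sigma^2) \text{ i.i.d.}, $$

with $x_e$ built from a generating event model and a double-gamma HRF at a
chosen time-to-peak (4, 5 or 6 s by default — the default evaluation
timing and the approximate range of empirically observed HRFs), and noise
SD on the ladder 0, 0.067, 0.1, 0.15, 0.225. `factorial_grid()` enumerates
the full design: four generating models × three times-to-peak × five
noise levels = 60 datasets, each with its own derived seed.

The shipped fixtures are inputs, not claims:

* `wm_example_models()` — four plausible three-event models (encoding,
  delay, response) of a slow event-related working-memory trial over
  roughly 13 s plus return-to-baseline, two theory-like and two with later
  onsets/shorter durations;
* `default_amplitudes()` — 10 hypothetical ROIs with per-event amplitudes
  drawn once (fixed seed) from $U(0.5, 1.5)$: clearly active regions with
  about a three-fold spread in responsiveness;
* `amplitude_grid()` — a full factorial of per-event amplitude levels
  (6 levels per 3 events = 216 ROIs by default, levels kept strictly
  positive so no simulated ROI is signal-free). The factorial structure is
  what lets `beta_recovery()` ask how much the $\beta$ of one event is
  contaminated by the activity of the others: for each target amplitude
  level there is a group of ROIs identical in the target event but varying
  in the rest.

The generator emulates single-trial (trial-averaged) series with white
Gaussian noise. It deliberately omits physiological drift, autocorrelated
noise, HRF variability across ROIs, jittered multi-trial structure and
motion artefacts — so passing tests demonstrate correctness of the
machinery and recoverability under idealised conditions, not performance
on raw empirical data.

## Recovery metrics

* `overlap_coverage(simulated, estimated)` =
  $100\,|s \cap e| / |s|$: the percentage of the true event interval
  covered by the estimate.
* `overlap_robustness(intervals)` =
  $100\,|\bigcap_i I_i| / |\bigcup_i I_i|$: the common time covered by all
  recovered intervals relative to the time covered by any — used both
  across noise levels and across recording sessions.
* `beta_recovery()` reports, per event, the Pearson correlation between
  simulated amplitudes and estimated $\beta$s across ROIs (reported as
  `NA`, not 0, when the amplitude column is constant), and per amplitude
  level the range of the $\beta$s plus a bootstrap percentile 95% CI of
  their mean.

## Problem sizes used in the tests and acceptance script

The validation suite runs at desk scale, chosen to exercise every code
path while keeping a full run in the order of a minute or two: 10-ROI
datasets with 28–30 frames at TR 1 s, searches with population 50 and
50–100 iterations, five search seeds per condition, and the 216-ROI
factorial for amplitude recovery. On zero-noise data whose generating
model lies inside strict constraint windows (windows equal to the
generating intervals), such a search reliably reaches weighted
$R^2 \ge 0.99$ and near-complete coverage of the long delay event;
recovery of the short encoding event is best when the data-generating HRF
matches the 5 s evaluation timing and degrades at 4 s or 6 s — shorter
events are intrinsically harder, since a small timing shift is a large
fraction of their length.

## Known limitations

* One event model for all ROIs; per-ROI or per-participant optimisation is
  out of scope.
* No nuisance modelling (drift, autocorrelation); inputs must be
  pre-processed accordingly, and $R^2$ on residualised data can be
  negative.
* The BIC is defined up to a constant; it should never be compared across
  different datasets or series lengths.
* Search cost grows linearly with population × iterations × ROIs; the
  cumulative-sum fast path keeps desk-scale problems in seconds, but
  voxelwise use is not intended.
* Runs are reproducible for a fixed seed, R version and platform;
  floating-point results may differ in the last bits across BLAS builds.
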