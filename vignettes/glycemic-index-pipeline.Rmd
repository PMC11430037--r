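---
title: "Glycemic indices for irregular ICU glucose series: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycemic indices for irregular ICU glucose series: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycindex)
```

## The problem

After an aneurysmal subarachnoid hemorrhage (aSAH), roughly a third to a
half of ICU patients develop delayed cerebral ischemia (DCI), typically
between day 3 and day 14. Blood glucose is measured frequently but
irregularly in these patients — every few hours, more often when the
patient deteriorates — so naive summary statistics confound the glucose
process with the sampling process. `glycindex` implements a set of
sampling-aware indices for such traces, an event-anchored windowing of
each trace around DCI onset, cohort-level event-aligned dysglycemia
curves, and the statistical cascade used to relate the indices to the
event.

All computation uses hours since ICU admission and mg/dL; traces are
truncated at 336 h (14 days), the assumed DCI window.

## The indices

For a window containing measurements $(t_i, g_i)$, $i = 1..n$:

* **MBG** $= \frac{1}{n}\sum_i g_i$. Sensitive to measurement clustering:
  a burst of samples during a hyperglycemic episode drags the mean.
* **TWAG** $= \frac{1}{t_n - t_1}\int_{t_1}^{t_n} \hat g(t)\,dt$ with
  $\hat g$ the piecewise-linear interpolant (trapezoidal rule). The
  denominator is the *observed* span $t_n - t_1$, not a nominal window
  length: the curve is undefined outside the measurements and we do not
  extrapolate. For the same reason the pre-onset and post-onset TWAG of
  a DCI patient are computed on their own measurement sets, with no
  interpolation across the onset boundary. Whether step (last value
  carried forward) or trapezoidal integration is used matters little at
  2–4-h sampling; we use the trapezoid as the natural reading of "area
  under the glucose curve".
* **CV** $= 100\,s_g / \mathrm{MBG}$ with the sample ($n-1$) standard
  deviation. The $n-1$ convention is pinned by tests.
* **AACTD** $= \frac{1}{n-1}\sum_i |g_{i+1} - g_i| / (t_{i+1} - t_i)$ —
  the mean of per-pair absolute rates, not total variation over total
  time. The two readings differ for uneven spacing; the per-pair mean is
  the direct reading of "average absolute change divided by the
  inter-measurement time". It doubles when the same excursions happen
  twice as fast, which the tests assert as a scaling law.
* **TUDR** — the time-unified dysglycemic rate. The admission-anchored
  timeline is cut into fixed periods of length $L$; a period is
  *dysglycemic* if any of its values leaves the corridor (below
  70 mg/dL or above 140/160/180 mg/dL); the individual TUDR is the
  fraction of dysglycemic periods among evaluated periods. Fixed
  periods, unlike absolute time in range, are robust to unlucky timing
  of sparse measurements.

### Period grids and conventions

Periods are half-open $[kL, (k+1)L)$. The grid is clipped at the last
measurement: a value falling exactly on the boundary closing the
observed span belongs to the final evaluated period, so a 30-h trace on
a 6-h grid occupies five periods, not five plus a zero-width sixth.

Two conventions are genuinely underdetermined and are therefore explicit
design choices:

* **Empty periods** are excluded from both numerator and denominator of
  the individual TUDR. Counting them in the denominator would label
  unobserved time normoglycemic; the coverage-based period-length
  selection exists precisely to make empty periods rare. The alternative
  is available as `count_empty = TRUE` but is not the default.
* **A measurement exactly at DCI onset** belongs to the post window (the
  pre window is half-open), and in event-anchored grids period $k = 0$
  does not exist: $k = -1$ ends at onset, $k = +1$ starts at it. The
  pre/post split and the event-aligned grids therefore agree on every
  measurement.

### Period-length selection

For each candidate $L \in \{1, 3, 6, 12\}$ h we compute, per patient,
the fraction of grid periods between their first and last measurement
that contain at least one measurement, and take the cohort median. The
selected length is the shortest candidate whose median coverage reaches
95%. The "median of per-patient coverage" reading is implemented (rather
than "percent of fully covered patients"); with 2.8–4-h sampling it
reproduces the familiar outcome that 3-h periods are too sparse
(median coverage well below 95%) while 6-h periods pass.
Raising the threshold can only push the choice towards longer periods,
which the tests assert as a monotonicity property.

## Event-aligned analysis

For each DCI patient, onset defines time zero and signed 6-h periods
extend 168 h each way. Per period $k$ the cohort-level **cumulative
TUDR** is the fraction of patients with at least one out-of-corridor
value among patients with any measurement in that period — patients not
measured in a period drop out of that period's denominator — and the
per-period **TWAG distribution** collects within-period TWAGs of
patients with at least two measurements in the period.

The interrupted time-series model is segmented OLS on the per-period
series $y_k$ (median TWAG, or cumulative TUDR rate):

$$y_k = \beta_0 + \beta_1 k + \beta_2\,\mathbb{1}(k>0)
        + \beta_3 (k - k_+)\,\mathbb{1}(k>0) + \varepsilon_k$$

with $k_+$ the first post-onset period, so $\beta_2$ is the level change
at onset, $\beta_1$ the pre-onset slope and $\beta_1 + \beta_3$ the
post-onset slope. The model form is a package choice: segmented
regression with a level and a slope change is the standard interrupted
time-series parameterisation, and the p-value for the post slope is a
Wald test on the linear combination $\beta_1 + \beta_3$. Periods whose
denominator is empty contribute no point and are dropped before
fitting; the fit requires at least three points per segment.

## The statistical cascade

Glycemic indices are compared with the Mann–Whitney U test (no-DCI vs
each DCI window) and the Wilcoxon matched-pairs signed-rank test (pre vs
post within DCI patients); binary variables with Fisher's exact test;
normally-behaved baseline variables with Welch's t-test, with a
percentile-t bootstrap (10,000 resamples of the group-centred values)
for skewed ones. When paired differences have tied absolute values and
at most 15 non-zero pairs, the signed-rank p-value is computed by exact
enumeration of all sign flips of the midranks, because the usual
implementation silently switches to a normal approximation under ties.
When every value is identical the tests return p = 1 with a degenerate
flag rather than an error.

Before regression, predictors correlated at Pearson $r \ge 0.50$ are
grouped by transitive closure (so an MBG–TWAG–TUDR140 chain forms one
group even if MBG and TUDR140 fall just under the threshold) and each
group is represented by its member with the smallest univariate
logistic p-value. The threshold is applied to the signed correlation.
Univariate logistic fits report per-unit odds ratios with Wald 95%
intervals ($e^{\hat\beta \pm 1.96\,SE}$); predictors with univariate
p < 0.05 enter one joint multivariable model. Fits flagged for
non-convergence or separation (explosive standard errors) are excluded
from the joint model and reported with their flag. No multiple-testing
correction is applied anywhere; the cascade is exploratory and the
p-values are interpreted as such.

## The synthetic cohort generator

Real per-patient glucose traces from such cohorts are not publicly
deposited, so the package ships a generator whose defaults encode the
study conditions the pipeline targets: 46.4% DCI incidence with onset
uniform on 72–336 h; truncated-normal inter-measurement intervals
(mean ± SD 4.0 ± 1.6 h for no-DCI, 2.8 ± 0.8 h for DCI patients, lower
bound 0.25 h, matching the stated mean ± SD parameterisation directly);
glucose as `setpoint(t) × (1 + 0.18 · z_t)` where the setpoint is
125.6 mg/dL for no-DCI patients and steps from 130.7 to 149.2 mg/dL at
onset for DCI patients; and `z_t` a stationary lag-1 autoregressive
standard normal sequence with coefficient 0.5. The step (rather than a
ramp) mirrors the observed level shift at onset with no within-segment
trend; the AR(1) multiplicative noise makes consecutive-measurement
changes — hence the AACTD — finite and tunable, and the 0.5 coefficient
is a realistic middle ground for few-hourly glucose autocorrelation.
Values are floored at 40 mg/dL to avoid non-physiological output; the
floor is arbitrary but documented, and at the default noise level it is
a > 3σ event. Covariates (age, sex, mFisher, Hunt & Hess, SAPS II) are
drawn with group-dependent distributions typical of aSAH cohorts, with
an age–SAPS II correlation near 0.5 so that the screening stage has a
realistic collinear pair to resolve.

What the generator does *not* emulate: insulin and nutrition dynamics,
circadian structure, measurement error, informative sampling (clinicians
measuring more when glucose is abnormal), or any feedback from glucose
to DCI risk — group membership is assigned, not caused. Parameter
recovery on this generator therefore validates the *estimators* (that
TWAG, interval statistics, the ITS level change and logistic CIs recover
what was injected), not any clinical claim about real cohorts. The
generator targets process means, while cohort tables usually report
medians; recovery tests compare generator means with estimated means and
medians of per-patient statistics, which for these symmetric noise
settings nearly coincide.

## Numerical and testing choices

Problem sizes were chosen to make the test suite informative yet quick:
parameter recovery uses 20 cohorts of 400 patients (interval and
setpoint recovery within 0.2 h and 5 mg/dL), 500 replicates each for the
ITS step-recovery and logistic CI-coverage simulations, and 1,000-trace
sweeps for the structural invariants (corridor monotonicity, TWAG
collinear-insertion invariance, CV scale invariance, the AACTD scaling
law). Exact tests are pinned against brute-force enumeration oracles at
n ≤ 10, TWAG against dense trapezoidal integration at 0.001-h steps, and
logistic coefficients against direct likelihood maximisation on a tiny
fixture. Null calibration of the rank tests at α = 0.05 is checked to
land in [0.03, 0.07] over 1,000 simulations; Fisher's exact test is
checked against its enumeration oracle and its null rejection rate
bounded above, but its lower bound is relaxed because the conditional
test is conservative by construction on discrete tables.

Storage precision is 0.01 h and 0.1 mg/dL; round-trips through the CSV
format are lossless at that precision. All simulations accept explicit
seeds, and the generator restores the caller's RNG state.

## Worked example

```{r example, eval = FALSE}
library(glycindex)

cohort <- generate_cohort(generator_config(n_patients = 150, seed = 1234))
out <- analyze_cohort(cohort)

out$period_h            # 6 (coverage-selected)
out$coverage_medians    # per-candidate median coverage
subset(out$comparisons, variable == "twag")
out$regression$univariate
out$its                 # level change at onset per series
```

## Known limitations

* The pipeline analyses a single event per patient; recurrent or
  uncertain onset times are out of scope.
* Cumulative curves treat patients as exchangeable within a period;
  there is no within-patient correlation model in the ITS stage, whose
  OLS p-values are therefore exploratory, consistent with the cascade's
  stance.
* The individual-TUDR empty-period rule and the onset boundary
  convention are choices on genuinely underdetermined points (see
  above); both are surfaced in the API rather than buried.
* Fisher's exact p-values are conservative on small tables; this is a
  property of the test, not of the implementation.
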