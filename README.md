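# glycindex

Glycemic variability indices and event-aligned dysglycemia analysis for
irregularly sampled ICU blood-glucose time series.

## What this is for

In neurocritical care, blood glucose after aneurysmal subarachnoid
hemorrhage (aSAH) is measured every few hours at irregular intervals, and
patients who develop delayed cerebral ischemia (DCI, typically days 3–14)
tend to be sampled more densely than those who do not. Plain summary
statistics therefore mix up the glucose process with the sampling
process. `glycindex` computes sampling-aware per-patient indices, splits
each DCI patient's trace into pre-onset and post-onset windows, aligns the
whole cohort at DCI onset, and runs the associated statistical cascade.

For a window with measurements $(t_i, g_i)$, $i = 1..n$ (hours, mg/dL):

| Index | Definition |
|---|---|
| MBG | $\frac{1}{n}\sum_i g_i$ |
| TWAG | $\frac{1}{t_n-t_1}\int_{t_1}^{t_n}\hat g(t)\,dt$, trapezoidal on the piecewise-linear interpolant |
| CV | $100\, s_g/\mathrm{MBG}$ (sample SD) |
| AACTD | $\frac{1}{n-1}\sum_i \lvert g_{i+1}-g_i\rvert/(t_{i+1}-t_i)$ |
| TUDR | fraction of fixed-length periods containing a value outside the corridor (70 to 140/160/180 mg/dL), among periods containing a measurement |

The TUDR period length is selected from measurement coverage: the
shortest of 1/3/6/12 h whose median per-patient coverage reaches 95%.
Cohort-level *cumulative* TUDR curves report, per signed 6-h period around
each patient's own onset, the fraction of measured patients with an
out-of-corridor value; an interrupted time-series model
$y_k=\beta_0+\beta_1 k+\beta_2\mathbb{1}(k>0)+\beta_3(k-k_+)\mathbb{1}(k>0)$
estimates the level change at onset and the within-segment trends.

Because real traces of this kind are not publicly deposited, the package
includes a seeded synthetic-cohort generator (`generate_cohort()`) with
known ground truth — irregular truncated-normal sampling intervals, a
step in the glucose setpoint at onset, lag-1 autocorrelated multiplicative
noise — used throughout the test suite for parameter-recovery checks.

## Worked example

```r
library(glycindex)

cohort <- generate_cohort(generator_config(n_patients = 150, seed = 1234))
out <- analyze_cohort(cohort)

out$period_h
#> [1] 6
round(out$coverage_medians, 3)
#>    1h    3h    6h   12h
#> 0.268 0.735 1.000 1.000
subset(out$comparisons, variable == "twag" & comparison == "pre_vs_post",
       c(median_pre, median_post, p_value))
#> # A tibble: 1 × 3
#>   median_pre median_post  p_value
#>        <dbl>       <dbl>    <dbl>
#> 1       131.        149. 7.24e-13
subset(out$its, series %in% c("twag", "tudr140"),
       c(series, level_change, level_change_p, pre_slope_p, post_slope_p))
#> # A tibble: 2 × 5
#>   series  level_change level_change_p pre_slope_p post_slope_p
#>   <chr>          <dbl>          <dbl>       <dbl>        <dbl>
#> 1 twag          19.0         5.29e-15     0.00872     0.000291
#> 2 tudr140        0.233       1.49e- 9     0.0442      0.542
```

Reading this: 6-h periods were coverage-selected; within DCI patients the
time-weighted average glucose rises from a median of 131 to 149 mg/dL
after onset (signed-rank p ≈ 7e-13); the interrupted time series detects
a level jump at onset of ≈ 19 mg/dL in TWAG — close to the 18.5 mg/dL
setpoint step the generator injects — and of ≈ 0.23 in the cumulative
dysglycemia rate at the 70–140 corridor. (The small but nominally
significant within-segment slopes are what exploratory OLS p-values look
like on one realisation; the recovery simulations in the test suite are
the calibrated statement.)

A worked individual-TUDR example: a 30-h trace sampled every 2 h at
120 mg/dL, with 150 mg/dL excursions at t = 7 h and t = 19 h, has five
admission-anchored 6-h periods of which the second and fourth are
dysglycemic at the 70–140 corridor:

```r
t <- sort(c(seq(0, 30, 2), 7, 19))
g <- ifelse(t %in% c(7, 19), 150, 120)
individual_tudr(t, g, high = 140, period_length = 6)
#> [1] 0.4
```

A thin command-line wrapper over the same functions lives in
`inst/cli/glycindex.R` (subcommands `simulate`, `indices`, `tudr`,
`analyze`).

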