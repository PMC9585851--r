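---
title: "How risize estimates the minimum sample size for a reference interval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How risize estimates the minimum sample size for a reference interval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(risize)
```

## The problem

A 95% reference interval (RI) is bounded by the 2.5th and 97.5th
percentile reference limits of a healthy population, and each limit is
itself an estimate with sampling uncertainty. The working rule in
clinical chemistry is that a limit is trustworthy when its 90%
confidence interval is narrower than 0.2 times the RI width. The
long-standing guideline minimum of 120 reference subjects comes from
the smallest n at which a non-parametric 90% CI of a percentile can be
formed at all — it says nothing about whether 120 is *enough* for a
given analyte, nor whether a parametric estimator could do with less.

`risize` turns the 0.2 rule into a sample-size estimator: given a large
reference dataset (real or synthetic), it finds the smallest n at which
both reference limits satisfy the rule *stably* under resampling.

## The procedure

Write `x` for the cleaned reference population of one analyte. For each
candidate size n on a grid:

1. **Inner bootstrap.** Draw B resamples of size n with replacement
   from `x`. On each resample compute the RI limits by the method under
   study:
   - *transformed parametric*: fit a Box–Cox transform
     `y = ((x + c)^λ − 1)/λ` (λ by profile maximum likelihood, shift
     `c = 1 − min(x)` only when values are non-positive), take
     `m ± z·s` on the transformed scale with
     `z = Φ⁻¹(0.975) ≈ 1.959964`, and back-transform;
   - *non-parametric*: the empirical 2.5th/97.5th percentiles.
2. **Limit CIs.** The 90% percentile-bootstrap CI of the lower and of
   the upper limit (5th and 95th percentiles of the B replicate
   limits).
3. **Ratios.** `R1 = LLW_CI / W_RI` and `R2 = ULW_CI / W_RI`, where
   `W_RI` is a scalar summary of the B bootstrap RI widths (default:
   their median).
4. **Flag.** n passes (flag 1) iff both ratios are below the threshold
   0.2.
5. **Stabilization.** Because R1 and R2 fluctuate with n, the first
   passing n can be a transient. The flag sequence is smoothed by a
   moving sum of window w = 10, then a moving median of window w; the
   estimate is the grid value at which the moving median first equals
   w, i.e. the start of the first run in which essentially every
   neighbouring size passes.
6. **Validation.** The two ratios are re-measured at the estimate with
   an independent seed and reported alongside it.

The method assumes the input population is large relative to the
candidate sizes (several thousand values, so resampling at n ≤ 2000
explores genuine sampling variability), describes healthy subjects, and
has been cleaned of outliers. It estimates the size needed to pin down
the *population's own* limits; it cannot correct a biased population.

## Tunable parameters

All constants live in `ri_control()`:

| parameter | default | meaning |
|---|---|---|
| `n_min`, `n_max`, `step` | 40, 2000, 1 | candidate grid, in subjects. With `step > 1` the estimate's resolution is ±step. |
| `B` | 1000 | bootstrap resamples per candidate n |
| `ri_level` | 0.95 | RI coverage |
| `ci_level` | 0.90 | bootstrap CI level of each limit |
| `threshold` | 0.2 | pass criterion on both ratios (dimensionless) |
| `window` | 10 | moving sum/median width, in grid steps |
| `width_summary` | `"median"` | scalar summary of the B RI widths |
| `seed` | 1 | root seed for all resampling |
| `early_stop` | `TRUE` | stop the sweep once the estimate is final |
| `report_position` | `"run_start"` | index-to-n mapping (below) |
| `tukey` | `TRUE` | Tukey fence filtering of the input, once, up front |

The defaults reproduce the published procedure; anything smaller
(`B`, `step`) is a speed/precision trade-off that leaves the estimator
unchanged.

## Design choices where the procedure is underdetermined

**Quantile convention.** One convention is used everywhere (reference
limits, bootstrap CIs, Tukey quartiles, width summaries): linear
interpolation of order statistics at plotting position k/(n+1) — the
CLSI rank `r = p(n+1)` rule for non-parametric reference limits, and
`type = 6` in `stats::quantile()`. Ranks outside [1, n] clip to the
extreme order statistics.

**"Quintile" of the RI widths.** The denominator of the ratios must be
a scalar, but quintiles are four cut points. The default is the median
of the B widths — the only robust single-number reading — with
`width_summary = "quintile1"… "quintile4"` and `"mean"` available for
sensitivity analysis.

**Bootstrap CI flavour.** Plain percentile (no BCa or basic), matching
the choice of a bootstrap CI over closed-form formulas in the first
place: the same machinery serves both estimators, so their CI widths
are directly comparable.

**Index-to-n mapping.** Each smoothing pass shortens the sequence by
w − 1, so "the n where the moving median first equals w" is ambiguous.
The default maps the first all-pass median index j back to
`n_grid[j]` — the start of the earliest window contributing to it,
i.e. the beginning of the stable run. The alternative reading,
`n_grid[j + 2(w−1)]` (the end of the double window), is available as
`report_position = "window_end"`; the two differ by at most
2(w−1)·step subjects.

**Early stopping.** The first all-pass median index cannot change once
it is observed (it depends only on flags up to 2(w−1) grid steps past
the run start), so the sweep halts there by default. `early_stop =
FALSE` evaluates the full grid, e.g. for trace plots. Either way every
bootstrap at a given (n, method) uses a seed derived deterministically
from the root seed by integer hashing, so results are identical under
any evaluation order, early stopping, or method subset — and the
validation re-run uses a separately keyed seed that no search step ever
uses.

**Outlier filtering.** Tukey fences (Q1 − 1.5·IQR, Q3 + 1.5·IQR) are
applied once to the raw input, not inside the bootstrap loop — per-
resample filtering would change the resampling distribution mid-search.
Filtering on the raw rather than a transformed scale is a documented
choice (`tukey = FALSE` turns it off). Note one consequence for clean
synthetic data: on an exact lognormal population the upper fence sits
near the 96th–98th percentile, so filtering truncates the tail and
*reduces* the sample size the non-parametric method appears to need.
Property checks on explicitly specified synthetic populations therefore
run with `tukey = FALSE`, while the worked examples keep the full
pipeline a practitioner would run on real data.

**Always-transform parametric arm.** The "transformed parametric"
method always fits Box–Cox (λ is free, and lands near 1 for already-
normal data) rather than gating the transform on a per-sample normality
test — gating per resample would mix two different estimators within
one bootstrap distribution. The Lilliefors-corrected KS report
(`ks_normality()`) is descriptive.

## Numerical details and degenerate inputs

- λ is maximized over [−5, 5] with `stats::optimize()` at tolerance
  1e-5; near-ties are broken toward smaller |λ|. The transform uses
  `expm1`/`log1p` forms, and invert∘apply is the identity to < 1e-9.
- Back-transforming `m ± z·s` can leave the Box–Cox range (e.g. the
  lower limit with λ > 0 on short-tailed data); the limit is then
  clipped to the domain boundary and the interval flagged, not an
  error.
- A constant bootstrap resample has no Box–Cox likelihood; such
  replicates are redrawn (up to 10·B attempts, with the count recorded)
  so all B replicates are effective. A constant *population* makes the
  parametric search an error and gives the non-parametric method a
  zero-width RI, which is treated as a degenerate evaluation: ratio 0/0
  is a failure (flag 0), never a pass.
- Non-convergence by `n_max` is a first-class result (`converged =
  FALSE`, `estimated_n = NA`, full trace retained; `NC` in TSV
  reports), because convergence before any fixed bound is a property of
  the dataset, not a guarantee.

## The synthetic generator

`generate_population()` draws from normal, lognormal, gamma or
two-component normal-mixture distributions; `true_ri()` returns the
generating distribution's exact 2.5th/97.5th quantiles (closed form, or
CDF inversion at tolerance 1e-8 for mixtures), so RI recovery can be
checked against ground truth. The `analyte_preset()`s pin only the
*between-subject coefficient of variation* of five thyroid analytes —
TSH-like lognormal at CV 35%, and normal FT3/FT4/TT3/TT4-like at CV
6.0/7.7/9.4/6.4% — at a default location of 1.0 analyte units; the
estimator is location/scale-equivariant for the normal family and
scale-equivariant for the lognormal, so only shape and CV matter.

What the presets do *not* emulate: analytical (assay) imprecision,
within-subject variation, age/sex structure, mixture contamination from
undiagnosed disease, or the heavier-than-lognormal tails real TSH data
can show. Passing tests on these populations therefore demonstrates
that the estimator behaves correctly for the stated shapes and CVs —
not that any particular analyte needs any particular n in a given
laboratory; with real data, expect larger estimates than the clean
presets give, especially for skewed analytes.

## Problem sizes used by the test-suite and acceptance script

The package's checks use populations of 5000 (100,000 for quantile-
recovery checks), B between 50 and 300, and grid step 5–25 — the
package's demonstration scale, at which the estimator's qualitative
properties (CI narrowing with n, parametric-before-non-parametric
ordering, threshold monotonicity, seeded determinism) are already
stable across seeds. The procedure defaults (B = 1000, step 1) sharpen
the estimates without changing these properties.

## Known limitations

- The estimate inherits the grid resolution (±step) and, through the
  stabilization windows, shifts by at most 2(w−1)·step between the two
  reporting conventions.
- With B in the low hundreds the flag sequence is noisy near the
  crossing point; the moving-median stage absorbs most but not all of
  it, so estimates at coarse settings vary by a few grid steps across
  seeds.
- The robust (small-sample) RI estimator and indirect/data-mining RI
  methods are out of scope, as are multi-analyte joint designs and
  age/sex partitioning — the tool estimates one analyte, one
  population, one partition at a time.
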