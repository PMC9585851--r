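# risize

How many reference subjects do you need before a clinical reference
interval (RI) is worth publishing? `risize` answers that question for a
single analyte by simulation from the data you already have: it estimates
the minimum sample size at which the 95% RI becomes *stable*, separately
for the two standard direct estimators —

- the **transformed parametric** method: Box–Cox-transform the data
  toward normality, take `m ± z₀.₉₇₅·s` on the transformed scale, and
  back-transform the limits;
- the **non-parametric** method: the empirical 2.5th and 97.5th
  percentiles (CLSI rank convention `r = p(n+1)`).

It is aimed at clinical-laboratory statisticians planning direct RI
studies, and at anyone re-examining the blanket "120 samples" rule:
analytes with small biological variation stabilize well below 120 with
the parametric method, while skewed, high-variation analytes (TSH-like)
need far more.

## The estimator

For each candidate sample size `n` on a grid (default 40…2000, step 1):

1. Draw `B = 1000` bootstrap resamples of size `n` with replacement from
   the reference population and compute both RI limits on each resample.
2. Form the 90% percentile confidence interval of the lower and the
   upper limit from their bootstrap distributions.
3. Divide each CI width by a scalar summary (default: median) of the
   `B` bootstrap RI widths, giving the ratios
   `R1 = LLW_CI / W_RI` and `R2 = ULW_CI / W_RI`.
4. Flag `n` as passing when `R1 < 0.2` and `R2 < 0.2` (a reference
   limit's CI should be narrower than one fifth of the RI).
5. Smooth the 0/1 flag sequence with a moving sum of window 10, then a
   moving median of window 10; the estimate is the first `n` whose
   moving median reaches 10 — the first **stably** passing size, immune
   to transient passes caused by bootstrap fluctuation.

The ratios at the estimate are then re-measured with an independent seed
(the "validation" columns); being a fresh stochastic re-run they are
usually, but not always, below 0.2.

## Worked example

A right-skewed, TSH-like population (lognormal, between-subject CV 35%)
with a known true interval:

```r
library(risize)
spec <- analyte_preset("tsh_like", pop_size = 5000, seed = 42)
pop  <- generate_population(spec)
true_ri(spec)
#> 95% reference interval (analytic, n = NA): [0.4848, 1.838]
nonparametric_ri(pop$values)
#> 95% reference interval (non-parametric, n = 5000): [0.4772, 1.826]

fit <- ri_samplesize(pop, method = "both",
                     control = ri_control(B = 200, step = 5, seed = 42))
fit
#> Minimum sample size for reference interval establishment
#>   analyte: tsh_like (n = 4877, au); Tukey-removed: 123
#>   grid 40..2000 step 5, B = 200, threshold 0.2, window 10, seed 42
#>   transformed parametric  n = 95  (validation LLW_CI/W_RI = 0.096, ULW_CI/W_RI = 0.205)
#>   non-parametric          n = 110  (validation LLW_CI/W_RI = 0.111, ULW_CI/W_RI = 0.196)
coef(fit)
#>    parametric nonparametric
#>            95           110
```

Reading the output: after Tukey outlier filtering (123 values removed),
the transformed parametric RI becomes stable at n = 95 reference
subjects while the non-parametric one needs n = 110 — the parametric
method's limits typically settle earlier, and the gap widens with
skewness.
The validation columns are the two CI-width/RI-width ratios re-measured
at the estimate with a fresh seed; values slightly above 0.2 (here
0.205) are the expected stochastic wobble of a re-run. `plot(fit)` draws
R1/R2 against n with the 0.2 threshold and the estimate marked;
`summary(fit)` and `write_report(fit, "report.json")` give the full
trace.

Note that these are demonstration settings (`B = 200`, grid step 5);
with the procedure defaults (`B = 1000`, step 1) estimates are sharper
and runtimes correspondingly longer. The grid step bounds the
resolution of the estimate (±5 here).

## Command line

```sh
Rscript inst/cli/risize.R estimate --input tsh.csv --column TSH \
    --B 1000 --step 1 --seed 7 --out report.json
Rscript inst/cli/risize.R simulate --preset tsh_like --pop-size 5000 --out pop.csv
Rscript inst/cli/risize.R ri --input pop.csv --column tsh_like --n 150
Rscript inst/cli/risize.R trace-plot --report report.json --out trace.png
```

Input can be CSV/TSV (one column per analyte) or a GCT v1.2/1.3
expression matrix (`--gene SYMBOL`, one gene row becomes the
population). Exit codes: 0 success, 2 input error, 3 non-convergence
(the report is still written, with `SampleSize = NC`).

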