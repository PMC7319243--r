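# rogersfr

Estimation and validation tools for predator functional responses from
**non-replacement** feeding trials, for quantitative ecologists comparing
consumer–resource interaction strengths across predator and prey size
classes.

When eaten prey are not replaced, prey density declines during a trial
and the Holling disc equation no longer describes the data. The correct
model is Rogers' random predator equation,

    Ne = N0 (1 - exp(a (Ne h - T))),

with attack rate `a` (cage/hr), handling time `h` (hr/prey) and trial
duration `T` (hr). The equation is implicit in the number eaten `Ne`;
the package solves it explicitly through the Lambert W function,

    Ne = N0 - W(a h N0 exp(-a (T - h N0))) / (a h),

and fits it to trial data by maximum likelihood with binomial errors.
Around that core the package provides:

* **Classification** of response type (II vs III) by logistic regression
  of proportion eaten on density, with AIC arbitration across type II /
  Hassell type III / generalized non-replacement forms when signs are
  equivocal (`classify_fr()`).
* **Bootstrap uncertainty** for `a` and `h` (density-stratified
  resampling, draws floored at 0) and Gamma-GLM comparison of draws
  across species and size classes (`bootstrap_fr()`,
  `compare_bootstrapped_params()`).
* **Body-mass-ratio scaling**: log-transformed parameters regressed on
  log10 predator–prey mass ratio, polynomial degree 1–3 selected by AICc
  (`fit_scaling()`).
* **Prey-depletion bias study**: a deterministic validation that
  integrates the depletion dynamics `dN/dt = -aNP/(1+ahN)`, refits the
  random predator equation to rounded counts across durations and
  parameter grids, and checks whether the estimates' SE intervals cover
  the inputs (`run_bias_study()`).
* **Synthetic trials** emulating a fully crossed 2-species × 3 predator
  size × 3 prey size feeding experiment, for testing every stage without
  real data (`generate_trials()`).

## Worked example

Generate deterministic consumption data from the depletion dynamics at
`a = 1`, `h = 0.01` over 1 hr, then fit the random predator equation:

```r
library(rogersfr)
tr <- simulate_consumption(a = 1, h = 0.01, duration = 1)
fit_rogers_mle(tr)
#> <fr_fit: rogers_ii>  n = 18 trials, logLik = -27.051, AIC = 58.101
#>   estimate      se
#> a  0.96281 0.14960
#> h  0.00845 0.00508
```

The rounded counts recover the generating parameters: the attack rate
estimate 0.96 ± 0.15 covers the input 1, and the handling time
0.0085 ± 0.0051 covers 0.01 — prey depletion (54% in this scenario) did
not bias the estimator. Running the full grid shows the same everywhere
it is estimable:

```r
res <- run_bias_study()
subset(res, !(a_overlap & h_overlap))
#>   a_in h_in duration_hr ... depletion
#>      1  0.3         0.2 ...    0.0238
```

The single non-overlap is the short, nearly information-free cell
(0.2-hr trials, strong handling limitation, 2% depletion); one
near-total-depletion cell (`a = 5`, 1.5 hr, 99% depletion) is flagged
non-identified, with `NA` overlap, because the attack rate cannot be
estimated when almost every density is eaten out.

The `analysis/` directory holds the full workflow as numbered scripts —
simulate → classify → fit + bootstrap → scaling → bias study — each a
thin driver over the package functions, writing its tables under
`results/`. `run_pipeline()` runs the same six stages programmatically
and writes a manifest with seeds and output checksums.

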