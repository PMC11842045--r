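# ipdinfer

Valid statistical inference when some — often most — of the outcome values
in an analysis are predictions from an AI/ML system rather than
measurements.

## The problem

Analyses increasingly regress machine-predicted outcomes on features of
interest: a phenotype imputed from health records, a molecular property
predicted from sequence.  Treating predictions as truth (the *naive*
analysis) yields biased estimates with anti-conservative intervals;
restricting to the small labeled subset with measured outcomes (the
*classic* analysis) is valid but wasteful.  Methods for **inference on
predicted data (IPD)** use the labeled subset to correct the
prediction-based analysis, retaining validity while using all rows.

Data are a labeled set $\{(Y_i, f_i, X_i)\}_{i=1}^{n}$ (observed outcome,
prediction, features) and an unlabeled set $\{(f_i, X_i)\}_{i=n+1}^{n+N}$,
drawn from one population.  For an estimand defined by an estimating
function $\psi$ (mean, quantile, linear or logistic regression
coefficients), the package implements:

* **PostPI** (`postpi_analytic`, `postpi_boot`) — fit a *relationship
  model* of $Y$ on $f$ on the labeled rows, then correct on the outcome
  scale: analytically (rescale the naive fit through the relationship
  slope, delta-method variance) or by simulating pseudo-outcomes in a
  bootstrap.
* **PPI** (`ppi`) — solve the *rectified* estimating equation
  $\tfrac1N\sum_U \psi(f_i;\theta) - \big[\tfrac1n\sum_L \psi(f_i;\theta)
  - \tfrac1n\sum_L \psi(Y_i;\theta)\big] = 0$, whose labeled correction
  term removes the prediction bias at every $\theta$.
* **PPI++** (`ppi_plusplus`) — PPI with a scalar power-tuning weight
  $\lambda \in [0,1]$ on the correction, estimated to minimize asymptotic
  variance; $\lambda = 0$ is the classic fit, $\lambda = 1$ is PPI.
* **PSPA** (`pspa`) — per-coordinate weights $\omega$ generalizing
  $\lambda$, each minimizing its own coordinate's asymptotic variance.

All fits report sandwich (HC0) standard errors and normal-approximation
confidence intervals, plus the method's intermediate quantities
(relationship model, $\lambda$, $\omega$).  Oracle / naive / classic
benchmark fits, a synthetic-data generator with a GAM prediction step, and
a replicated benchmark harness support method evaluation end to end.

## Worked example

Simulate a stacked dataset (100 training / 100 labeled / 1000 unlabeled
rows), train the prediction model on the training block, predict
everywhere, and fit PSPA for the linear-regression estimand.  The formula
`Y - f ~ X1 + ...` names the outcome, the prediction, and the features;
`label` names the column holding the train/labeled/unlabeled split:

```r
library(ipdinfer)

dat <- simdat(seed = 1)                  # beta1 = 1, sigma_y = 4
predictor <- train_predictor(dat)        # GAM on the training block
dat <- add_predictions(dat, predictor)   # adds column `f`

fit <- ipd(Y - f ~ X1 + X2 + X3 + X4, method = "pspa", model = "ols",
           data = dat, label = "set_label")
summary(fit)
#> Inference on predicted data
#>
#> Formula:  Y - f ~ X1 + X2 + X3 + X4
#> Method:   pspa
#> Estimand: ols
#> Rows:     100 labeled, 1000 unlabeled
#>
#> Coefficients (95% confidence limits):
#>             Estimate Std. Error   Lower  Upper
#> (Intercept)   0.2450     0.3888 -0.5170 1.0070
#> X1            0.9772     0.3781  0.2361 1.7182
#> X2            0.3786     0.3351 -0.2781 1.0354
#> X3            1.2195     0.3862  0.4625 1.9765
#> X4            0.2448     0.3342 -0.4103 0.8999
```

The `X1` row is the target of inference: the data were generated with a
linear `X1` coefficient of 1, and the corrected estimate 0.98 ± 0.38
covers it, using the labeled outcomes only through the rectifying
correction.  The fitted per-coordinate weights are in the one-row model
summary (`glance`), alongside the sample sizes:

```r
glance(fit)$omega
#> [1] "0.487,0.388,0.515,0.399,0.243"
```

Weights near 0 mean the predictions contribute little for that coordinate
(the fit falls back toward the classic labeled-only estimator); weights
near 1 mean full PPI strength.  `tidy(fit)` returns the coefficient table
as a tibble and `augment(fit)` adds fitted values and labeled-row
residuals to the data; both are ready for `write.csv()`.

Replicated method comparison (the oracle / naive / classic benchmarks plus
every correction, with coverage and interval widths):

```r
bm <- run_benchmark(reps = 500, seed = 1)
bm$summary
```

## Scope

Estimands: mean, single quantile, linear and logistic regression.
Features must be plain numeric columns (no factor expansion or
interactions).  Labeled and unlabeled rows are assumed exchangeable; no
correction here addresses covariate shift.  Each method is implemented
over its published scope only — e.g. `postpi_analytic` is linear-regression
only — and unsupported method × estimand combinations fail fast.  See the
vignette in `vignettes/` for the models, the tuning machinery, numerical
conventions, and known limitations (including the attenuation of the
PostPI point estimate when predictions are weak).
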