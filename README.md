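# whalecomp

Predicting baleen whale density from planktonic community composition.

`whalecomp` is an R package for ecologists who hold two kinds of survey
data from the same cruises — line-transect sightings of whales and eDNA
metabarcoding (ASV) count tables from water samples — and want to ask
whether the planktonic community predicts whale density after seasonality
is accounted for. It implements the full chain as tested, composable
functions:

- **Multiple-covariate distance sampling.** Detection functions (uniform,
  half-normal, hazard-rate keys; cosine/polynomial adjustments; covariates
  on the scale parameter via a log link) fitted by maximum likelihood with
  forward AIC selection and a Cramér–von Mises goodness-of-fit test.
  Density per cruise follows the Horvitz–Thompson-style estimator

  ```
  y_i = 1 / (2 L_i w) * sum_g  s_g / p_hat_g(z_g)
  ```

  (individuals per 1000 km²; `L_i` effort in km, `w` truncation in m,
  `s_g` group size, `p_hat_g` average detectability given covariates),
  with variance combining between-transect encounter-rate and
  detection-function components as `cv² = cv_er² + cv_det²`.

- **Compositional predictors.** Prevalence filtering (1%–99%), geometric
  Bayesian-multiplicative zero imputation, weighted geometric aggregation
  of samples to cruise level, and centered log-ratio scaling into
  typical-abundance ratios `z_ij = x_ij / g_i`.

- **Seasonally adjusted log-contrast regression.** With within-quarter
  geometric means `g(i, ·)` as seasonal references,

  ```
  log(y_i / g(i,y)) = b0 + sum_j b_j log(z_ij / g(i,z_j)) + e_i
  ```

  fitted by SIMPLS partial least squares; a sparse variant (component-wise
  soft thresholding at a fraction `lambda` of the largest loading) drives
  **stability selection**: selection probabilities along a sparsity path
  over leave-one-out folds, a per-family error-rate heuristic to pick the
  admissible `lambda` region, and a stable set of ASVs whose selection
  probability exceeds `pi_max`. Coefficients are reported as multiplicative
  associations `2^(b_j)` per doubling of relative abundance.

- **Validation.** Nested outer leave-one-out re-selection summarized by a
  thresholded Jaccard index, leave-one-out density predictions benchmarked
  against lag and seasonal-mean baselines, and quarter-stratified bootstrap
  percentile intervals.

- **A synthetic-data generator** (`sim_config`, `generate_dataset`) that
  emulates the joint survey — quarterly cruises, transects, two-depth
  station sampling, multinomial read counts with seasonal and spatial
  structure, planted driver ASVs, and detection-process sightings — with
  recorded ground truth for calibration and recovery testing.

See the methods vignette (`vignettes/methods.Rmd`) for the model,
assumptions, parameter defaults and known limitations.

## Worked example

A self-contained run on synthetic data with 5 planted driver ASVs among
500 candidates:

```r
library(whalecomp)

cfg <- pipeline_config(simulate = TRUE,
                       sim = sim_config(seed = 90001, p_asvs = 500,
                                        driver_count = 5))
res <- run_pipeline(cfg)
res
#> Pipeline result
#>   cruises: 25  candidate ASVs: 259
#>   detection: half-normal (AIC 12943.64 )
#>   stable set: 2 ASVs; K = 5
#>   adjusted R2: 0.790 (log) / 0.941 (original)
#>   LOO RMSPE: 0.938 (log) / 24.298 (original); reduction vs lag 22.7%, vs mean 17.9%

paste0("asv", res$truth$drivers)   # planted drivers
#> [1] "asv101" "asv105" "asv249" "asv312" "asv471"
res$stable_set$names               # selected by stability selection
#> [1] "asv101" "asv471"
```

Reading the output: 259 of 500 simulated ASVs survive prevalence
filtering; the detection stage picks a half-normal detection function; the
stable set contains 2 ASVs — both planted drivers — and the model fitted on
them explains 79% of log-scale variance in seasonally adjusted density
(94% on the density scale, where the summer peaks dominate). Out-of-sample
leave-one-out predictions beat the carry-forward baseline by 22.7% and the
seasonal-mean baseline by 17.9% in RMSPE. With the response taken from the
noisy sighting process, the stable set is conservative (it recovers a
subset of drivers and no noise ASVs); driving the model with the true
densities recovers all five.

`res$associations` tabulates each selected ASV's per-doubling association
factor, `res$density` the per-cruise density estimates with CVs, and
`res$predictions` the leave-one-out predictions.

A command-line wrapper lives in `inst/scripts/whalecomp-cli.R`
(`simulate` and `run` subcommands).

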