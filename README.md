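# nbsga — gestational age estimation from newborn screening metabolic profiles

Accurate gestational age (GA) at birth is often unknown in settings without
early dating ultrasound, yet it drives preterm-birth surveillance and
newborn care. Routinely collected dried-blood-spot screening analytes —
amino acids, acylcarnitines, endocrine markers and the hemoglobin fractions —
shift systematically with fetal maturity, so a newborn's metabolic profile
can be inverted into a postnatal GA estimate. `nbsga` implements that whole
analysis as a tested R package: it simulates multi-site screening cohorts
with the statistical structure such data exhibit, applies the standard
metabolomic preparation steps, fits three regression model families, and
validates them internally and externally the way transportability studies of
clinical prediction models are validated.

## The models

For infant *i* with reference GA $y_i$ (decimal weeks), preprocessed
predictors enter one of three families:

* **Model 1 (baseline)** — ordinary least squares on sex, a 5-knot
  restricted cubic spline in birth weight, and their interaction.
* **Model 2** — elastic net on sex and all screening analytes (no birth
  weight), with the top screened analytes splined and pairwise interactions.
* **Model 3 (full)** — elastic net on sex, birth weight and all analytes,
  splines on birth weight and the top analytes, pairwise interactions.

The elastic net minimizes

$$\tfrac{1}{2}\,\mathrm{MSE}(\beta) + \lambda\left[\alpha\lVert\beta\rVert_1
  + \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\right]$$

with $(\alpha, \lambda)$ chosen by validation-set MSE over a grid. Before
modelling, each analyte is winsorized at the Tukey fences
$[Q_1 - 3\,\mathrm{IQR},\ Q_3 + 3\,\mathrm{IQR}]$, log-transformed, and
pareto-scaled ($x \mapsto (x - \bar{x})/\sqrt{s_x}$); the fetal-to-adult
hemoglobin ratio is computed as
$(\mathrm{HbF}+\mathrm{HbF1})/(\mathrm{HbF}+\mathrm{HbF1}+\mathrm{HbA})$.
Analytes are ranked by generalized partial Spearman correlation with GA,
mutually adjusted for the other analytes and clinical covariates; the top
seven (six at sites without hemoglobin measurements) receive splines with
knots at the 5th/27.5th/50th/72.5th/95th percentiles. Accuracy is summarized
by MAE, RMSE and the percentage of infants within ±1 and ±2 weeks, with 95%
bootstrap percentile confidence intervals, overall and in preterm
(< 37 weeks), SGA10 and SGA3 subgroups, plus calibration-in-the-large of the
preterm birth rate.

## Worked example

```r
library(nbsga)

cfg <- pipeline_config(seed = 2, n_internal = 4000, n_external = 1500,
                       bootstrap_replicates = 100, n_lambda = 25)
res <- run_pipeline(cfg)

attr(res$screening, "top_k")
#> [1] "hb_ratio" "C4DC"     "17OHP"    "ALA"      "TYR"      "C5DC"     "C5"

res$internal_reports$model1$subgroups$overall$mae
#> [1] 1.039269

res$internal_reports$model3
#> Validation report: internal_test_model3
#>   overall n=904 MAE=0.500 (0.476, 0.525) RMSE=0.624; within 1wk 89.0%, 2wk 99.9%
#>   preterm n=34 MAE=0.644 (0.500, 0.760)
#>   sga10   n=97 MAE=0.616 (0.539, 0.693)
#>   sga3    n=34 MAE=0.729 (0.610, 0.867)
#>   preterm rate: estimated 3.98% (2.60, 5.15) vs observed 3.76%

res$external_reports$siteC$model3$subgroups$overall$mae
#> [1] 0.6747266
```

Reading the output: screening recovers the hemoglobin ratio as the strongest
GA correlate, followed by the endocrine and acylcarnitine/amino-acid
markers. The baseline sex + birth-weight model estimates GA to about ±7 days
(MAE 1.04 weeks); adding the metabolic profile halves the error (MAE 0.50
weeks, 89% of infants within ±1 week). At the external site lacking
hemoglobin measurements the restricted full model degrades to MAE 0.67
weeks — better than the baseline, but worse than internal validation, the
expected transportability loss.

## The analysis workflow

The `analysis/` scripts run the full study shape over the package, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R   # three-site synthetic cohorts
Rscript analysis/02_preprocess.R         # exclusions, subgroups, scaling
Rscript analysis/03_screen_and_fit.R     # split, screening, Models 1-3
Rscript analysis/04_validate.R           # internal + external reports
```

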