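---
title: "Methods: metabolic gestational age estimation and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic gestational age estimation and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
generative model behind the synthetic cohorts, the preparation and modelling
choices, the numerical conventions, and what the passing test suite does and
does not demonstrate about real newborn screening data.

## The estimation problem

Dried-blood-spot newborn screening measures dozens of analytes whose levels
shift with fetal maturity: the fetal hemoglobin fraction falls steadily after
term, 17-hydroxyprogesterone declines, several acylcarnitines and amino
acids drift with gestational age (GA). Given a cohort with reliable
ultrasound-dated GA, one can regress GA on the metabolic profile and deploy
the fitted equation where dating is unavailable. The scientific questions the
pipeline addresses are (a) how much accuracy analytes add over sex and birth
weight alone, (b) how that accuracy transports to external laboratories with
different panels, assays and collection practices, and (c) how the models
behave in the subgroups that matter most — preterm and growth-restricted
infants, where birth weight is a misleading proxy for maturity.

## The synthetic cohort generator

Real cohorts of this kind sit under data-sharing agreements, so the package
ships a generator that reproduces the *statistical structure* the analysis
relies on, as first-class tested code.

**Gestational age.** GA is a two-component mixture: a term Gaussian
truncated to $[37, \mathrm{ga.max}]$ and an exponential preterm tail
$37 - \mathrm{Exp}(\lambda)$ truncated at `ga_min`, with the preterm mixture
weight equal to `preterm_target_fraction` — the preterm rate is a direct
parameter. The term-component location is solved numerically (truncated
normal moments + `uniroot`) so that the overall mean equals `ga_mean`. The
published cohort moments this emulates (mean 39.3, SD 1.6 weeks, 5.6%
preterm) are jointly incompatible with a single Gaussian — a N(39.3, 1.6)
puts 7.5% of its mass below 37 weeks — which is why the preterm fraction
must be a separate dial. The tail rate default $\lambda = 0.5$/week puts
roughly 93% of preterm infants in the late-preterm band, matching the
severity composition such registries report. The realized overall SD
(~1.7 weeks) is emergent rather than directly set.

**Birth weight** follows a quadratic sex-specific curve
(about 3.4 kg at 40 weeks, ~175 g/week near term, males ~130 g heavier) with
multiplicative (8% log-normal) and additive (150 g) noise. A configurable
fraction (default 10%) of infants is *growth restricted*: their expected
weight is multiplied by 0.75 regardless of GA. This is the subpopulation in
which any birth-weight-based GA model must fail, and it drives the SGA
subgroup analyses.

**Analytes** are log-normal with log-level linear in GA. Six named analytes
(17OHP, C4DC, TYR, ALA, C5, C5DC) carry graded GA slopes; 33 others are
GA-null noise. Hemoglobins are generated as a total level split by a fetal
fraction whose logit declines linearly in GA (−0.18 logit/week, residual SD
0.25), so the derived ratio (HbF+HbF1)/(HbF+HbF1+HbA) is the strongest
single correlate — by design the screening step should find it first.

**Calibration of effect sizes.** The informative slopes are not free-floating:
they are derived once, analytically, so that the Gaussian information
identity
$$\mathrm{Var}(G \mid \text{predictors})^{-1} \approx \mathrm{Var}(G)^{-1}
 + \left(\tfrac{s_{bw}}{\sigma_{bw}}\right)^2
 + \left(\tfrac{s_{hb}}{\sigma_{hb}}\right)^2
 + \sum_j \left(\tfrac{s_j}{\sigma_j}\right)^2$$
yields a conditional SD of GA given all predictors equal to
`target_conditional_sd` (default 0.6 weeks). Under that calibration a
correctly specified estimator has a large-sample MAE floor of
$0.6\sqrt{2/\pi} \approx 0.479$ weeks, which is what the accuracy-recovery
test checks the full model against. The identity is approximate (the GA
prior is a mixture, the hemoglobin ratio enters through a monotone
transform), hence the test's 15% band.

**Collection ages** are log-normal (median ~28 h) with an additive delay
(default 18 h) in the preterm stratum. Combined with the 48-h exclusion rule
this reproduces a real artifact: preterm infants are excluded
disproportionately, so the observed preterm rate in analyzed cohorts sits
below the birth-population rate. Screen-positive records (1.5%) receive
grossly abnormal analyte spikes and exercise the exclusion logic; a further
0.3% receive unflagged spikes that exercise winsorization.

**Site shifts** apply per-analyte multiplicative bias and additive log
shifts, drop unmeasured analytes, delay collection, optionally floor GA to
completed weeks, and rescale dispersion. Dispersion factors above 1 add
independent log-scale noise with SD $s\sqrt{d^2-1}$ (seeded), because the
residual dispersion of an observed value cannot be inflated deterministically
without knowing its GA-conditional mean; factors below 1 shrink values toward
the cohort mean. Published sources do not quantify between-laboratory shifts,
so the default magnitudes (±10% bias, 15–20% dispersion inflation, 6–24 h
delays) are free parameters chosen to be plausible, and are documented as
such.

**What the generator does not emulate:** absolute concentration scales tied
to published reference ranges, assay chemistry, analyte–analyte biological
correlation beyond the shared GA signal, seasonality, or missing-data
mechanisms. Passing tests therefore demonstrate that the *pipeline* recovers
structure it is pointed at, not that real cohorts would yield the published
accuracy.

## Data preparation

The exclusion order is fixed — late collection, then screen-positive, then
missing fields — and each removed record is attributed to the first matching
rule, so the counts partition the removals. Thresholds are 48 h for the
derivation cohort and 72 h for external cohorts.

Winsorization uses Tukey fences with multiplier 3 fitted on the raw scale;
the natural log follows; pareto scaling (subtract mean, divide by
$\sqrt{\mathrm{SD}}$) comes last. Choices the narrative description leaves
open are pinned down as follows:

* **Quantile rule**: linear interpolation of order statistics (type 7),
  used identically for fences, spline knots and SGA centiles.
* **Zeros before the log**: a zero reading is replaced by half the smallest
  positive observed value of that analyte; the offset is stored with the
  fitted parameters.
* **SD convention**: the $n-1$ sample SD.
* **Birth weight** is pareto-scaled without a log (the log transform is
  described for measured analytes; weight is roughly symmetric).
* **Fences before or after the log**: the narrative order
  (winsorize → log → scale) is followed; fences live on the raw scale.
* **Standardization contract**: by default every cohort is standardized
  locally (its own fences and scaling constants), mirroring the local
  standardization used to absorb between-laboratory calibration differences;
  a switch allows reusing derivation-cohort parameters for sensitivity
  analysis. A test asserts that training-scaled parameters applied to a
  shifted cohort leave a detectable nonzero mean — i.e., the contract is
  observable.

SGA10/SGA3/LGA are defined against empirical sex × completed-week
birth-weight centiles computed from a designated reference cohort (default:
the derivation cohort) and applied uniformly everywhere, standing in for
licensed growth-standard tables. Strata with fewer than 10 reference records
yield `unclassifiable` flags rather than silent extrapolation.

## Design and model fitting

The 50/25/25 development/validation/test split is stratified by completed GA
week × sex with largest-remainder allocation, so every stratum matches the
target fractions within one record; strata smaller than 3 fall back to a
global lottery with a warning.

Restricted cubic splines use the standard truncated-power construction: for
knots $t_1 < \dots < t_k$ the basis is $x$ plus $k-2$ nonlinear terms that
are identically zero below $t_1$ and exactly linear above $t_k$, scaled by
$(t_k - t_1)^{-2}$. A test compares the closed form against an independent
implementation that solves the tail-linearity constraints as a linear
system.

"Generalized partial Spearman correlation" is implemented as: rank-transform
GA and every variable, residualize GA and each candidate analyte on all
other variables by least squares on ranks, and correlate the residuals —
computed equivalently (and much faster) through the precision matrix of the
rank correlation matrix. This is an approximation to the cited
rank-correlation metric, adequate for ranking; the equivalence of the two
computations is itself a test. The top seven analytes get splines; when the
hemoglobin ratio is unavailable at a deployment site the restricted models
spline the remaining top six. The screened set is always recomputed, never
hard-coded.

The interaction policy is a deliberate design choice where the phrase
"pairwise interactions among predictors" is ambiguous: pairwise products of
the scalar (pre-spline) standardized predictors, plus sex × every spline
basis column, with spline × spline tensor products excluded to cap the
design at roughly a thousand columns; the elastic net prunes whatever is
uninformative. Both the spline and interaction switches are exposed on the
`model_spec`, but no numeric expectation is attached to the alternatives.

Elastic-net fitting is delegated to `glmnet`, whose objective
$\frac{1}{2n}\mathrm{RSS} + \lambda[\alpha\|\beta\|_1 +
\frac{1-\alpha}{2}\|\beta\|_2^2]$ is exactly the declared
$\frac12\mathrm{MSE} + $ penalty form; solutions are taken at path points, so
no interpolation error enters. Hyperparameters are selected on the internal
validation sub-cohort over $\alpha \in \{0.1, 0.5, 0.9\}$ and a 50-point
log-spaced $\lambda$ path (ties resolved toward the larger penalty); the
published work does not state its tuning procedure, so this grid is the
package's own convention. Model 1 is unpenalized least squares with aliased
columns dropped on rank deficiency. GA estimates are never clipped;
out-of-range estimates are simply reported.

Coefficients are stored against standardized predictors, and prediction
requires a cohort that declares which preprocessing parameters produced it —
making the local-vs-training scaling contract explicit rather than implicit.

## Validation conventions

MAE and RMSE follow their displayed formulas; the ±7-day and ±14-day bands
use closed bounds ($|r| \le 1$ and $|r| \le 2$ weeks) — the boundary
convention is unstated in the source material, and the closed choice is
documented here. For cohorts reporting completed weeks, both arms are
floored (`floor(est) − floor(ref)`) before any metric, and the estimated
preterm flag uses the floored estimate. All confidence intervals are 95%
bootstrap percentile intervals resampling the infant (reference and estimate
together); the preterm-rate CI uses the same engine. Degenerate subgroups
(n = 0) report absent metrics rather than failing.

## Problem sizes and numerical conventions

The test suite and the acceptance script scale the study down to sizes the
package chooses for its own verification: a 44,000-infant derivation cohort
(≈20,000 development / 10,000 test after exclusions) for accuracy recovery;
100 replicates of n = 20,000 cohorts for screening recovery; 200 simulated
cohorts of n = 2,000 with 200 bootstrap replicates for CI coverage
(scaled down from the 1,000 replicates used for reporting); and an
8,000-infant run for preterm-rate calibration, whose check deliberately uses
a cohort of moderate size — see limitations below. Random number streams are
fixed by explicit seeds everywhere; reruns are byte-identical.

Degenerate inputs are handled explicitly: empty cohorts flow through
exclusions and reports; constant vectors produce equal fences and a no-op
winsorization but a named error at scaling; fewer than 3 distinct knots is
an error; tied knots collapse with a warning; collinear adjustment sets in
screening drop dependent columns with a warning.

## Known limitations

* **Calibration-in-the-large is fragile by construction.** An MSE-optimal
  estimator is less dispersed than the truth, so thresholding it at 37 weeks
  undercounts preterm births; conversely, the differential exclusion of
  late-collected preterm samples removes true preterm infants while leaving
  term-side misclassifications in place, inflating the estimated rate
  relative to the observed one. The two effects partially cancel; their
  residual (a few tenths of a percentage point) is a systematic property of
  dichotomized point estimates, not sampling noise, so with very large test
  sets a bootstrap interval around the estimated rate will exclude the
  observed rate even when agreement is practically good.
* The screening statistic is a residualization-based approximation to the
  cited partial rank correlation, not the exact published estimator.
* Synthetic analytes are conditionally independent given GA; real panels
  have correlated assay noise and biological pathways, which would make
  screening harder than it is here.
* External-site shift magnitudes are unquantified in the source material and
  are free parameters of the simulation.
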