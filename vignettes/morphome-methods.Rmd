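---
title: "Quantitative tumor budding morphomics: models and methods"
author: "morphome package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative tumor budding morphomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphome)
```

## The scientific problem

Tumor budding -- the presence of small, detached clusters of carcinoma cells
at the invasion front -- is an adverse prognostic feature in several
gastrointestinal cancers, and is widely read as the histologic face of
(partial) epithelial-mesenchymal transition (EMT). During EMT, E-Cadherin
(ECad) relocates from the cell membrane to the cytoplasm, so the subcellular
ECad pattern of each tumor cell (membranous, mixed, cytoplasmic) is a
per-cell EMT surrogate that can be scored alongside budding itself.

`morphome` implements a quantitative pipeline for this readout. Starting
from a per-cell annotation table (patient, field, cluster membership, ECad
pattern), it:

1. builds a per-patient **cluster census** (cohesive clusters of 1-50 tumor
   cells; anything larger counts as main tumor mass and is excluded with a
   log);
2. derives a 40-column **morphome matrix**: cluster counts in ten 5-cell
   size bins (`buds.5` ... `buds.50`) plus, per bin, the fractions of cells
   with cytoplasmic, mixed and membranous ECad (`cyto.u`, `mix.u`,
   `memb.u`);
3. screens these features for prognostic value by **stability selection**
   over repeated cross-validated lasso Cox regression;
4. fits a Cox model on the stable features, splits its linear predictor at
   the median into a **low/high budding grade**, and
5. reports Kaplan-Meier curves, median survival and the log-rank test per
   grade, plus a stepwise multivariable Cox model against
   clinicopathological covariates.

All survival machinery (Cox partial-likelihood maximization, the penalized
coordinate-descent path, Kaplan-Meier, log-rank, Fisher's exact test) is
implemented in the package itself; the established implementations
(`survival`, `glmnet`, `stats::fisher.test`) serve as independent oracles
in the test suite only.

## Data model

`CellRecord` rows are keyed by (patient, field, cluster, cell); the three
ECad patterns are a closed set -- truly ECad-negative tumor cells do not
occur in this assay, so any other value is rejected at parse time. Clusters
are keyed *within* a field: the same `cluster_id` in two fields denotes two
clusters. The census keeps the inclusive size cutoff at 50 cells
(half-open interval (0, 50]); size-51 clusters land in the exclusion log.

Cohort accounting (`summarizeCensus`) reports pattern totals as exact
integer counts; fractions share the common denominator so they sum to one
up to the final float conversion. The median cluster size is computed per
patient first, and the cohort value is the median of per-patient medians --
the convention for aggregating a per-tumor morphometric readout. Report
percentages round half-up (26/54/21-style presentation).

One naming caveat: features carry the *upper bound* of their size bin, so
`cyto.30` is the cytoplasmic fraction in clusters of 26-30 cells. Published
tables sometimes describe the same feature by the neighbouring bin
(31-35 cells); the package follows the bin-naming convention consistently
and documents the discrepancy here.

### Empty size bins

A patient with no cluster in a bin has count 0 there, and the three pattern
fractions are undefined. They are imputed as 0 (configurable via
`emptyValue`). The zero count is itself a feature the penalized model sees,
so "absence of clusters" is carried by the count column rather than by a
fraction placeholder; imputing all three fractions identically keeps the
matrix complete without inventing a localization signal. All three
collinear fractions (sum = 1 in occupied bins) are retained; the penalized
fit tolerates the collinearity and reporting stays symmetric in the three
patterns.

## Survival core

`coxPH()` maximizes the Cox partial likelihood by Newton-Raphson with
step-halving; ties are handled by the Breslow approximation by default
(matching the convention of the penalized path; Efron is available).
Convergence requires the largest coefficient update or the relative
log-likelihood change to drop below 1e-9; the covariance is the inverse
observed information. A monotone likelihood (|beta| growing past 22, e.g.
complete separation) is flagged `converged = FALSE` with a warning instead
of being reported as a finite estimate. The derivative computations are in
compiled code with the linear predictor centred before exponentiation.

`kaplanMeier()` is the product-limit estimator; subjects censored at a
death time remain at risk for that time. The median is the first time the
curve reaches 0.5 *or less*, and is reported as `NA` ("not reached")
otherwise. `logrankTest()` is the two-group O-E statistic with
hypergeometric variance on one chi-square degree of freedom, two-sided.
`fisherExactTest()` enumerates all 2x2 tables with the observed margins and
sums the probabilities not exceeding the observed one (relative tolerance
1e-7 for floating-point ties); an all-zero margin is degenerate with p = 1.
All testing in the pipeline is two-sided at alpha = 0.05.

## Penalized Cox path and cross-validation

`coxnetPath()` minimizes

    -loglik(beta)/n + lambda * sum_j [ alpha |beta_j| + (1 - alpha) beta_j^2 / 2 ]

by cyclic coordinate descent with soft-thresholding on the iteratively
reweighted quadratic approximation of the Breslow partial likelihood, with
warm starts down a 100-value log-spaced lambda grid
(`lambdaMinRatio = 1e-4`, the convention for the n > p regime).
`lambda_max` -- the smallest penalty with an all-zero solution -- is the
largest absolute component of the per-subject-scaled score at beta = 0 on
the standardized scale, divided by alpha (a 1e-8 relative inflation keeps
the all-zero solution exact against floating-point differences between the
two code paths that evaluate the score). Features are standardized
internally to mean 0 / SD 1 (population SD); zero-variance features keep
coefficient 0; results are reported on the original scale, which makes the
fit scaling-equivariant. The default coordinate-descent tolerance is 1e-5
on the largest coefficient update, comparable to the reference
implementation's default on its scaled criterion; oracle comparisons in the
tests tighten it explicitly.

`cvCoxnet()` tunes lambda by V-fold cross-validated partial-likelihood
deviance, with the fold-k contribution

    -2 * ( loglik_full(beta_-k) - loglik_-k(beta_-k) )

(the cross-validated partial-likelihood construction, which remains defined
when a single held-out fold has too few events of its own). Folds come from
a seeded shuffle into groups within one subject of each other; a shuffle
leaving a fold with no events is redrawn (up to 10 attempts). `lambdaOpt`
is the deviance minimum -- the "optimal" tuning value; the 1-SE value is
computed as an option but is deliberately not the default, since the
dichotomized grade downstream benefits from the better-predicting model
rather than the sparsest one.

With `alpha = 1` (the default) the elastic net is the lasso, which is the
configuration the pipeline mirrors.

## Stability selection

`stabilitySelect()` repeats the CV-tuned lasso `R = 10` times. The key
interpretive choice: a "repetition" reshuffles the cross-validation folds
only -- the data are fixed, and the penalty is retuned at each repetition's
deviance minimum, independently per repetition. (Bootstrap resampling of
patients is available behind `bootstrap = TRUE` but is not the default
reading of repeated cross-validation.) A feature is *selected* when its
coefficient is nonzero at `lambdaOpt` in strictly more than
`threshold = 0.8` of repetitions; with ten repetitions that means at least
9/10. Each repetition runs under a recorded seed derived deterministically
from the master seed, so a report is a pure function of (data, seed).

Because repetitions share the data, per-feature frequencies concentrate
near 0 or 1: the procedure asks which features survive *retuning under fold
perturbation*, not sampling noise. That makes the strict 0.8 cut a sharp
stability filter rather than a frequency estimate. It also bounds what the
filter can reject: a spurious association that is strong *in this dataset*
is stably spurious, so on outcome-permuted data a feature occasionally
passes the threshold anyway (about one permuted cohort in five at the
default study scale). Only repetition-level resampling of patients
(`bootstrap = TRUE`) would convert the frequency into a sampling-noise
estimate; it is provided but is not the default reading of repeated
cross-validation.

## Budding grade and multivariable reporting

`fitSelectedCox()` refits the unpenalized Cox model on exactly the selected
features -- the per-feature hazard-ratio table of the pipeline report.
`assignBuddingGrade()` ranks patients by the linear predictor, breaking
ties by patient id (deterministic and auditable), and labels the first
`ceiling(n/2)` as low grade -- two equally sized groups, with the extra
patient on the low side for odd n (a 171-patient cohort splits 86/85).
Because only ranks matter, any strictly monotone transform of the predictor
yields identical grades.

`stepwiseCox()` performs bidirectional stepwise selection starting from the
empty model with AIC as the default criterion; both choices are stated
because "stepwise selection" alone under-determines them, and both are
configurable (`start = "full"`, `criterion = "pvalue"` with 0.05/0.10
entry/removal). Multi-level factors (tumor location, histologic subtype)
enter and leave as whole dummy blocks against their reference levels (PDAC,
pancreatobiliary). Covariates such as age and sex can be forced in via
`forceIn`, covering report tables that keep baseline adjustments regardless
of selection. Candidate moves that hit a monotone likelihood are skipped
with a warning. The budding grade is always offered as a candidate
covariate, and subgroup reruns (e.g. the PDAC-only model) reuse the grades
fitted on the full cohort, preserving the order of operations.

## The synthetic cohort generator

No patient-level data accompany the study this pipeline operationalizes, so
the generator is the package's test bed: it must produce inputs with the
statistical structure the analysis assumes, at the cohort scale the
published tables describe (171 patients, ~50% deaths, follow-up 1-116
months).

* **Cluster counts.** Patient p draws clusters of size s as
  Poisson(G_p c / s): the inverse count ~ 1/size law in expectation
  (E G_p = 1), with a gamma frailty G_p (shape 1.5) spreading the cluster
  budget across patients. The frailty is essential for realism: published
  cohort tables show clusters-per-patient ranges like 3-283 around a median
  of 42, a ~70-fold spread no pure Poisson model can produce. The scale
  c = 12 puts the median near 42 clusters per patient. Pure Poisson
  sampling is recovered with `clusterDispersion = Inf`.
* **ECad localization.** Each cell's pattern comes from a multinomial logit
  in cluster size (mixed as reference) plus per-patient normal offsets
  (`patternSd = 1`) on the cytoplasmic and membranous logits -- a
  patient-level EMT propensity. Coefficients were fixed once against the
  published cohort-level targets: overall pattern fractions near 26% / 54%
  / 21% (membranous / mixed / cytoplasmic), cytoplasmic fractions near 0.2
  in 11-15-cell clusters and 0.1 in 26-30-cell clusters, and the
  directional trends (cytoplasmic falling, membranous rising with size).
* **Survival.** Event times are exponential with rate
  `baselineHazard * exp(x beta)` computed on the *realized* morphome
  features; censoring is uniform over 1-116 months. The planted defaults
  put log-hazards on `buds.10` (+0.08 per cluster), `buds.35` (-0.35),
  `cyto.15` (+2.5) and `cyto.30` (+1.8) -- the logs of the published
  selected-feature hazard ratios -- and `baselineHazard = 0.0075`/month was
  calibrated once so that about half the cohort dies, matching the
  published event fraction.
* **Clinical covariates.** Independent categorical draws with the published
  cohort-table marginals (64% PDAC, 66% pT3, 67% N+, and so on), age from a
  truncated normal (median 67, range 30-89). Covariates are independent of
  the morphome by default, reflecting the reported absence of an
  association between cluster morphology and staging variables; a
  dependence knob is out of scope.

### What the generator does not emulate

* The per-patient *median cluster size* distribution. Published tables
  report per-patient medians of 2-36 cells (overall 16); any generator
  whose expected counts follow c/s for every patient concentrates
  per-patient medians near 5. Matching both the 1/size count law and the
  median-size spread would require per-patient size-law exponents, which
  would break the clean inverse-law mean structure the rest of the
  pipeline is tested against. We kept the law and accept the median-size
  mismatch.
* Spatial structure (hotspots, field geometry) and inter-field variation:
  one synthetic field per patient.
* Correlation between morphome features and clinical covariates.

Consequently, passing recovery tests demonstrate that the *pipeline*
recovers planted effects under realistic marginal structure and
overdispersion; they do not certify behaviour under confounding between
morphology and staging, nor under size-composition heterogeneity beyond
the shared-budget frailty.

A practical consequence of the frailty/offset realism is worth stating
plainly: all ten bud-count features share the patient budget G_p, and all
cytoplasmic fractions share the patient offset, so "null" features are
marginally correlated with planted ones. Stability selection then
sometimes stabilizes correlated proxies alongside the planted features --
as it would on real data. Idealized expectations (all four planted
features plus at most two stable false positives, simultaneously, in most
cohorts) sit at the edge of what these study conditions support; the
acceptance suite measures and reports the achieved rates rather than
tuning the generator to flatter ones.

## Numerical choices and problem sizes

* Newton-Raphson tolerance 1e-9, divergence guard |beta| > 22; coordinate
  descent tolerance 1e-5 (tightened in oracle tests), outer iteration cap
  100 per lambda with a |beta| > 50 separation guard.
* Seed derivation uses a Lehmer-style integer mix (`deriveSeed`), keeping
  all derived seeds below 2^31 and recorded in reports.
* Ties at the grade median break by patient id; ties in survival times are
  Breslow-handled by default everywhere for internal consistency.
* Test and acceptance problem sizes are deliberate package choices: oracle
  fixtures use 8-120 subjects; recovery experiments use 200-patient cohorts
  with 50 master seeds (stability) and the 171-patient cohort scale for the
  grade-direction experiment; interval-coverage checks use 500 replicates
  at n = 150.

## Known limitations

* The stepwise move log records AIC only; small-sample corrected criteria
  (AICc) are not implemented.
* The penalized path supports dense matrices only, adequate for 40-column
  morphome designs.
* `cvCoxnet` reports partial-likelihood deviance only; concordance-based
  tuning is intentionally out of scope.
* The grade split assumes a single cohort-wide median; stratified or
  site-specific splits are not provided.
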