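# morphome

Quantitative analysis of tumor budding and E-Cadherin (ECad) shifting in
adenocarcinoma cohorts — a "morphome" pipeline from per-cell annotations to
a prognostic budding grade.

Tumor budding (small detached clusters of carcinoma cells at the invasion
front) and the relocation of E-Cadherin from membrane to cytoplasm are
histologic faces of epithelial–mesenchymal transition and adverse
prognostic features. This package quantifies both jointly: every tumor cell
in an annotated field carries its cluster membership and one of three ECad
patterns (membranous / mixed / cytoplasmic), and the pipeline turns those
annotations into survival-relevant morphometry.

## The model at its core

Per patient, clusters of 1–50 cohesive cells are tallied into ten 5-cell
size bins, giving 40 features: counts `buds.u` and per-bin pattern
fractions `cyto.u`, `mix.u`, `memb.u` (u = bin upper bound). Prognostic
features are found by **stability selection**: the lasso-penalized Cox
model

&nbsp;&nbsp;&nbsp;&nbsp; minimize −ℓ(β)/n + λ Σⱼ [α|βⱼ| + (1−α)βⱼ²/2],  α = 1

is tuned by tenfold cross-validated partial-likelihood deviance, the
procedure is repeated ten times with reshuffled folds, and features with a
nonzero coefficient at the tuned λ in **more than 80%** of repetitions are
kept. An unpenalized Cox fit on the stable features yields a linear
predictor η = xᵀβ̂; its median split defines the **low/high budding
grade**, assessed by Kaplan–Meier curves, the log-rank test, and a stepwise
multivariable Cox model against clinicopathological covariates.

Cox regression (Newton–Raphson on the Breslow/Efron partial likelihood),
the coordinate-descent penalty path, Kaplan–Meier, log-rank and Fisher's
exact test are implemented in the package (compiled core via Rcpp);
`survival` and `glmnet` appear only as independent oracles in the tests.
A synthetic-cohort generator (`simulateCohort`) emulates the inverse
cluster-count/size law with patient-level overdispersion, size-dependent
ECad localization, cohort-table clinical marginals, and censored survival
with planted feature effects — so the whole pipeline is testable without
patient data.

## Worked example

```r
library(morphome)

cfg <- simulationConfig()            # 171-patient cohort-scale defaults
coh <- simulateCohort(cfg, seed = 2026)

res <- runMorphomePipeline(coh$cells, coh$clinical, seed = 7,
  stepwiseCovariates = c("age", "sex", "pT", "pN", "M", "grade",
                         "lymphovascular", "vascular", "perineural",
                         "location", "histology"))

res$stability
#> StabilityReport: 10 repetitions, threshold > 0.80, seed 7
#>   selected: cyto.5, cyto.15, cyto.25, cyto.40, cyto.50
#>   frequencies > 0:
#>     cyto.5     1.00
#>     cyto.15    1.00
#>     ...

res$report$table
#>   grade  n events median_os
#> 1   low 86     23        NA
#> 2  high 85     50   30.2501
res$report$logrank
#> log-rank chi2 = 19.43, p = 1e-05
res$stepwise$retained
#> [1] "budding_grade" "perineural" "pN"
```

Reading the output: the stability report selected five cytoplasmic-ECad
fractions (including the planted `cyto.15`); the 171 patients split 86/85
into budding grades; the low grade never reaches median survival while the
high grade's median is 30 months, and the log-rank test separates the
grades at p = 1e-05. The stepwise multivariable model keeps the budding
grade as an independent prognostic factor next to nodal stage and
perineural invasion — the qualitative behaviour the pipeline is built to
detect. (The generator plants effects on `buds.10`, `buds.35`, `cyto.15`,
`cyto.30`; correlated features can stabilize alongside them, see the
methods vignette.)

Key entry points: `readCells`/`buildClusterCensus`/`summarizeCensus`,
`buildMorphomeMatrix` (returns a `MorphomeExperiment`, a
SummarizedExperiment of features × patients), `coxPH`, `kaplanMeier`,
`logrankTest`, `fisherExactTest`, `coxnetPath`/`cvCoxnet`,
`stabilitySelect`, `assignBuddingGrade`, `stepwiseCox`,
`gradeSurvivalReport`, and the `simulate*` family. The methods vignette
(`vignettes/morphome-methods.Rmd`) documents the models, numerical choices
and generator calibration.

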