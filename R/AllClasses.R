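ECAD_PATTERNS <- c("membranous", "mixed", "cytoplasmic")

CENSUS_COLUMNS <- c("patient_id", "field_id", "cluster_id", "size",
                    "n_membranous", "n_mixed", "n_cytoplasmic")

#' ClusterCensus: per-patient tumor cell cluster census
#'
#' One row per cohesive tumor cell cluster, holding its size (cell count) and
#' the number of member cells with membranous, mixed and cytoplasmic
#' E-Cadherin localization. Clusters larger than `maxSize` cells (the main
#' tumor mass boundary; 50 by default) are kept apart in the `excluded` slot
#' rather than silently dropped.
#'
#' @slot clusters data.frame of included clusters (columns `patient_id`,
#'   `field_id`, `cluster_id`, `size`, `n_membranous`, `n_mixed`,
#'   `n_cytoplasmic`), ordered by (patient_id, cluster_id).
#' @slot excluded data.frame of over-size clusters, same columns.
#' @slot maxSize largest cell count for a cluster to stay in the census.
#' @aliases ClusterCensus
#' @export
setClass("ClusterCensus",
  representation(clusters = "data.frame", excluded = "data.frame",
                 maxSize = "numeric"))

setValidity("ClusterCensus", function(object) {
  cl <- object@clusters
  if (!all(CENSUS_COLUMNS %in% names(cl)))
    return("clusters must have the census columns")
  if (nrow(cl)) {
    if (any(cl$size < 1)) return("cluster sizes must be >= 1")
    if (any(cl$size > object@maxSize))
      return("included clusters exceed maxSize")
    tot <- cl$n_membranous + cl$n_mixed + cl$n_cytoplasmic
    if (any(tot != cl$size))
      return("pattern counts must sum to cluster size")
  }
  TRUE
})

#' CensusSummary: cohort-level cluster census summary
#'
#' Cohort totals and per-patient medians derived from a [ClusterCensus]:
#' total assessed cells, cells per E-Cadherin pattern (counts and fractions),
#' clusters per patient, and the median cluster size computed per patient
#' with the overall value taken as the median of the per-patient medians.
#'
#' @slot totalCells total number of cells in included clusters.
#' @slot patternTotals named integer vector of cells per pattern.
#' @slot patternFractions pattern totals divided by the cell total.
#' @slot clustersPerPatient named integer vector.
#' @slot medianClusterSizePerPatient named numeric vector.
#' @slot overallMedianClusterSize median of the per-patient medians.
#' @aliases CensusSummary
#' @export
setClass("CensusSummary",
  representation(totalCells = "integer", patternTotals = "numeric",
                 patternFractions = "numeric", clustersPerPatient = "numeric",
                 medianClusterSizePerPatient = "numeric",
                 overallMedianClusterSize = "numeric"))

setValidity("CensusSummary", function(object) {
  if (sum(object@patternTotals) != object@totalCells)
    return("pattern totals must sum to the cell total")
  if (abs(sum(object@patternFractions) - 1) > 1e-12)
    return("pattern fractions must sum to 1")
  TRUE
})

#' MorphomeExperiment: per-patient morphome feature container
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single `"morphome"`
#' assay holds the 40 morphome features (rows) by patients (columns): ten
#' cluster-size-bin counts `buds.5` ... `buds.50`, then the per-bin fractions
#' of cells with cytoplasmic (`cyto.*`), mixed (`mix.*`) and membranous
#' (`memb.*`) E-Cadherin localization. Feature names carry the upper bound of
#' the 5-cell size bin, so `cyto.30` is the cytoplasmic fraction in clusters
#' of 26-30 cells (note that some published tables label the same quantity by
#' the next bin). Clinical covariates and the survival outcome
#' (`time_months`, `event`) live in `colData`.
#'
#' @aliases MorphomeExperiment
#' @export
setClass("MorphomeExperiment", contains = "SummarizedExperiment")

setValidity("MorphomeExperiment", function(object) {
  if (!"morphome" %in% SummarizedExperiment::assayNames(object))
    return("assay 'morphome' is required")
  if (!identical(rownames(object), morphomeFeatureNames()))
    return("rows must be the 40 canonical morphome features, in order")
  a <- SummarizedExperiment::assay(object, "morphome")
  fr <- a[grep("^(cyto|mix|memb)\\.", rownames(a)), , drop = FALSE]
  if (length(fr) && (min(fr) < -1e-12 || max(fr) > 1 + 1e-12))
    return("pattern-fraction features must lie in [0, 1]")
  TRUE
})

#' CoxPHFit: Cox proportional hazards fit
#'
#' Result of maximizing the (Breslow or Efron) partial likelihood by
#' Newton-Raphson. Hazard ratios and their Wald 95% intervals are on the
#' `exp(beta)` scale.
#'
#' @slot coefficients named log hazard ratios.
#' @slot covariance inverse observed information.
#' @slot hazardRatios `exp(coefficients)`.
#' @slot ci95 two-column matrix of Wald interval bounds for the hazard ratios.
#' @slot waldP two-sided Wald p-values.
#' @slot logLik partial log-likelihood at the estimate.
#' @slot nullLogLik partial log-likelihood at beta = 0.
#' @slot ties `"breslow"` or `"efron"`.
#' @slot converged FALSE when the likelihood is monotone (diverging beta).
#' @slot iterations Newton-Raphson iterations used.
#' @slot n,nEvents subjects and observed deaths.
#' @aliases CoxPHFit
#' @export
setClass("CoxPHFit",
  representation(coefficients = "numeric", covariance = "matrix",
                 hazardRatios = "numeric", ci95 = "matrix", waldP = "numeric",
                 logLik = "numeric", nullLogLik = "numeric", ties = "character",
                 converged = "logical", iterations = "integer",
                 n = "integer", nEvents = "integer"))

#' KMEstimate: Kaplan-Meier product-limit estimate
#'
#' @slot table risk table with one row per distinct follow-up time: columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @slot medianSurvival first time at which survival drops to 0.5 or below;
#'   `NA` when never reached.
#' @slot n,nEvents subjects and observed deaths.
#' @aliases KMEstimate
#' @export
setClass("KMEstimate",
  representation(table = "data.frame", medianSurvival = "numeric",
                 n = "integer", nEvents = "integer"))

setValidity("KMEstimate", function(object) {
  s <- object@table$survival
  if (length(s) && (any(diff(s) > 1e-12) || s[1] > 1 + 1e-12))
    return("survival must be non-increasing and start at or below 1")
  TRUE
})

#' CoxnetPath: lasso / elastic-net penalized Cox solution path
#'
#' Coefficients along a decreasing lambda sequence for the penalized Breslow
#' partial likelihood, fitted by cyclic coordinate descent on internally
#' standardized features and reported on the original feature scale.
#'
#' @slot alpha elastic-net mixing parameter (1 = lasso).
#' @slot lambda decreasing penalty sequence; the first value is lambda_max,
#'   the smallest penalty with an all-zero solution.
#' @slot beta feature-by-lambda coefficient matrix (original scale).
#' @slot center,scale per-feature standardization constants.
#' @slot df number of nonzero coefficients per lambda.
#' @slot converged logical per lambda.
#' @aliases CoxnetPath
#' @export
setClass("CoxnetPath",
  representation(alpha = "numeric", lambda = "numeric", beta = "matrix",
                 center = "numeric", scale = "numeric", df = "integer",
                 converged = "logical"))

setValidity("CoxnetPath", function(object) {
  if (is.unsorted(rev(object@lambda), strictly = TRUE))
    return("lambda must be strictly decreasing")
  TRUE
})

#' CoxnetCV: cross-validated penalized Cox fit
#'
#' V-fold cross-validation of a [CoxnetPath] by the cross-validated
#' partial-likelihood deviance (the deviance contribution of fold k is
#' `-2 * (loglik_full(beta_-k) - loglik_-k(beta_-k))`).
#'
#' @slot foldAssignment integer fold label per subject.
#' @slot lambda penalty sequence shared with the full-data path.
#' @slot meanDeviance,seDeviance per-lambda mean and standard error across folds.
#' @slot lambdaOpt deviance-minimizing lambda.
#' @slot lambda1se largest lambda within one SE of the minimum.
#' @slot path full-data [CoxnetPath].
#' @slot seed seed used for the fold shuffle.
#' @aliases CoxnetCV
#' @export
setClass("CoxnetCV",
  representation(foldAssignment = "integer", lambda = "numeric",
                 meanDeviance = "numeric", seDeviance = "numeric",
                 lambdaOpt = "numeric", lambda1se = "numeric",
                 path = "CoxnetPath", seed = "integer"))

#' StabilityReport: repeated-CV lasso Cox selection frequencies
#'
#' For each of `nRepeats` repetitions the cross-validation folds are
#' reshuffled, the penalty is retuned at that repetition's deviance minimum,
#' and the nonzero coefficient set is recorded. A feature is selected when
#' its frequency is strictly greater than `threshold` (with the default 10
#' repetitions and threshold 0.8 this requires at least 9/10).
#'
#' @slot nRepeats number of repetitions.
#' @slot threshold selection frequency cut (strict inequality).
#' @slot frequency named selection frequency per feature.
#' @slot selected features with frequency strictly above the threshold, in
#'   feature order.
#' @slot perRepeat data.frame with one row per repetition: derived seed,
#'   tuned lambda, and the comma-separated nonzero feature set.
#' @slot seed master seed.
#' @aliases StabilityReport
#' @export
setClass("StabilityReport",
  representation(nRepeats = "integer", threshold = "numeric",
                 frequency = "numeric", selected = "character",
                 perRepeat = "data.frame", seed = "integer"))

setValidity("StabilityReport", function(object) {
  want <- names(object@frequency)[object@frequency > object@threshold]
  if (!identical(object@selected, want))
    return("selected set must be exactly {frequency > threshold}")
  TRUE
})
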