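# Budding grade construction and multivariable survival reporting.

#' Cox model on the stability-selected morphome features
#'
#' Fits [coxPH()] on exactly the selected feature columns; this is the
#' multivariable model whose hazard ratios are reported per selected feature
#' and whose linear predictor defines the budding grade.
#'
#' @param x feature matrix (subjects x features) or [MorphomeExperiment] with
#'   attached survival.
#' @param selected character vector of selected feature names, or a
#'   [StabilityReport].
#' @param time,event survival outcome (taken from `colData` for a
#'   MorphomeExperiment).
#' @param ... passed to [coxPH()].
#' @return a [CoxPHFit].
#' @export
fitSelectedCox <- function(x, selected, time = NULL, event = NULL, ...) {
  if (is(selected, "StabilityReport")) selected <- selectedFeatures(selected)
  if (!length(selected))
    stop("no features selected; review the stability-selection threshold",
         call. = FALSE)
  if (is(x, "MorphomeExperiment")) {
    y <- survivalOutcome(x)
    time <- y$time; event <- y$event
    x <- morphomeMatrix(x)
  }
  miss <- setdiff(selected, colnames(x))
  if (length(miss))
    stop("selected feature(s) not in the matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  coxPH(x[, selected, drop = FALSE], time, event, ...)
}

#' Linear predictor of a Cox fit
#'
#' @param fit a [CoxPHFit].
#' @param x feature matrix or [MorphomeExperiment]; columns matching the fit
#'   coefficients are used.
#' @return named vector `eta = x %*% beta` per subject.
#' @export
linearPredictor <- function(fit, x) {
  stopifnot(is(fit, "CoxPHFit"))
  if (is(x, "MorphomeExperiment")) x <- morphomeMatrix(x)
  drop(x[, names(coef(fit)), drop = FALSE] %*% coef(fit))
}

#' Dichotomize linear predictors into a low/high budding grade
#'
#' Patients are ranked by their linear predictor (ascending), ties broken by
#' patient id in lexicographic order; the first `ceiling(n/2)` patients form
#' the low-grade group and the rest the high-grade group, so the groups are
#' equally sized with the extra patient (odd n) in the low grade. The
#' assignment depends only on ranks, so any strictly monotone transform of
#' the predictor yields the same grades.
#'
#' @param eta named numeric vector of linear predictors (names = patient
#'   ids; defaults to the element index when unnamed).
#' @return data.frame (in input order) with `patient_id`,
#'   `linear_predictor`, and `grade` (factor low/high).
#' @examples
#' assignBuddingGrade(c(P1 = 0.2, P2 = -1, P3 = 0.5))
#' @export
assignBuddingGrade <- function(eta) {
  if (length(eta) < 2) stop("need at least 2 patients", call. = FALSE)
  ids <- names(eta)
  if (is.null(ids)) ids <- as.character(seq_along(eta))
  o <- order(eta, ids)
  n_low <- ceiling(length(eta) / 2)
  grade <- character(length(eta))
  grade[o] <- rep(c("low", "high"), c(n_low, length(eta) - n_low))
  data.frame(patient_id = ids, linear_predictor = unname(eta),
             grade = factor(grade, levels = c("low", "high")))
}

# -- stepwise multivariable Cox ----------------------------------------------

expand_term <- function(data, term) {
  v <- data[[term]]
  if (is.character(v)) v <- factor(v)
  if (is.factor(v)) {
    m <- stats::model.matrix(~v)[, -1, drop = FALSE]
    colnames(m) <- paste0(term, sub("^v", ":", colnames(m)))
  } else {
    m <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, term))
  }
  m
}

step_fit <- function(blocks, terms, time, event, ties) {
  if (!length(terms)) {
    n <- length(time)
    ll <- cox_loglik(matrix(0, n, 1), 0, time, event)
    return(list(fit = NULL, k = 0L, loglik = ll, aic = -2 * ll))
  }
  Xc <- do.call(cbind, blocks[terms])
  fit <- tryCatch(suppressWarnings(coxPH(Xc, time, event, ties = ties)),
                  error = function(e) NULL)
  if (is.null(fit) || !fit@converged) return(NULL)
  list(fit = fit, k = ncol(Xc), loglik = fit@logLik,
       aic = -2 * fit@logLik + 2 * ncol(Xc))
}

#' Stepwise multivariable Cox model over clinicopathological covariates
#'
#' Bidirectional stepwise selection of a Cox proportional hazards model.
#' Multi-level factors enter and leave as blocks of dummy columns coded
#' against their first (reference) level. Starting from the empty (default)
#' or full model, the single add or drop move that most improves the
#' criterion is taken at each step until no move improves; candidate moves
#' whose fit fails or hits a monotone likelihood are skipped with a warning.
#' The default criterion is AIC; a p-value rule (likelihood-ratio entry at
#' `alphaEnter`, removal at `alphaRemove`) is available.
#'
#' @param data data.frame of covariates; factors are dummy-coded against
#'   their first level (set reference levels via factor level order).
#' @param time,event survival outcome.
#' @param candidates names of `data` columns eligible for selection.
#' @param forceIn columns kept in the model at every step (e.g. age and sex
#'   as forced baseline adjustments).
#' @param start `"empty"` (default) or `"full"`.
#' @param criterion `"aic"` (default) or `"pvalue"`.
#' @param alphaEnter,alphaRemove p-value thresholds for the `"pvalue"` rule.
#' @param ties passed to [coxPH()].
#' @return list with `fit` (final [CoxPHFit], or NULL for the empty model),
#'   `retained` (selected columns, including `forceIn`), and `trace` (move
#'   log with the criterion value after each step).
#' @export
stepwiseCox <- function(data, time, event, candidates = names(data),
                        forceIn = character(), start = c("empty", "full"),
                        criterion = c("aic", "pvalue"),
                        alphaEnter = 0.05, alphaRemove = 0.10,
                        ties = "breslow") {
  start <- match.arg(start)
  criterion <- match.arg(criterion)
  y <- check_survival(time, event, nrow(data))
  stopifnot(all(candidates %in% names(data)), all(forceIn %in% names(data)))
  candidates <- setdiff(candidates, forceIn)
  blocks <- lapply(setNames(nm = c(forceIn, candidates)),
                   function(tm) expand_term(data, tm))
  current <- if (start == "empty") forceIn else c(forceIn, candidates)
  cur <- step_fit(blocks, current, y$time, y$event, ties)
  if (is.null(cur))
    stop("the starting model is not estimable", call. = FALSE)
  trace <- data.frame(step = 0L, action = "start",
                      term = paste(current, collapse = "+"), aic = cur$aic)
  for (step in seq_len(50)) {
    moves <- rbind(
      if (length(setdiff(candidates, current)))
        data.frame(action = "add", term = setdiff(candidates, current)),
      if (length(setdiff(current, forceIn)))
        data.frame(action = "drop", term = setdiff(current, forceIn)))
    if (is.null(moves) || !nrow(moves)) break
    best <- NULL
    for (i in seq_len(nrow(moves))) {
      terms <- if (moves$action[i] == "add") c(current, moves$term[i])
               else setdiff(current, moves$term[i])
      f <- step_fit(blocks, terms, y$time, y$event, ties)
      if (is.null(f)) {
        warning("skipping non-estimable move: ", moves$action[i], " ",
                moves$term[i], call. = FALSE)
        next
      }
      if (criterion == "pvalue") {
        # LRT of the moved block against the smaller of the two models
        small <- if (moves$action[i] == "add") cur else f
        big <- if (moves$action[i] == "add") f else cur
        lrt <- 2 * (big$loglik - small$loglik)
        pv <- pchisq(lrt, df = max(1, big$k - small$k), lower.tail = FALSE)
        ok <- if (moves$action[i] == "add") pv < alphaEnter
              else pv > alphaRemove
        score <- if (moves$action[i] == "add") pv else -pv
        if (ok && (is.null(best) || score < best$score))
          best <- list(terms = terms, fit = f, score = score,
                       action = moves$action[i], term = moves$term[i])
      } else {
        if (f$aic < cur$aic - 1e-8 && (is.null(best) || f$aic < best$fit$aic))
          best <- list(terms = terms, fit = f, score = f$aic,
                       action = moves$action[i], term = moves$term[i])
      }
    }
    if (is.null(best)) break
    current <- best$terms
    cur <- best$fit
    trace <- rbind(trace, data.frame(step = step, action = best$action,
                                     term = best$term, aic = cur$aic))
  }
  list(fit = cur$fit, retained = current, trace = trace, aic = cur$aic)
}

#' Survival report by budding grade
#'
#' Per-grade Kaplan-Meier estimates with median overall survival and the
#' two-group log-rank test -- the survival-analysis summary table for a
#' low/high budding grading.
#'
#' @param grade factor (or character) with levels low/high, one per subject.
#' @param time,event survival outcome.
#' @return list with `table` (grade, n, events, median_os), `logrank`
#'   (chi2, p), and `km` (per-grade [KMEstimate]s).
#' @export
gradeSurvivalReport <- function(grade, time, event) {
  grade <- factor(as.character(grade), levels = c("low", "high"))
  y <- check_survival(time, event, length(grade))
  if (any(!table(grade) > 0) || anyNA(grade))
    stop("both budding grades must be present", call. = FALSE)
  km <- lapply(split(seq_along(grade), grade), function(i)
    kaplanMeier(y$time[i], y$event[i]))
  lr <- logrankTest(y$time[grade == "low"], y$event[grade == "low"],
                    y$time[grade == "high"], y$event[grade == "high"])
  tab <- data.frame(
    grade = c("low", "high"),
    n = as.integer(table(grade)),
    events = vapply(km, function(k) as.integer(k@nEvents), integer(1)),
    median_os = vapply(km, medianSurvival, numeric(1)))
  rownames(tab) <- NULL
  list(table = tab, logrank = lr[c("chi2", "p")], km = km)
}

#' Run the full morphome grading pipeline
#'
#' Census to report in one call: builds the cluster census from per-cell
#' annotations, derives the morphome matrix, stability-selects prognostic
#' features with repeated CV lasso Cox, fits the selected-feature Cox model,
#' dichotomizes its linear predictor into the budding grade, and summarizes
#' per-grade survival. Optionally a stepwise multivariable Cox over
#' clinicopathological covariates (with the budding grade always offered as
#' a candidate) is run on the whole cohort and, if requested, on a subgroup
#' -- using the grades fitted on the full cohort.
#'
#' @param cells per-cell annotation data.frame (see [readCells()]).
#' @param clinical clinical table with `patient_id`, `time_months`, `event`
#'   and any covariates.
#' @param seed master seed for stability selection.
#' @param R,V,alpha,threshold stability-selection settings (field-standard
#'   defaults: 10 repetitions of tenfold CV lasso, strict 0.8 cut).
#' @param maxSize census cluster-size cutoff.
#' @param stepwiseCovariates optional covariate column names for the final
#'   stepwise model (budding grade is added automatically).
#' @param forceIn covariates forced into the stepwise model.
#' @param subgroup optional named length-1 list/vector, e.g.
#'   `c(location = "PDAC")`: rerun the stepwise model within that subset,
#'   keeping the full-cohort grades.
#' @return list with `census`, `experiment`, `stability`, `fit`, `grades`,
#'   `report`, and (when requested) `stepwise` / `stepwiseSubgroup`.
#' @export
runMorphomePipeline <- function(cells, clinical, seed, R = 10, V = 10,
                                alpha = 1, threshold = 0.8, maxSize = 50,
                                stepwiseCovariates = NULL,
                                forceIn = character(), subgroup = NULL) {
  census <- buildClusterCensus(cells, maxSize = maxSize)
  me <- buildMorphomeMatrix(census, patients = clinical$patient_id)
  me <- attachClinical(me, clinical)
  stab <- stabilitySelect(me, R = R, V = V, alpha = alpha,
                          threshold = threshold, seed = seed)
  fit <- fitSelectedCox(me, stab)
  eta <- linearPredictor(fit, me)
  grades <- assignBuddingGrade(eta)
  y <- survivalOutcome(me)
  report <- gradeSurvivalReport(grades$grade, y$time, y$event)
  out <- list(census = census, experiment = me, stability = stab, fit = fit,
              grades = grades, report = report)
  if (!is.null(stepwiseCovariates)) {
    dat <- as.data.frame(colData(me))[stepwiseCovariates]
    dat$budding_grade <- grades$grade
    out$stepwise <- stepwiseCox(dat, y$time, y$event,
                                candidates = names(dat), forceIn = forceIn)
    if (!is.null(subgroup)) {
      var <- names(subgroup)[1]
      keep <- as.character(colData(me)[[var]]) == subgroup[[1]]
      out$stepwiseSubgroup <- stepwiseCox(dat[keep, , drop = FALSE],
                                          y$time[keep], y$event[keep],
                                          candidates = names(dat),
                                          forceIn = forceIn)
    }
  }
  out
}
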