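# Self-contained survival and categorical statistics: Cox proportional
# hazards by Newton-Raphson on the partial likelihood, the Kaplan-Meier
# product-limit estimator, the two-group log-rank test, and Fisher's exact
# test by hypergeometric enumeration.

sort_survival <- function(X, time, event) {
  o <- order(time)
  list(X = X[o, , drop = FALSE], time = time[o], event = event[o], order = o)
}

#' Cox proportional hazards regression
#'
#' Maximizes the Cox partial likelihood (Breslow or Efron tie handling) by
#' Newton-Raphson with step-halving. Convergence is declared when the largest
#' coefficient update or the relative log-likelihood change falls below
#' `tol`; the covariance is the inverse observed information. A monotone
#' partial likelihood (a coefficient diverging past `|beta| > 22`, e.g.
#' complete separation of events) is flagged `converged = FALSE` with a
#' warning rather than reported as a finite estimate.
#'
#' @param X numeric design matrix (subjects x covariates), no missing values,
#'   no constant columns.
#' @param time follow-up time (months), positive.
#' @param event 0/1 (or logical) death indicator; at least 2 events.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param tol convergence tolerance (default 1e-9).
#' @param maxIter Newton-Raphson iteration cap.
#' @return a [CoxPHFit].
#' @examples
#' set.seed(1)
#' x <- rnorm(60)
#' t <- rexp(60, exp(0.7 * x))
#' fit <- coxPH(x, t, rep(1, 60))
#' hazardRatios(fit)
#' @export
coxPH <- function(X, time, event, ties = c("breslow", "efron"),
                  tol = 1e-9, maxIter = 50) {
  ties <- match.arg(ties)
  X <- as_design_matrix(X)
  y <- check_survival(time, event, nrow(X))
  if (sum(y$event) < 2) stop("need at least 2 events", call. = FALSE)
  const <- apply(X, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    stop("constant column(s): ", paste(colnames(X)[const], collapse = ", "),
         call. = FALSE)
  s <- sort_survival(X, y$time, y$event)
  p <- ncol(X)
  beta <- numeric(p)
  efron <- ties == "efron"
  d0 <- cox_pl_cpp(s$X, beta, s$time, s$event, efron, TRUE)
  nullLL <- d0$loglik
  ll <- nullLL; g <- d0$grad; H <- d0$hess
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(maxIter)) {
    iter <- it
    step <- tryCatch(drop(solve(-H, g)), error = function(e)
      stop("singular information matrix", call. = FALSE))
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      dc <- cox_pl_cpp(s$X, cand, s$time, s$event, efron, TRUE)
      if (dc$loglik >= ll - 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    delta <- max(abs(cand - beta))
    relchange <- abs(dc$loglik - ll) / (abs(ll) + 1e-12)
    beta <- cand; ll <- dc$loglik; g <- dc$grad; H <- dc$hess
    if (max(abs(beta)) > 22) {
      warning("monotone partial likelihood: coefficient diverging, ",
              "fit flagged as non-converged", call. = FALSE)
      break
    }
    if (delta < tol || relchange < tol) { converged <- TRUE; break }
  }
  cov <- tryCatch(solve(-H), error = function(e)
    stop("singular information matrix", call. = FALSE))
  cov <- (cov + t(cov)) / 2
  se <- sqrt(pmax(diag(cov), 0))
  z <- beta / se
  names(beta) <- colnames(X)
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  rownames(ci) <- colnames(X)
  new("CoxPHFit", coefficients = beta, covariance = cov,
      hazardRatios = setNames(exp(beta), colnames(X)), ci95 = ci,
      waldP = setNames(2 * pnorm(-abs(z)), colnames(X)),
      logLik = ll, nullLogLik = nullLL, ties = ties, converged = converged,
      iterations = iter, n = nrow(X), nEvents = sum(y$event))
}

#' @rdname CoxPHFit-class
#' @export
setMethod("hazardRatios", "CoxPHFit", function(x, ...) x@hazardRatios)

#' @rdname CoxPHFit-class
#' @export
setMethod("coef", "CoxPHFit", function(object, ...) object@coefficients)

#' @rdname CoxPHFit-class
#' @param object a [CoxPHFit].
#' @return `summary()`: data.frame with one row per covariate (coefficient,
#'   hazard ratio, Wald 95% CI, p), the layout of a multivariable survival
#'   report table.
#' @export
setMethod("summary", "CoxPHFit", function(object, ...) {
  data.frame(coef = object@coefficients, hr = object@hazardRatios,
             lower95 = object@ci95[, "lower"], upper95 = object@ci95[, "upper"],
             p = object@waldP)
})

setMethod("show", "CoxPHFit", function(object) {
  cat(sprintf("CoxPHFit (%s ties): n = %d, events = %d, loglik = %.3f%s\n",
              object@ties, object@n, object@nEvents, object@logLik,
              if (object@converged) "" else " [NOT CONVERGED]"))
  s <- summary(object)
  s$`HR (95% CI)` <- sprintf("%.3f (%.3f-%.3f)", s$hr, s$lower95, s$upper95)
  print(s[, c("HR (95% CI)", "p")], digits = 3)
})

# Score (Rao) test of beta = 0; with one binary covariate and no ties this
# equals the two-group log-rank chi-square.
cox_score_test <- function(X, time, event, ties = "breslow") {
  X <- as_design_matrix(X)
  y <- check_survival(time, event, nrow(X))
  s <- sort_survival(X, y$time, y$event)
  d <- cox_pl_cpp(s$X, numeric(ncol(X)), s$time, s$event, ties == "efron", TRUE)
  stat <- drop(crossprod(d$grad, solve(-d$hess, d$grad)))
  list(chi2 = stat, df = ncol(X), p = pchisq(stat, ncol(X), lower.tail = FALSE))
}

#' Kaplan-Meier product-limit estimator
#'
#' Right-censored survival curve. Subjects censored at a death time stay in
#' the risk set for that time (censoring is ordered after events at equal
#' times). The median is the first time at which the curve reaches 0.5 or
#' less, and `NA` ("not reached") when survival never drops that far.
#'
#' @param time positive follow-up times.
#' @param event 0/1 death indicator.
#' @return a [KMEstimate].
#' @export
kaplanMeier <- function(time, event) {
  y <- check_survival(time, event)
  if (!length(y$time)) stop("empty survival sample", call. = FALSE)
  ut <- sort(unique(y$time))
  nrisk <- vapply(ut, function(t) sum(y$time >= t), numeric(1))
  nev <- vapply(ut, function(t) sum(y$time == t & y$event == 1), numeric(1))
  ncs <- vapply(ut, function(t) sum(y$time == t & y$event == 0), numeric(1))
  surv <- cumprod(1 - nev / nrisk)
  tab <- data.frame(time = ut, n_risk = nrisk, n_event = nev,
                    n_censor = ncs, survival = surv)
  med <- if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1]] else NA_real_
  new("KMEstimate", table = tab, medianSurvival = med,
      n = length(y$time), nEvents = sum(y$event))
}

#' @rdname KMEstimate-class
#' @export
setMethod("medianSurvival", "KMEstimate", function(x, ...) x@medianSurvival)

setMethod("show", "KMEstimate", function(object) {
  cat(sprintf("KMEstimate: n = %d, events = %d, median survival = %s\n",
              object@n, object@nEvents,
              if (is.na(object@medianSurvival)) "not reached"
              else format(object@medianSurvival)))
})

#' Risk table of a Kaplan-Meier estimate
#'
#' @param km a [KMEstimate].
#' @param path optional path; when given, the table (time, n_risk, n_event,
#'   survival) is also written tab-separated for replotting.
#' @return the risk table data.frame.
#' @export
riskTable <- function(km, path = NULL) {
  stopifnot(is(km, "KMEstimate"))
  tab <- km@table[, c("time", "n_risk", "n_event", "survival")]
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric variance,
#' referred to a chi-square distribution with one degree of freedom
#' (two-sided).
#'
#' @param time1,event1 survival outcome of group 1.
#' @param time2,event2 survival outcome of group 2.
#' @return list with `chi2`, `p`, and per-group `observed` / `expected`
#'   event counts.
#' @export
logrankTest <- function(time1, event1, time2, event2) {
  y1 <- check_survival(time1, event1)
  y2 <- check_survival(time2, event2)
  if (!length(y1$time) || !length(y2$time))
    stop("both groups must be non-empty", call. = FALSE)
  time <- c(y1$time, y2$time)
  event <- c(y1$event, y2$event)
  grp <- rep(1:2, c(length(y1$time), length(y2$time)))
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  ut <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O1 - E1)^2 / V else 0
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE),
       observed = c(O1, sum(event) - O1),
       expected = c(E1, sum(event) - E1))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value obtained by enumerating, with margins fixed, all tables
#' whose hypergeometric probability does not exceed that of the observed
#' table (up to a 1e-7 relative tolerance for floating-point ties).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value; a table with an all-zero margin is
#'   degenerate and returns 1.
#' @export
fisherExactTest <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
    stop("need a 2x2 table of non-negative integers", call. = FALSE)
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m == 0 || n == 0 || k == 0 || sum(tab[, 2]) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
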