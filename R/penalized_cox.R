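# Lasso / elastic-net penalized Cox regression along a lambda path with
# V-fold cross-validated partial-likelihood deviance.

cox_loglik <- function(X, beta, time, event) {
  s <- sort_survival(as_design_matrix(X), time, event)
  cox_pl_cpp(s$X, beta, s$time, s$event, FALSE, FALSE)$loglik
}

#' Penalized Cox regression path
#'
#' Coefficients of the elastic-net penalized Cox model (Breslow ties) along a
#' decreasing lambda sequence, minimizing
#' `-loglik(beta)/n + lambda * sum_j [alpha |beta_j| + (1 - alpha) beta_j^2 / 2]`
#' by cyclic coordinate descent with soft-thresholding on the quadratic
#' approximation, warm-started down the path. Features are standardized
#' internally (mean 0, SD 1; zero-variance features are fixed at coefficient
#' 0) and coefficients are reported on the original scale. `lambda_max`, the
#' first value of the sequence, is the smallest penalty with an all-zero
#' solution: the largest absolute per-subject-scaled score component at
#' beta = 0 on the standardized scale, divided by `alpha`.
#'
#' @param X numeric feature matrix (subjects x features).
#' @param time,event right-censored survival outcome (months, 0/1).
#' @param alpha elastic-net mixing in (0, 1]; 1 (the default) is the lasso.
#' @param nLambda number of log-spaced penalty values (default 100).
#' @param lambdaMinRatio smallest lambda as a fraction of lambda_max.
#' @param lambda optional explicit decreasing sequence, overriding the grid.
#' @param tol coordinate-descent convergence tolerance.
#' @param maxit outer iteration cap per lambda; non-convergence is flagged
#'   with a warning.
#' @return a [CoxnetPath].
#' @export
coxnetPath <- function(X, time, event, alpha = 1, nLambda = 100,
                       lambdaMinRatio = 1e-4, lambda = NULL,
                       tol = 1e-5, maxit = 100) {
  X <- as_design_matrix(X)
  y <- check_survival(time, event, nrow(X))
  if (sum(y$event) < 2) stop("need at least 2 events", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  live <- scl > 0
  Xs <- sweep(X, 2, ctr)
  Xs[, live] <- sweep(Xs[, live, drop = FALSE], 2, scl[live], "/")
  Xs[, !live] <- 0
  s <- sort_survival(Xs, y$time, y$event)
  if (is.null(lambda)) {
    g0 <- cox_pl_cpp(s$X, numeric(p), s$time, s$event, FALSE, TRUE)$grad
    lmax <- max(abs(g0)) / n / alpha
    # tiny inflation keeps the all-zero solution exact under floating-point
    # differences between the score and the descent path
    lambda <- exp(seq(log(lmax * (1 + 1e-8)), log(lmax * lambdaMinRatio),
                      length.out = nLambda))
  } else {
    if (is.unsorted(rev(lambda), strictly = TRUE))
      stop("lambda must be strictly decreasing", call. = FALSE)
  }
  fit <- coxnet_path_cpp(s$X, s$time, s$event, lambda, alpha, tol, maxit)
  bs <- fit$beta
  b <- matrix(0, p, length(lambda),
              dimnames = list(colnames(X), signif(lambda, 6)))
  b[live, ] <- bs[live, , drop = FALSE] / scl[live]
  conv <- as.logical(fit$converged)
  if (!all(conv))
    warning(sum(!conv), " lambda value(s) did not converge in ", maxit,
            " iterations", call. = FALSE)
  new("CoxnetPath", alpha = alpha, lambda = as.numeric(lambda), beta = b,
      center = ctr, scale = scl, df = as.integer(colSums(b != 0)),
      converged = conv)
}

#' @rdname CoxnetPath-class
#' @param object a [CoxnetPath].
#' @param s penalty value; the nearest lambda on the path is used.
#' @param ... unused.
#' @return `coef()`: named coefficient vector at `s` (original scale).
#' @export
setMethod("coef", "CoxnetPath", function(object, s, ...) {
  object@beta[, which.min(abs(object@lambda - s))]
})

setMethod("show", "CoxnetPath", function(object) {
  cat(sprintf("CoxnetPath: alpha = %g, %d features, %d lambda values (%.4g .. %.4g)\n",
              object@alpha, nrow(object@beta), length(object@lambda),
              object@lambda[1], object@lambda[length(object@lambda)]))
  cat("  df range:", paste(range(object@df), collapse = "-"), "\n")
})

#' Export a penalty path in long format
#'
#' @param path a [CoxnetPath].
#' @param file output path for a tab-separated (lambda, feature, coefficient)
#'   table.
#' @export
writeCoxnetPath <- function(path, file) {
  stopifnot(is(path, "CoxnetPath"))
  long <- data.frame(
    lambda = rep(path@lambda, each = nrow(path@beta)),
    feature = rep(rownames(path@beta), length(path@lambda)),
    coefficient = as.vector(path@beta))
  write.table(long, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

make_cv_folds <- function(n, V, event, seed) {
  for (attempt in 0:9) {
    fold <- with_seed(deriveSeed(seed, attempt),
                      rep(seq_len(V), length.out = n)[sample.int(n)])
    ev_per_fold <- vapply(seq_len(V), function(k) sum(event[fold == k]),
                          numeric(1))
    if (all(ev_per_fold >= 1) && all(sum(event) - ev_per_fold >= 2))
      return(fold)
  }
  stop("could not build ", V, " folds each containing an event in 10 attempts",
       call. = FALSE)
}

#' Cross-validated penalized Cox regression
#'
#' Tunes the penalty of [coxnetPath()] by V-fold cross-validated
#' partial-likelihood deviance: for fold k the contribution at each lambda is
#' `-2 * (loglik_full(beta_-k) - loglik_-k(beta_-k))`, where `beta_-k` is the
#' path fitted without fold k (van Houwelingen's construction, which stays
#' defined when a held-out fold alone has too few events). `lambdaOpt`
#' minimizes the mean deviance across folds; the 1-SE value is also reported.
#' Folds are drawn by a seeded shuffle into groups of size within one of each
#' other; a shuffle leaving any fold without an event is redrawn (at most 10
#' attempts).
#'
#' @inheritParams coxnetPath
#' @param V number of folds (default 10).
#' @param seed integer seed for the fold shuffle (required, for auditable
#'   repeats).
#' @return a [CoxnetCV].
#' @export
cvCoxnet <- function(X, time, event, V = 10, alpha = 1, seed,
                     nLambda = 100, lambdaMinRatio = 1e-4,
                     tol = 1e-5, maxit = 100) {
  X <- as_design_matrix(X)
  y <- check_survival(time, event, nrow(X))
  n <- nrow(X)
  if (V < 2 || n < V) stop("need 2 <= V <= n", call. = FALSE)
  full <- coxnetPath(X, y$time, y$event, alpha = alpha, nLambda = nLambda,
                     lambdaMinRatio = lambdaMinRatio, tol = tol, maxit = maxit)
  lambda <- full@lambda
  fold <- make_cv_folds(n, V, y$event, seed)
  dev <- matrix(NA_real_, V, length(lambda))
  s_all <- sort_survival(X, y$time, y$event)
  for (k in seq_len(V)) {
    tr <- fold != k
    pk <- coxnetPath(X[tr, , drop = FALSE], y$time[tr], y$event[tr],
                     alpha = alpha, lambda = lambda, tol = tol, maxit = maxit)
    s_tr <- sort_survival(X[tr, , drop = FALSE], y$time[tr], y$event[tr])
    ll_all <- cox_loglik_path_cpp(s_all$X, s_all$time, s_all$event, pk@beta)
    ll_tr <- cox_loglik_path_cpp(s_tr$X, s_tr$time, s_tr$event, pk@beta)
    dev[k, ] <- -2 * (ll_all - ll_tr)
  }
  mean_dev <- colMeans(dev)
  se_dev <- apply(dev, 2, sd) / sqrt(V)
  iopt <- which.min(mean_dev)
  within1se <- mean_dev <= mean_dev[iopt] + se_dev[iopt]
  new("CoxnetCV", foldAssignment = as.integer(fold), lambda = lambda,
      meanDeviance = mean_dev, seDeviance = se_dev,
      lambdaOpt = lambda[iopt], lambda1se = lambda[which(within1se)[1]],
      path = full, seed = as.integer(seed))
}

#' @rdname CoxnetCV-class
#' @export
setMethod("lambdaOpt", "CoxnetCV", function(x, ...) x@lambdaOpt)

#' @rdname CoxnetCV-class
#' @param object a [CoxnetCV].
#' @param s `"lambda.opt"` (default), `"lambda.1se"`, or a numeric penalty.
#' @param ... unused.
#' @return `coef()`: coefficients of the full-data path at `s`.
#' @export
setMethod("coef", "CoxnetCV", function(object, s = "lambda.opt", ...) {
  lam <- if (identical(s, "lambda.opt")) object@lambdaOpt
         else if (identical(s, "lambda.1se")) object@lambda1se
         else as.numeric(s)
  coef(object@path, s = lam)
})

setMethod("show", "CoxnetCV", function(object) {
  cat(sprintf("CoxnetCV: %d folds, lambdaOpt = %.5g (df = %d), lambda1se = %.5g\n",
              max(object@foldAssignment), object@lambdaOpt,
              sum(coef(object) != 0), object@lambda1se))
})
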