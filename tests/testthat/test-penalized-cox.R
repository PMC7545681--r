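test_that("penalty path hits the unpenalized fit at small lambda and zero at lambda_max", {
  fx <- random_surv_fixture(60, 3, c(0.8, -0.6, 0), seed = 8)
  path <- coxnetPath(fx$X, fx$time, fx$event, lambdaMinRatio = 1e-6,
                     tol = 1e-10, maxit = 500)
  expect_true(all(path@beta[, 1] == 0))
  unpen <- coxPH(fx$X, fx$time, fx$event)
  expect_equal(unname(path@beta[, ncol(path@beta)]), unname(coef(unpen)),
               tolerance = 1e-4)
  # sparsity grows with the penalty (on average along the path)
  half <- length(path@lambda) %/% 2
  expect_lte(mean(path@df[seq_len(half)]), mean(path@df[-seq_len(half)]))
})

test_that("mid-path solutions match a generic optimizer of the penalized objective", {
  # 12-subject, 3-feature fixture
  set.seed(42)
  X <- matrix(rnorm(36), 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  time <- c(2, 4, 5, 7, 8, 10, 12, 13, 15, 17, 19, 21)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1, 0, 1, 1, 1)
  path <- coxnetPath(X, time, event, nLambda = 40, tol = 1e-12, maxit = 2000)
  std <- standardize_cols(X)
  o <- order(time)
  Xs <- std$Xs[o, , drop = FALSE]; tt <- time[o]; ee <- event[o]
  for (l in c(10, 20, 30)) {
    lam <- path@lambda[l]
    b_std <- path@beta[, l] * std$scale     # back to the standardized scale
    obj <- function(b) coxnet_objective(b, Xs, tt, ee, lam)
    # generic optimizer: Nelder-Mead restarted from several points
    best <- Inf
    for (start in list(rep(0, 3), b_std + 0.3, b_std - 0.3)) {
      op <- optim(start, obj, control = list(maxit = 5000, reltol = 1e-14))
      op <- optim(op$par, obj, control = list(maxit = 5000, reltol = 1e-14))
      best <- min(best, op$value)
    }
    expect_equal(obj(b_std), best, tolerance = 1e-5)
    # coordinate-wise optimality at the returned solution
    for (j in 1:3) for (eps in c(-1e-4, 1e-4)) {
      bp <- b_std; bp[j] <- bp[j] + eps
      expect_gte(obj(bp), obj(b_std) - 1e-10)
    }
  }
})

test_that("one-feature lasso equals direct minimization with soft-threshold shrinkage", {
  fx <- random_surv_fixture(40, 1, 1, seed = 19)
  path <- coxnetPath(fx$X, fx$time, fx$event, nLambda = 20, tol = 1e-12,
                     maxit = 2000)
  std <- standardize_cols(fx$X)
  o <- order(fx$time)
  Xs <- std$Xs[o, , drop = FALSE]
  for (l in c(5, 10, 15)) {
    lam <- path@lambda[l]
    f <- function(b) coxnet_objective(b, Xs, fx$time[o], fx$event[o], lam)
    oracle <- optimize(f, c(-3, 3), tol = 1e-12)$minimum
    expect_equal(unname(path@beta[1, l] * std$scale), oracle, tolerance = 1e-5)
    # the solution is strictly shrunk towards zero relative to lambda -> 0
    expect_lte(abs(path@beta[1, l]), abs(path@beta[1, 20]) + 1e-10)
  }
})

test_that("warm starts descend the penalized objective along the path", {
  fx <- random_surv_fixture(50, 5, c(1, -0.5, 0, 0, 0), seed = 77)
  path <- coxnetPath(fx$X, fx$time, fx$event, nLambda = 30)
  std <- standardize_cols(fx$X)
  o <- order(fx$time)
  Xs <- std$Xs[o, ]; tt <- fx$time[o]; ee <- fx$event[o]
  for (l in 2:30) {
    lam <- path@lambda[l]
    b_now <- path@beta[, l] * std$scale
    b_prev <- path@beta[, l - 1] * std$scale
    expect_lte(coxnet_objective(b_now, Xs, tt, ee, lam),
               coxnet_objective(b_prev, Xs, tt, ee, lam) + 1e-10)
  }
})

test_that("coefficients are scaling-equivariant at a fixed lambda sequence", {
  fx <- random_surv_fixture(70, 3, c(0.7, -0.4, 0.2), seed = 55)
  p1 <- coxnetPath(fx$X, fx$time, fx$event, tol = 1e-10, maxit = 500)
  X2 <- fx$X; X2[, 2] <- X2[, 2] * 10
  p2 <- coxnetPath(X2, fx$time, fx$event, lambda = p1@lambda, tol = 1e-10,
                   maxit = 500)
  expect_equal(p2@beta[2, ], p1@beta[2, ] / 10, tolerance = 1e-6)
  expect_equal(p2@beta[c(1, 3), ], p1@beta[c(1, 3), ], tolerance = 1e-6)
})

test_that("path coefficients track the reference elastic-net implementation", {
  skip_if_not_installed("glmnet")
  skip_if_not_installed("survival")
  fx <- random_surv_fixture(120, 8, c(0.9, -0.7, 0.4, rep(0, 5)), seed = 101)
  path <- coxnetPath(fx$X, fx$time, fx$event, tol = 1e-9, maxit = 500)
  ref <- glmnet::glmnet(fx$X, survival::Surv(fx$time, fx$event),
                        family = "cox", lambda = path@lambda, thresh = 1e-12)
  expect_equal(path@lambda[1], max(ref$lambda), tolerance = 1e-6)
  for (l in c(25, 50, 75, 100))
    expect_equal(unname(path@beta[, l]), as.numeric(coef(ref)[, l]),
                 tolerance = 2e-3)
})

test_that("cross-validation is seed-deterministic with balanced, event-bearing folds", {
  fx <- random_surv_fixture(83, 6, c(1, rep(0, 5)), seed = 4)
  cv1 <- cvCoxnet(fx$X, fx$time, fx$event, seed = 12)
  cv2 <- cvCoxnet(fx$X, fx$time, fx$event, seed = 12)
  expect_identical(cv1@foldAssignment, cv2@foldAssignment)
  expect_identical(lambdaOpt(cv1), lambdaOpt(cv2))
  expect_identical(cv1@meanDeviance, cv2@meanDeviance)
  sizes <- table(cv1@foldAssignment)
  expect_lte(diff(range(sizes)), 1)
  ev <- tapply(fx$event, cv1@foldAssignment, sum)
  expect_true(all(ev >= 1))
  expect_true(lambdaOpt(cv1) %in% cv1@lambda)
  expect_gte(cv1@lambda1se, lambdaOpt(cv1))
})

test_that("cross-validated tuning recovers a planted strong feature", {
  hits <- 0L
  for (s in 1:40) {
    fx <- random_surv_fixture(200, 10, c(1.5, rep(0, 9)), seed = 4000 + s,
                              cmax = 30)
    cv <- suppressWarnings(cvCoxnet(fx$X, fx$time, fx$event, seed = s))
    if (coef(cv)["f1"] != 0) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.9)
})

test_that("pure-noise outcomes tune to a larger penalty than planted signal", {
  diffs <- vapply(1:8, function(s) {
    sig <- random_surv_fixture(200, 10, c(1.5, rep(0, 9)), seed = 6000 + s,
                               cmax = 30)
    nul <- random_surv_fixture(200, 10, rep(0, 10), seed = 6000 + s, cmax = 30)
    cvs <- suppressWarnings(cvCoxnet(sig$X, sig$time, sig$event, seed = s))
    cvn <- suppressWarnings(cvCoxnet(nul$X, nul$time, nul$event, seed = s))
    # compare on the relative penalty scale (lambda / lambda_max)
    log(lambdaOpt(cvn) / cvn@lambda[1]) - log(lambdaOpt(cvs) / cvs@lambda[1])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("degenerate cross-validation inputs are rejected", {
  fx <- random_surv_fixture(30, 2, c(0.5, 0), seed = 3)
  expect_error(cvCoxnet(fx$X, fx$time, fx$event, V = 1, seed = 1), "V")
  expect_error(coxnetPath(fx$X, fx$time, rep(0, 30)), "2 events")
  expect_error(coxnetPath(fx$X, fx$time, fx$event, alpha = 0), "alpha")
})
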