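test_that("Cox fit is zero under group-exchange symmetry and matches a 1-D oracle", {
  # two groups with identical event-time patterns: relabeling swaps the
  # covariate, so the estimate must be its own negation
  time <- c(2, 4, 6, 8, 2, 4, 6, 8)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  x <- rep(c(0, 1), each = 4)
  fit <- coxPH(x, time, event)
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-8)

  # fixed 8-subject fixture against grid + golden-section maximization of
  # the explicitly coded partial likelihood
  time2 <- c(3, 5, 7, 9, 11, 13, 15, 17)
  event2 <- c(1, 1, 1, 0, 1, 1, 0, 1)
  x2 <- c(0.5, -1.2, 0.3, 2.1, -0.7, 1.4, 0.2, -1.9)
  fit2 <- coxPH(x2, time2, event2)
  oracle <- golden_cox_1d(x2, time2, event2)
  expect_equal(unname(coef(fit2)), oracle, tolerance = 1e-6)
  # stationarity of the explicit log-likelihood at the estimate
  eps <- 1e-5
  gnum <- (breslow_loglik(coef(fit2) + eps, cbind(x2), time2, event2) -
           breslow_loglik(coef(fit2) - eps, cbind(x2), time2, event2)) / (2 * eps)
  expect_lt(abs(gnum), 1e-5)
})

test_that("Cox fit agrees with the survival package for both tie methods", {
  skip_if_not_installed("survival")
  fx <- random_surv_fixture(90, 4, c(0.6, -0.5, 0, 0.3), seed = 14)
  ref <- survival::coxph(survival::Surv(fx$time, fx$event) ~ fx$X,
                         ties = "breslow")
  fit <- coxPH(fx$X, fx$time, fx$event)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit@covariance), unname(ref$var), tolerance = 1e-6)

  # heavy ties, Efron approximation
  t3 <- ceiling(fx$time)
  refE <- survival::coxph(survival::Surv(t3, fx$event) ~ fx$X, ties = "efron")
  fitE <- coxPH(fx$X, t3, fx$event, ties = "efron")
  expect_equal(unname(coef(fitE)), unname(coef(refE)), tolerance = 1e-7)
  # hazard ratio intervals bracket the point estimate
  expect_true(all(fitE@ci95[, "lower"] <= fitE@hazardRatios &
                  fitE@hazardRatios <= fitE@ci95[, "upper"]))
})

test_that("Cox fit flags monotone likelihoods and rejects bad designs", {
  # perfectly separating covariate: all early deaths in one group
  time <- c(1, 2, 3, 4, 10, 11, 12, 13)
  event <- c(1, 1, 1, 1, 0, 0, 0, 0)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_warning(fit <- coxPH(x, time, event), "monotone")
  expect_false(fit@converged)

  expect_error(coxPH(rep(1, 8), time, event), "constant")
  expect_error(coxPH(rnorm(4), c(1, 2, 3, 4), c(1, 0, 0, 0)), "2 events")
})

test_that("Kaplan-Meier matches hand-computed product limits", {
  km <- kaplanMeier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km@table$survival, c(2 / 3, 2 / 3, 0))
  expect_equal(medianSurvival(km), 3)

  none <- kaplanMeier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(none@table$survival == 1))
  expect_true(is.na(medianSurvival(none)))

  onetime <- kaplanMeier(rep(5, 4), rep(1, 4))
  expect_equal(onetime@table$survival, 0)
  expect_equal(medianSurvival(onetime), 5)

  # censoring at a death time keeps the censored subject at risk there
  km2 <- kaplanMeier(c(2, 2, 5), c(1, 0, 1))
  expect_equal(km2@table$survival[km2@table$time == 2], 2 / 3)
})

test_that("Kaplan-Meier equals one minus the empirical CDF without censoring", {
  set.seed(9)
  for (rep in 1:3) {
    tt <- sample(1:40, 25, replace = TRUE)
    km <- kaplanMeier(tt, rep(1, 25))
    ecdf_surv <- 1 - ecdf(tt)(km@table$time)
    expect_equal(km@table$survival, ecdf_surv)
  }
})

test_that("log-rank test matches hand summation and is label-symmetric", {
  expect_error(logrankTest(numeric(0), integer(0), 1, 1), "non-empty")
  same <- logrankTest(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  # 6 vs 6 fixture, O-E/V summed by hand over the event times
  t1 <- c(1, 3, 5, 7, 9, 11); e1 <- c(1, 1, 0, 1, 0, 1)
  t2 <- c(2, 4, 6, 8, 10, 12); e2 <- c(1, 0, 1, 1, 1, 0)
  lr <- logrankTest(t1, e1, t2, e2)
  time <- c(t1, t2); event <- c(e1, e2); grp <- rep(1:2, each = 6)
  O1 <- E1 <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t); n1 <- sum(time >= t & grp == 1)
    d <- sum(time == t & event == 1)
    O1 <- O1 + sum(time == t & event == 1 & grp == 1)
    E1 <- E1 + d * n1 / n
    V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$chi2, (O1 - E1)^2 / V)
  expect_equal(lr$observed[1], O1)

  # swap invariance
  lr_sw <- logrankTest(t2, e2, t1, e1)
  expect_equal(lr_sw$chi2, lr$chi2)
  expect_equal(lr_sw$p, lr$p)

  # far-shifted second group: clearly significant
  sh <- logrankTest(1:6, rep(1, 6), 101:106, rep(1, 6))
  expect_lt(sh$p, 0.01)
})

test_that("log-rank agrees with survdiff and with the Cox score test", {
  skip_if_not_installed("survival")
  fx <- random_surv_fixture(80, 1, 0.8, seed = 31)
  grp <- as.integer(fx$X[, 1] > 0)
  lr <- logrankTest(fx$time[grp == 0], fx$event[grp == 0],
                    fx$time[grp == 1], fx$event[grp == 1])
  sd <- survival::survdiff(survival::Surv(fx$time, fx$event) ~ grp)
  expect_equal(lr$chi2, sd$chisq, tolerance = 1e-9)

  # classical equivalence: score test at beta = 0 with a binary covariate
  # equals the log-rank statistic on tie-free data
  sc <- morphome:::cox_score_test(grp, fx$time, fx$event)
  expect_equal(sc$chi2, lr$chi2, tolerance = 1e-6)
})

test_that("Fisher's exact test matches enumeration and handles degeneracy", {
  expect_equal(fisherExactTest(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisherExactTest(matrix(c(0, 3, 0, 4), 2)), 1)

  tab <- matrix(c(1, 11, 9, 3), 2)
  # exhaustive enumeration over tables with the observed margins
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  p_obs <- dhyper(tab[1, 1], m, n2, k)
  p_enum <- sum(vapply(max(0, k - n2):min(k, m), function(a) {
    pa <- dhyper(a, m, n2, k)
    if (pa <= p_obs * (1 + 1e-7)) pa else 0
  }, numeric(1)))
  expect_equal(fisherExactTest(tab), p_enum)
  expect_equal(fisherExactTest(tab), fisher.test(tab)$p.value, tolerance = 1e-12)

  set.seed(2)
  for (rep in 1:20) {
    tb <- matrix(rpois(4, 6), 2)
    expect_equal(fisherExactTest(tb), fisher.test(tb)$p.value,
                 tolerance = 1e-10)
  }
  expect_error(fisherExactTest(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Wald intervals achieve nominal coverage on simulated cohorts", {
  beta_true <- 0.5
  cover <- 0L
  nrep <- 500
  set.seed(123)
  for (r in seq_len(nrep)) {
    x <- rnorm(150)
    tt <- rexp(150, 0.1 * exp(beta_true * x))
    cens <- runif(150, 0, 25)
    fit <- coxPH(x, pmin(tt, cens), as.integer(tt <= cens))
    se <- sqrt(fit@covariance[1, 1])
    if (abs(coef(fit) - beta_true) <= 1.96 * se) cover <- cover + 1L
  }
  expect_gte(cover / nrep, 0.93)
  expect_lte(cover / nrep, 0.97)
})
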