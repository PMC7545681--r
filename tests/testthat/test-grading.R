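test_that("the selected-feature Cox fit is a pure delegation", {
  fx <- random_surv_fixture(80, 6, c(0.8, -0.6, rep(0, 4)), seed = 44)
  fit <- fitSelectedCox(fx$X, c("f1", "f4"), fx$time, fx$event)
  direct <- coxPH(fx$X[, c("f1", "f4")], fx$time, fx$event)
  expect_identical(coef(fit), coef(direct))
  expect_identical(fit@covariance, direct@covariance)

  expect_error(fitSelectedCox(fx$X, character(0), fx$time, fx$event),
               "threshold")
  expect_error(fitSelectedCox(fx$X, "nope", fx$time, fx$event), "not in")

  # single feature on symmetric null data: interval contains 1
  set.seed(1)
  x <- rnorm(120)
  tt <- rexp(120, 0.1)
  fit0 <- fitSelectedCox(cbind(f = x), "f", tt, rep(1, 120))
  expect_true(fit0@ci95[1, "lower"] < 1 && 1 < fit0@ci95[1, "upper"])
})

test_that("planted hazard directions are recovered by the selected-feature model", {
  # only these two effects are planted, so the two-feature fit is well
  # specified and must recover their opposite directions
  cfg <- simulationConfig(nPatients = 200,
                          beta = c(cyto.15 = 2.5, buds.35 = -0.35))
  hit <- 0L
  for (s in 1:10) {
    coh <- suppressMessages(simulateCohort(cfg, seed = 300 + s))
    fit <- fitSelectedCox(coh$experiment, c("cyto.15", "buds.35"))
    hr <- hazardRatios(fit)
    if (hr["cyto.15"] > 1 && hr["buds.35"] < 1 &&
        all(fit@waldP[c("cyto.15", "buds.35")] < 0.05)) hit <- hit + 1L
  }
  expect_gte(hit, 8L)
})

test_that("budding grade splits patients into equal halves with a deterministic tie rule", {
  set.seed(10)
  eta <- setNames(rnorm(171), sprintf("P%03d", 1:171))
  gr <- assignBuddingGrade(eta)
  expect_identical(as.vector(table(gr$grade)), c(86L, 85L))
  expect_lte(max(gr$linear_predictor[gr$grade == "low"]),
             min(gr$linear_predictor[gr$grade == "high"]))

  two <- assignBuddingGrade(c(a = 1, b = 0))
  expect_identical(as.character(two$grade[two$patient_id == "b"]), "low")

  ties <- assignBuddingGrade(setNames(rep(0, 5), c("P5", "P1", "P3", "P2", "P4")))
  expect_setequal(ties$patient_id[ties$grade == "low"], c("P1", "P2", "P3"))
  expect_setequal(ties$patient_id[ties$grade == "high"], c("P4", "P5"))

  # invariance under strictly monotone transforms of the predictor
  gr2 <- assignBuddingGrade(exp(eta))
  expect_identical(gr2$grade, gr$grade)
  expect_error(assignBuddingGrade(c(a = 1)), "at least 2")
})

test_that("stepwise selection finds the best AIC among all subsets on a small design", {
  set.seed(65)
  n <- 80
  dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  tt <- rexp(n, 0.08 * exp(1.1 * dat$x1 - 0.6 * dat$x2))
  cens <- runif(n, 1, 30)
  time <- pmin(tt, cens); event <- as.integer(tt <= cens)
  sw <- stepwiseCox(dat, time, event)
  # exhaustive enumeration of the 8 subsets
  subsets <- unlist(lapply(0:3, function(k)
    combn(names(dat), k, simplify = FALSE)), recursive = FALSE)
  aics <- vapply(subsets, function(tm) {
    if (!length(tm)) {
      ll <- morphome:::cox_loglik(matrix(0, n, 1), 0, time, event)
      return(-2 * ll)
    }
    f <- coxPH(as.matrix(dat[tm]), time, event)
    -2 * f@logLik + 2 * length(tm)
  }, numeric(1))
  expect_equal(sw$aic, min(aics), tolerance = 1e-9)
  expect_setequal(sw$retained, subsets[[which.min(aics)]])
  expect_identical(sw$trace$action[1], "start")
})

test_that("a strong covariate is retained and forced-in covariates persist", {
  keep <- 0L
  for (s in 1:10) {
    set.seed(900 + s)
    n <- 300
    dat <- data.frame(strong = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                      n3 = rnorm(n))
    tt <- rexp(n, 0.08 * exp(1 * dat$strong))
    cens <- runif(n, 1, 30)
    sw <- stepwiseCox(dat, pmin(tt, cens), as.integer(tt <= cens))
    if ("strong" %in% sw$retained) keep <- keep + 1L
  }
  expect_gte(keep, 9L)

  # forceIn keeps a null covariate in the final model
  set.seed(77)
  n <- 120
  dat <- data.frame(age = rnorm(n), x = rnorm(n))
  tt <- rexp(n, 0.08 * exp(0.9 * dat$x))
  sw <- stepwiseCox(dat, tt, rep(1, n), candidates = "x", forceIn = "age")
  expect_true(all(c("age", "x") %in% sw$retained))
})

test_that("all-noise designs rarely admit covariates under AIC", {
  # per-covariate false inclusion under AIC ~ P(chisq_1 > 2) = 0.157
  admitted <- integer(3)
  nseed <- 50
  for (s in seq_len(nseed)) {
    set.seed(1200 + s)
    n <- 150
    dat <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    tt <- rexp(n, 0.08)
    cens <- runif(n, 1, 30)
    sw <- stepwiseCox(dat, pmin(tt, cens), as.integer(tt <= cens))
    admitted <- admitted + as.integer(names(dat) %in% sw$retained)
  }
  expect_true(all(admitted / nseed <= pchisq(2, 1, lower.tail = FALSE) + 0.05))
})

test_that("multi-level factors move through stepwise selection as blocks", {
  set.seed(31)
  n <- 240
  loc <- factor(sample(c("PDAC", "DBDAC", "AMPAC", "DUOAC"), n, TRUE,
                       prob = c(.6, .1, .25, .05)),
                levels = c("PDAC", "DBDAC", "AMPAC", "DUOAC"))
  eff <- c(PDAC = 0, DBDAC = 0.1, AMPAC = -1.2, DUOAC = 0.4)
  tt <- rexp(n, 0.08 * exp(eff[as.character(loc)]))
  dat <- data.frame(location = loc, noise = rnorm(n))
  sw <- stepwiseCox(dat, tt, rep(1, n))
  expect_true("location" %in% sw$retained)
  # the whole dummy block (3 columns against the reference) entered together
  expect_identical(sum(startsWith(names(coef(sw$fit)), "location")), 3L)
})

test_that("grade survival reports order medians correctly and detect null splits", {
  # high group has uniformly halved survival, all events observed
  t_low <- seq(10, 96, length.out = 30)
  rep1 <- gradeSurvivalReport(rep(c("low", "high"), each = 30),
                              c(t_low, t_low / 2), rep(1, 60))
  expect_lt(rep1$table$median_os[rep1$table$grade == "high"],
            rep1$table$median_os[rep1$table$grade == "low"])
  expect_lt(rep1$logrank$p, 0.01)
  expect_identical(rep1$table$n, c(30L, 30L))

  # identical survival in both grades
  rep2 <- gradeSurvivalReport(rep(c("low", "high"), each = 12),
                              rep(c(3, 6, 9, 12), 6), rep(1, 24))
  expect_equal(rep2$logrank$p, 1)

  expect_error(gradeSurvivalReport(rep("low", 5), 1:5, rep(1, 5)), "present")
})

test_that("the full pipeline is bit-reproducible under a fixed master seed", {
  cfg <- simulationConfig(nPatients = 60)
  coh <- suppressMessages(simulateCohort(cfg, seed = 50))
  run <- function() suppressWarnings(runMorphomePipeline(
    coh$cells, coh$clinical, seed = 77, R = 3, V = 4,
    stepwiseCovariates = c("age", "pN", "location"),
    subgroup = c(location = "PDAC")))
  a <- run(); b <- run()
  expect_identical(selectionFrequency(a$stability),
                   selectionFrequency(b$stability))
  expect_identical(a$grades, b$grades)
  expect_identical(a$report$table, b$report$table)
  expect_identical(a$report$logrank$p, b$report$logrank$p)
  expect_identical(coef(a$fit), coef(b$fit))
  expect_identical(a$stepwise$retained, b$stepwise$retained)
  # the subgroup rerun uses the grades fitted on the full cohort
  expect_identical(a$stepwiseSubgroup$trace, b$stepwiseSubgroup$trace)
})
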