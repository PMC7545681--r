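# Repeated-CV lasso Cox stability selection.

#' Stability feature selection by repeated cross-validated lasso Cox
#'
#' Runs [cvCoxnet()] `R` times on the same data, reshuffling only the
#' cross-validation folds between repetitions and retuning the penalty at
#' each repetition's deviance minimum. A feature counts as picked in a
#' repetition when its coefficient at that repetition's `lambdaOpt` is
#' nonzero; features picked in strictly more than `threshold` of the
#' repetitions are selected (with the defaults `R = 10`, `threshold = 0.8`
#' this requires at least 9 of 10). Repetition r runs under the recorded
#' derived seed `deriveSeed(seed, r)`, so a report is a pure function of the
#' data and the master seed.
#'
#' An optional bootstrap mode additionally resamples patients with
#' replacement in each repetition; the default (fold reshuffling only) is the
#' reading of "repeated tenfold cross-validation" used throughout.
#'
#' @param x feature matrix (subjects x features) or a [MorphomeExperiment]
#'   with an attached survival outcome.
#' @param time,event survival outcome (ignored for a MorphomeExperiment).
#' @param R number of repetitions (default 10).
#' @param V folds per repetition (default 10).
#' @param alpha elastic-net mixing (default 1, the lasso).
#' @param threshold strict selection-frequency cutoff in [0, 1) (default 0.8).
#' @param seed master seed.
#' @param bootstrap resample subjects with replacement per repetition
#'   (default FALSE).
#' @param ... passed to [cvCoxnet()].
#' @return a [StabilityReport].
#' @export
setGeneric("stabilitySelect", function(x, ...) standardGeneric("stabilitySelect"))

#' @rdname stabilitySelect
#' @export
setMethod("stabilitySelect", "matrix",
  function(x, time, event, R = 10, V = 10, alpha = 1, threshold = 0.8,
           seed, bootstrap = FALSE, ...) {
    if (R < 1) stop("R must be >= 1", call. = FALSE)
    if (threshold < 0 || threshold >= 1)
      stop("threshold must be in [0, 1)", call. = FALSE)
    y <- check_survival(time, event, nrow(x))
    feats <- colnames(as_design_matrix(x))
    hits <- matrix(0, R, length(feats), dimnames = list(NULL, feats))
    rep_seed <- integer(R)
    rep_lambda <- numeric(R)
    rep_set <- character(R)
    for (r in seq_len(R)) {
      rep_seed[r] <- deriveSeed(seed, r)
      xi <- x; ti <- y$time; ei <- y$event
      if (bootstrap) {
        idx <- with_seed(deriveSeed(rep_seed[r], 0),
                         sample.int(nrow(x), replace = TRUE))
        xi <- x[idx, , drop = FALSE]; ti <- ti[idx]; ei <- ei[idx]
      }
      cv <- cvCoxnet(xi, ti, ei, V = V, alpha = alpha, seed = rep_seed[r], ...)
      nz <- names(which(coef(cv) != 0))
      hits[r, nz] <- 1
      rep_lambda[r] <- lambdaOpt(cv)
      rep_set[r] <- paste(nz, collapse = ",")
    }
    freq <- colMeans(hits)
    new("StabilityReport", nRepeats = as.integer(R), threshold = threshold,
        frequency = freq, selected = feats[freq > threshold],
        perRepeat = data.frame(repeat_index = seq_len(R), seed = rep_seed,
                               lambda_opt = rep_lambda, nonzero = rep_set),
        seed = as.integer(seed))
  })

#' @rdname stabilitySelect
#' @export
setMethod("stabilitySelect", "MorphomeExperiment",
  function(x, R = 10, V = 10, alpha = 1, threshold = 0.8, seed,
           bootstrap = FALSE, ...) {
    y <- survivalOutcome(x)
    stabilitySelect(morphomeMatrix(x), y$time, y$event, R = R, V = V,
                    alpha = alpha, threshold = threshold, seed = seed,
                    bootstrap = bootstrap, ...)
  })

#' @rdname StabilityReport-class
#' @export
setMethod("selectedFeatures", "StabilityReport", function(x, ...) x@selected)

#' @rdname StabilityReport-class
#' @export
setMethod("selectionFrequency", "StabilityReport", function(x, ...) x@frequency)

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf("StabilityReport: %d repetitions, threshold > %.2f, seed %d\n",
              object@nRepeats, object@threshold, object@seed))
  cat("  selected:",
      if (length(object@selected)) paste(object@selected, collapse = ", ")
      else "(none)", "\n")
  nz <- sort(object@frequency[object@frequency > 0], decreasing = TRUE)
  if (length(nz)) {
    cat("  frequencies > 0:\n")
    for (f in names(nz)) cat(sprintf("    %-10s %.2f\n", f, nz[[f]]))
  }
})

#' Write a stability report as machine-readable key-value text
#'
#' @param report a [StabilityReport].
#' @param file output path; frequencies for every feature, the threshold and
#'   the per-repetition log are written as tab-separated key-value sections.
#' @export
writeStabilityReport <- function(report, file) {
  stopifnot(is(report, "StabilityReport"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("n_repeats\t%d", report@nRepeats), con)
  writeLines(sprintf("threshold\t%g", report@threshold), con)
  writeLines(sprintf("seed\t%d", report@seed), con)
  writeLines(sprintf("selected\t%s", paste(report@selected, collapse = ",")), con)
  writeLines(sprintf("frequency\t%s\t%g", names(report@frequency),
                     report@frequency), con)
  writeLines(sprintf("repeat\t%d\t%d\t%g\t%s", report@perRepeat$repeat_index,
                     report@perRepeat$seed, report@perRepeat$lambda_opt,
                     report@perRepeat$nonzero), con)
  invisible(file)
}
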