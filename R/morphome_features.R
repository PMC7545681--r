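# The 40-feature morphome matrix: size-bin counts and per-bin E-Cadherin
# pattern fractions.

BIN_UPPER <- seq(5L, 50L, by = 5L)

#' Cluster size bins and morphome feature names
#'
#' Cluster sizes 1..50 partition into ten 5-cell bins (1-5, 6-10, ...,
#' 46-50). Features are named by the bin's upper bound: `buds.u` is the
#' number of clusters in the bin ending at `u` cells, and `cyto.u`, `mix.u`,
#' `memb.u` are the fractions of cells in those clusters with cytoplasmic,
#' mixed and membranous E-Cadherin localization.
#'
#' @return `sizeBins()`: data.frame with columns `index`, `lower`, `upper`,
#'   `label`; `morphomeFeatureNames()`: the 40 feature names in canonical
#'   column order (all counts, then cyto, mix, memb fraction blocks).
#' @export
sizeBins <- function() {
  data.frame(index = 1:10, lower = BIN_UPPER - 4L, upper = BIN_UPPER,
             label = paste0("buds.", BIN_UPPER))
}

#' @rdname sizeBins
#' @export
morphomeFeatureNames <- function() {
  c(paste0("buds.", BIN_UPPER), paste0("cyto.", BIN_UPPER),
    paste0("mix.", BIN_UPPER), paste0("memb.", BIN_UPPER))
}

#' Assign cluster sizes to size bins
#'
#' @param size integer vector of cluster sizes in 1..50.
#' @return integer bin index in 1..10 (`ceiling(size / 5)`).
#' @examples
#' assignSizeBin(6)   # bin 2, i.e. buds.10
#' @export
assignSizeBin <- function(size) {
  if (any(size < 1 | size > 50 | size != as.integer(size)))
    stop("cluster sizes must be integers in 1..50", call. = FALSE)
  as.integer(ceiling(size / 5))
}

#' Build the morphome feature matrix
#'
#' Converts a cluster census into the per-patient morphome features: for each
#' of the ten size bins, the cluster count (`buds.u`) and the fraction of
#' cells in that bin's clusters with each E-Cadherin pattern (`cyto.u`,
#' `mix.u`, `memb.u`). For a patient with no cluster in a bin the count is 0
#' and, by convention, all three fractions are imputed with `emptyValue`
#' (default 0; the zero count itself carries the absence signal to any
#' downstream model).
#'
#' @param census a [ClusterCensus].
#' @param patients patient ordering for the columns; defaults to the sorted
#'   patients present in the census. Every census patient must be listed;
#'   extra patients get all-zero features.
#' @param emptyValue value for the three pattern fractions of an empty bin.
#' @return a [MorphomeExperiment] (features x patients).
#' @export
buildMorphomeMatrix <- function(census, patients = NULL, emptyValue = 0) {
  stopifnot(is(census, "ClusterCensus"))
  cl <- clusters(census)
  if (is.null(patients)) patients <- sort(unique(cl$patient_id))
  if (!all(cl$patient_id %in% patients))
    stop("census contains patients missing from 'patients'", call. = FALSE)
  n <- length(patients)
  feat <- matrix(0, nrow = 40, ncol = n,
                 dimnames = list(morphomeFeatureNames(), patients))
  if (nrow(cl)) {
    bin <- assignSizeBin(cl$size)
    pi <- match(cl$patient_id, patients)
    lev <- paste(rep(seq_len(n), each = 10), 1:10, sep = ":")
    key <- paste(pi, bin, sep = ":")
    got <- rowsum(cbind(count = 1, cells = cl$size, cyto = cl$n_cytoplasmic,
                        mix = cl$n_mixed, memb = cl$n_membranous),
                  key)
    agg <- matrix(0, nrow = length(lev), ncol = ncol(got),
                  dimnames = list(lev, colnames(got)))
    agg[rownames(got), ] <- got
    cnt <- matrix(agg[, "count"], nrow = 10)     # bins x patients
    cells <- matrix(agg[, "cells"], nrow = 10)
    frac <- function(colname) {
      f <- matrix(agg[, colname], nrow = 10) / cells
      f[cells == 0] <- emptyValue
      f
    }
    feat[1:10, ] <- cnt
    feat[11:20, ] <- frac("cyto")
    feat[21:30, ] <- frac("mix")
    feat[31:40, ] <- frac("memb")
  }
  rd <- DataFrame(
    feature = morphomeFeatureNames(),
    type = rep(c("count", "fraction"), c(10, 30)),
    pattern = rep(c(NA, "cytoplasmic", "mixed", "membranous"), each = 10),
    bin_lower = rep(BIN_UPPER - 4L, 4), bin_upper = rep(BIN_UPPER, 4))
  se <- SummarizedExperiment(assays = list(morphome = feat), rowData = rd,
                             colData = DataFrame(row.names = patients))
  new("MorphomeExperiment", se)
}

#' @rdname MorphomeExperiment-class
#' @return `morphomeMatrix()`: the patients-by-features numeric matrix.
#' @export
setMethod("morphomeMatrix", "MorphomeExperiment",
          function(x, ...) t(SummarizedExperiment::assay(x, "morphome")))

#' @rdname MorphomeExperiment-class
#' @return `survivalOutcome()`: data.frame with columns `time` (months) and
#'   `event` (0/1), rownames = patients.
#' @export
setMethod("survivalOutcome", "MorphomeExperiment", function(x, ...) {
  cd <- colData(x)
  if (!all(c("time_months", "event") %in% names(cd)))
    stop("no survival outcome attached; see attachClinical()", call. = FALSE)
  data.frame(time = as.numeric(cd$time_months), event = as.integer(cd$event),
             row.names = rownames(cd))
})

#' Attach clinical covariates and survival to a MorphomeExperiment
#'
#' @param x a [MorphomeExperiment].
#' @param clinical data.frame with a `patient_id` column plus clinical
#'   covariates; for survival analyses it must include `time_months` and
#'   `event`.
#' @return `x` with the clinical columns merged into `colData`.
#' @export
attachClinical <- function(x, clinical) {
  stopifnot(is(x, "MorphomeExperiment"), "patient_id" %in% names(clinical))
  idx <- match(colnames(x), clinical$patient_id)
  if (anyNA(idx))
    stop("clinical table is missing patient(s): ",
         paste(colnames(x)[is.na(idx)], collapse = ", "), call. = FALSE)
  add <- clinical[idx, setdiff(names(clinical), "patient_id"), drop = FALSE]
  rownames(add) <- colnames(x)
  colData(x) <- cbind(colData(x), as(add, "DataFrame"))
  validObject(x)
  x
}

setMethod("show", "MorphomeExperiment", function(object) {
  cat("MorphomeExperiment:", ncol(object), "patients x", nrow(object),
      "morphome features\n")
  cat("  colData:", paste(names(colData(object)), collapse = ", "), "\n")
})

#' Inverse regression of cluster count on cluster size
#'
#' Ordinary least squares of `count ~ 1/size`, the inverse law relating how
#' many clusters of a given size are observed to the size itself (cluster
#' number rises steeply as cluster size falls). When applied at cohort level
#' the (size, count) points are pooled across patients, i.e. a
#' between-subjects analysis.
#'
#' @param sizes positive cluster sizes.
#' @param counts observed counts (one per size entry).
#' @return list with `intercept`, `slope` (coefficient of 1/size), `p_slope`
#'   (two-sided t-test), and `r_squared`.
#' @export
inverseRegression <- function(sizes, counts) {
  if (length(sizes) != length(counts) || length(sizes) < 3)
    stop("need >= 3 (size, count) points", call. = FALSE)
  if (any(sizes <= 0)) stop("sizes must be positive", call. = FALSE)
  inv <- 1 / sizes
  if (var(inv) == 0) stop("zero-variance predictor", call. = FALSE)
  fit <- lm(counts ~ inv)
  sm <- summary(fit)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       p_slope = unname(sm$coefficients["inv", "Pr(>|t|)"]),
       r_squared = sm$r.squared)
}

#' Write / read a morphome feature matrix
#'
#' Tab-separated table: first column `patient_id`, then the 40 canonical
#' feature columns in fixed order.
#'
#' @param x a [MorphomeExperiment].
#' @param path file path.
#' @export
writeMorphomeMatrix <- function(x, path) {
  stopifnot(is(x, "MorphomeExperiment"))
  tab <- data.frame(patient_id = colnames(x), morphomeMatrix(x),
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMorphomeMatrix
#' @export
readMorphomeMatrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE,
                    colClasses = c(patient_id = "character"))
  if (!identical(names(tab), c("patient_id", morphomeFeatureNames())))
    stop("not a morphome matrix file", call. = FALSE)
  m <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(m) <- tab$patient_id
  rd <- DataFrame(
    feature = morphomeFeatureNames(),
    type = rep(c("count", "fraction"), c(10, 30)),
    pattern = rep(c(NA, "cytoplasmic", "mixed", "membranous"), each = 10),
    bin_lower = rep(BIN_UPPER - 4L, 4), bin_upper = rep(BIN_UPPER, 4))
  se <- SummarizedExperiment(assays = list(morphome = m), rowData = rd,
                             colData = DataFrame(row.names = tab$patient_id))
  new("MorphomeExperiment", se)
}
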