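# Per-cell annotation I/O and the per-patient cluster census.

#' Read a per-cell E-Cadherin annotation table
#'
#' Reads the tab-separated per-cell table produced by manual or automated
#' field annotation: one row per tumor cell with its cluster membership and
#' subcellular E-Cadherin localization. Every cell must carry exactly one of
#' the three patterns `membranous`, `mixed`, `cytoplasmic` (E-Cadherin
#' negative tumor cells do not occur in this assay, so any other string is
#' rejected).
#'
#' @param path path to a UTF-8 tab-separated file with header columns
#'   `patient_id`, `field_id`, `cluster_id`, `cell_id`, `ecad_pattern`.
#' @return data.frame of validated cell records, `ecad_pattern` as a factor
#'   with levels membranous, mixed, cytoplasmic.
#' @seealso [buildClusterCensus()]
#' @export
readCells <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cells <- read.delim(path, colClasses = "character", check.names = FALSE)
  validateCells(cells)
}

#' @rdname readCells
#' @param cells a data.frame of cell records to validate (as read by
#'   `readCells` or constructed in code).
#' @export
validateCells <- function(cells) {
  need <- c("patient_id", "field_id", "cluster_id", "cell_id", "ecad_pattern")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cells <- as.data.frame(cells)[need]
  bad <- setdiff(unique(as.character(cells$ecad_pattern)), ECAD_PATTERNS)
  if (length(bad))
    stop("unknown ecad_pattern value(s): ", paste(bad, collapse = ", "),
         "; must be one of ", paste(ECAD_PATTERNS, collapse = "/"),
         call. = FALSE)
  key <- paste(cells$patient_id, cells$field_id, cells$cluster_id,
               cells$cell_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (patient_id, field_id, cluster_id, cell_id) cell keys",
         call. = FALSE)
  cells$ecad_pattern <- factor(as.character(cells$ecad_pattern),
                               levels = ECAD_PATTERNS)
  cells
}

#' Build the cluster census from cell records
#'
#' Tallies cells into one record per (patient, field, cluster): the cluster
#' size and the number of member cells per E-Cadherin pattern. Isolated cells
#' form size-1 clusters. Clusters above `maxSize` cells are treated as main
#' tumor mass, moved to the exclusion log, and reported with a message --
#' never silently dropped. Identical `cluster_id`s in different fields are
#' distinct clusters.
#'
#' @param cells data.frame of cell records (see [readCells()]).
#' @param maxSize inclusive cluster-size cutoff (default 50 cells).
#' @return a [ClusterCensus].
#' @examples
#' cells <- data.frame(patient_id = "P1", field_id = "F1",
#'                     cluster_id = c("c1", "c1", "c2"),
#'                     cell_id = c("a", "b", "c"),
#'                     ecad_pattern = c("membranous", "mixed", "cytoplasmic"))
#' census <- buildClusterCensus(cells)
#' clusters(census)
#' @export
buildClusterCensus <- function(cells, maxSize = 50) {
  cells <- validateCells(cells)
  if (!nrow(cells)) {
    empty <- data.frame(patient_id = character(), field_id = character(),
                        cluster_id = character(), size = integer(),
                        n_membranous = integer(), n_mixed = integer(),
                        n_cytoplasmic = integer())
    return(new("ClusterCensus", clusters = empty, excluded = empty,
               maxSize = maxSize))
  }
  key <- paste(cells$patient_id, cells$field_id, cells$cluster_id, sep = "\r")
  ind <- cbind(membranous = as.numeric(cells$ecad_pattern == "membranous"),
               mixed = as.numeric(cells$ecad_pattern == "mixed"),
               cytoplasmic = as.numeric(cells$ecad_pattern == "cytoplasmic"))
  agg <- rowsum(ind, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(patient_id = cells$patient_id[first],
                    field_id = cells$field_id[first],
                    cluster_id = cells$cluster_id[first],
                    size = as.integer(rowSums(agg)),
                    n_membranous = as.integer(agg[, "membranous"]),
                    n_mixed = as.integer(agg[, "mixed"]),
                    n_cytoplasmic = as.integer(agg[, "cytoplasmic"]))
  out <- out[order(out$patient_id, out$cluster_id, out$field_id), ]
  rownames(out) <- NULL
  over <- out$size > maxSize
  excluded <- out[over, , drop = FALSE]
  rownames(excluded) <- NULL
  if (nrow(excluded))
    message(nrow(excluded), " cluster(s) larger than ", maxSize,
            " cells excluded from the census (",
            sum(excluded$size), " cells)")
  new("ClusterCensus", clusters = out[!over, , drop = FALSE],
      excluded = excluded, maxSize = maxSize)
}

#' @rdname ClusterCensus-class
#' @export
setMethod("clusters", "ClusterCensus", function(x, ...) x@clusters)

#' @rdname ClusterCensus-class
#' @export
setMethod("excludedClusters", "ClusterCensus", function(x, ...) x@excluded)

#' @rdname ClusterCensus-class
#' @export
setMethod("maxSize", "ClusterCensus", function(x, ...) x@maxSize)

setMethod("show", "ClusterCensus", function(object) {
  cl <- object@clusters
  cat("ClusterCensus:", nrow(cl), "clusters /",
      length(unique(cl$patient_id)), "patients",
      sprintf("(size <= %g;", object@maxSize),
      nrow(object@excluded), "excluded)\n")
  if (nrow(cl))
    cat("  cells:", sum(cl$size), " size range:",
        paste(range(cl$size), collapse = "-"), "\n")
})

#' Summarize a cluster census
#'
#' Cohort-level accounting of an included-cluster census: total cells,
#' per-pattern totals and fractions, clusters per patient, and median cluster
#' size computed per patient first (the overall value is the median of the
#' per-patient medians, matching how a per-tumor morphometry readout is
#' aggregated).
#'
#' @param census a [ClusterCensus].
#' @return a [CensusSummary].
#' @export
summarizeCensus <- function(census) {
  stopifnot(is(census, "ClusterCensus"))
  cl <- clusters(census)
  if (!nrow(cl)) stop("empty census", call. = FALSE)
  totals <- c(membranous = sum(cl$n_membranous),
              mixed = sum(cl$n_mixed),
              cytoplasmic = sum(cl$n_cytoplasmic))
  per <- split(cl$size, cl$patient_id)
  med <- vapply(per, median, numeric(1))
  new("CensusSummary",
      totalCells = as.integer(sum(cl$size)),
      patternTotals = totals,
      patternFractions = patternFractions(totals),
      clustersPerPatient = vapply(per, length, numeric(1)),
      medianClusterSizePerPatient = med,
      overallMedianClusterSize = median(med))
}

#' Pattern fractions from integer pattern totals
#'
#' Converts per-pattern cell counts to fractions of the cell total. Counts
#' are exact integers, so the fractions share a common denominator and sum to
#' one up to a final floating-point conversion.
#'
#' @param totals named non-negative integer vector of cells per pattern.
#' @return named numeric fractions summing to 1.
#' @examples
#' patternFractions(c(membranous = 36981, mixed = 77535, cytoplasmic = 29879))
#' @export
patternFractions <- function(totals) {
  if (any(totals < 0) || sum(totals) == 0)
    stop("pattern totals must be non-negative with a positive sum",
         call. = FALSE)
  totals / sum(totals)
}

setMethod("show", "CensusSummary", function(object) {
  cat("CensusSummary:", object@totalCells, "cells in",
      sum(object@clustersPerPatient), "clusters /",
      length(object@clustersPerPatient), "patients\n")
  pct <- roundHalfUp(100 * object@patternFractions)
  for (p in names(object@patternTotals))
    cat(sprintf("  %-12s %7d (%g%%)\n", p, object@patternTotals[[p]], pct[[p]]))
  cat("  overall median cluster size:", object@overallMedianClusterSize, "\n")
})

#' Convert a field area to square millimetres
#'
#' Microscopy field areas are recorded in square micrometres; reports quote
#' them in mm^2 (e.g. the 516788.1 um^2 field of a 200x magnification view is
#' 0.517 mm^2). Rounds half-up to `decimals` places.
#'
#' @param area_um2 non-negative area in square micrometres.
#' @param decimals decimal places for the rounded result (default 3).
#' @return area in mm^2.
#' @examples
#' fieldAreaMm2(516788.1)
#' @export
fieldAreaMm2 <- function(area_um2, decimals = 3) {
  if (!is.numeric(area_um2) || any(area_um2 < 0))
    stop("area must be non-negative", call. = FALSE)
  roundHalfUp(area_um2 / 1e6, decimals)
}

#' Write / read a cluster census table
#'
#' Tab-separated serialization of the included clusters, ordered by
#' (patient_id, cluster_id) for byte-stable round trips.
#'
#' @param census a [ClusterCensus].
#' @param path output (input) file path.
#' @return `readClusterCensus` returns a [ClusterCensus] with an empty
#'   exclusion log (exclusions happen upstream of serialization).
#' @export
writeClusterCensus <- function(census, path) {
  stopifnot(is(census, "ClusterCensus"))
  write.table(clusters(census), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeClusterCensus
#' @param maxSize cluster-size cutoff recorded on the restored object.
#' @export
readClusterCensus <- function(path, maxSize = 50) {
  tab <- read.delim(path, colClasses = c(patient_id = "character",
                                         field_id = "character",
                                         cluster_id = "character"))
  tab <- tab[CENSUS_COLUMNS]
  for (col in c("size", "n_membranous", "n_mixed", "n_cytoplasmic"))
    tab[[col]] <- as.integer(tab[[col]])
  new("ClusterCensus", clusters = tab, excluded = tab[0, ], maxSize = maxSize)
}
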