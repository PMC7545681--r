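# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Decimal rounding with the "half-up" tie rule used in the report tables
#' (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @examples
#' roundHalfUp(0.5)    # 1
#' roundHalfUp(2.5)    # 3, where round() gives 2
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so seeded functions are pure.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

#' Derive a reproducible child seed
#'
#' Deterministic integer mixing of a master seed and an index, used to give
#' every repetition of a seeded procedure its own recorded RNG stream. The
#' result is always in `[1, 2^31 - 2]`.
#'
#' @param seed master seed (single integer).
#' @param index repetition index (single non-negative integer).
#' @return a single integer seed.
#' @export
deriveSeed <- function(seed, index) {
  stopifnot(length(seed) == 1, length(index) == 1)
  m <- 2147483647                       # 2^31 - 1, Mersenne prime modulus
  s <- (as.numeric(seed) %% m) + 1
  for (k in seq_len(index + 1)) s <- (s * 48271 + k) %% m
  as.integer(s %% (m - 1) + 1)
}

# Basic argument checks ------------------------------------------------------

check_survival <- function(time, event, n = NULL) {
  if (!is.numeric(time) || any(!is.finite(time)) || any(time <= 0))
    stop("follow-up 'time' must be positive and finite", call. = FALSE)
  ev <- as.integer(event)
  if (any(is.na(ev)) || !all(ev %in% c(0L, 1L)))
    stop("'event' must be 0/1 (or logical)", call. = FALSE)
  if (length(time) != length(ev))
    stop("'time' and 'event' lengths differ", call. = FALSE)
  if (!is.null(n) && length(time) != n)
    stop("survival outcome length does not match the design matrix", call. = FALSE)
  list(time = as.numeric(time), event = ev)
}

as_design_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (!is.matrix(x) || !is.numeric(x))
    stop("design must be a numeric matrix", call. = FALSE)
  if (anyNA(x)) stop("design matrix contains missing values", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  x
}
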