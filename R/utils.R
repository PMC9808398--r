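# Internal helpers: seed streams, argument checks.

#' Derive a reproducible sub-seed from a master seed
#'
#' Each pipeline stage draws its randomness from its own stream so that
#' changing, say, the number of control genes sampled during scoring does not
#' perturb the synthetic-data stream. Streams are derived deterministically
#' from one master seed and a stage tag; the result always fits in a 32-bit
#' signed integer.
#'
#' @param master integer master seed.
#' @param tag character stage label (e.g. `"qc"`, `"controls"`).
#' @param k optional integer offset for repeated draws within a stage.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, tag, k = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  val <- (abs(as.numeric(master)) * 48271 + h * 16807 + as.numeric(k) * 69621)
  as.integer(val %% (2^31 - 1))
}

# stop() unless x is a single finite number in [lo, hi]
.check_scalar <- function(x, name, lo = -Inf, hi = Inf,
                          integer = FALSE, lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  ok_lo <- if (lo_open) x > lo else x >= lo
  ok_hi <- if (hi_open) x < hi else x <= hi
  if (!ok_lo || !ok_hi)
    stop(sprintf("'%s' = %s is outside its allowed range", name,
                 format(x)), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(x)
}

# Dense or sparse matrix of non-negative counts with dimnames
.check_counts <- function(counts) {
  if (!(is.matrix(counts) || is(counts, "Matrix")))
    stop("'counts' must be a matrix (genes x cells)", call. = FALSE)
  if (min(counts) < 0)
    stop("'counts' must be non-negative", call. = FALSE)
  invisible(counts)
}

# Jaccard similarity of two character sets
.jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}
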