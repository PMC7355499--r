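# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards. A `NULL` seed evaluates `expr` with the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-stage child seeds from a master seed (counter scheme).
# Kept below 2^31 - 1.
derive_seeds <- function(master, n) {
  if (is.null(master)) return(rep(list(NULL), n))
  with_seed(master, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

# Positive draws from N(mean, sd) by rejection; sd = 0 returns the mean.
rnorm_pos <- function(n, mean, sd, max_retry = 1000L) {
  if (sd <= 0) {
    if (mean <= 0) stop("mean of a positive-truncated normal must be > 0 when sd = 0")
    return(rep(mean, n))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (k in seq_len(max_retry)) {
      x <- stats::rnorm(1L, mean, sd)
      if (x > 0) break
      x <- NA_real_
    }
    if (is.na(x)) stop("failed to draw a positive conduction velocity after ", max_retry, " retries")
    out[i] <- x
  }
  out
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a finite numeric scalar")
  }
  if (positive && x <= 0) stop("'", name, "' must be > 0")
  invisible(x)
}
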