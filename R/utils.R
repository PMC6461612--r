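# Small shared helpers: seeding, transforms.

#' Evaluate an expression with a locally fixed RNG state
#'
#' Saves the caller's RNG state, seeds the generator (Mersenne-Twister with
#' inversion sampling, so streams are identical across platforms), evaluates
#' `expr`, and restores the previous state. With `seed = NULL` the expression
#' simply runs against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Fisher r-to-z transform
#'
#' `atanh` with clamping just inside (-1, 1) so sample correlations of exactly
#' +/-1 stay finite.
#'
#' @param r correlations.
#' @return z values.
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
}

#' Rank-based inverse-normal (Blom) scores
#'
#' Maps a numeric vector to normal quantiles via
#' `qnorm((rank - 3/8) / (n + 1/4))` with ties averaged. Invariant under any
#' strictly monotone rescaling of the input.
#'
#' @param x numeric vector (length >= 1).
#' @return numeric vector of normal scores.
#' @export
rank_normal <- function(x) {
  n <- length(x)
  stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
}

# trapezoidal integral of y over x (both sorted by x)
.trapz <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("length mismatch between grid and values")
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# upper-triangle logical mask (no diagonal)
.ut <- function(n) upper.tri(matrix(0, n, n))
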