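# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded simulator calls do not disturb the session stream.
#' With `seed = NULL` the current stream is used (and advanced).
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  code
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and a stream tag.
sub_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 48271 + tag * 7919) %% 2147483629 + 1)
}

#' Rectified linear unit
#'
#' Elementwise `max(0, x)`, preserving array dimensions.
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape with negative entries zeroed.
#' @export
relu <- function(x) {
  y <- pmax(x, 0)
  dim(y) <- dim(x)
  dimnames(y) <- dimnames(x)
  y
}

#' Row-wise softmax
#'
#' Numerically stable softmax applied to each row of a matrix.
#' @param m Numeric matrix.
#' @return Matrix of the same shape; rows sum to 1.
#' @export
softmax_rows <- function(m) {
  m <- as.matrix(m)
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

# Row maxima of a matrix without apply() overhead.
row_max <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop(sprintf("'%s' must be a single non-negative integer", name), call. = FALSE)
  as.integer(x)
}
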