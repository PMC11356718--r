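# Network primitives: valid n-D convolution (im2col), non-overlapping
# max-pooling, Elman recurrence with day/entry masking, and parameter
# accounting. These are the building blocks of the MRI, HPMRS and tabular
# branches; layouts are spatial-dims-first with a trailing channel axis.

#' Convolution/pooling block specification
#'
#' Describes one encoder stage: a valid (no padding, stride 1) convolution
#' with `kernel`, a ReLU, and a non-overlapping max-pool whose stride equals
#' its kernel `pool`. The trainable parameter count is
#' `out_channels * (in_channels * prod(kernel) + 1)` (weights plus one bias
#' per output channel).
#'
#' @param in_channels,out_channels Channel counts (positive integers).
#' @param kernel Integer vector of kernel extents, one per spatial axis
#'   (length 3 for volumes, 2 for spectra).
#' @param pool Integer vector of pooling extents, same length as `kernel`.
#' @return An object of class `conv_spec`.
#' @export
conv_spec <- function(in_channels, out_channels, kernel, pool) {
  in_channels <- assert_count(in_channels, "in_channels")
  out_channels <- assert_count(out_channels, "out_channels")
  stopifnot(length(kernel) == length(pool), all(kernel >= 1), all(pool >= 1))
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 kernel = as.integer(kernel), pool = as.integer(pool)),
            class = "conv_spec")
}

#' Elman recurrence specification
#'
#' Single-layer recurrent aggregator: `h_t = tanh(W x_t + U h_{t-1} + b)`.
#' The optional linear output head is off by default; the hidden states are
#' the emitted representation, so the parameter count is
#' `hidden*input + hidden^2 + 2*hidden` (the conventional count includes the
#' input and recurrent biases).
#'
#' @param input,hidden Input and hidden widths.
#' @return An object of class `rnn_spec`.
#' @export
rnn_spec <- function(input, hidden) {
  structure(list(input = assert_count(input, "input"),
                 hidden = assert_count(hidden, "hidden")),
            class = "rnn_spec")
}

#' Multi-head attention specification
#'
#' Scaled dot-product attention with bias-free square projections for query,
#' key, value and output (`4 * d^2` parameters) split over `heads` heads of
#' width `d / heads`.
#'
#' @param d Embedding width (divisible by `heads`).
#' @param heads Number of attention heads.
#' @return An object of class `attention_spec`.
#' @export
attention_spec <- function(d = 256L, heads = 2L) {
  d <- assert_count(d, "d"); heads <- assert_count(heads, "heads")
  if (d %% heads != 0L) stop("'d' must be divisible by 'heads'")
  structure(list(d = d, heads = heads, d_k = d %/% heads), class = "attention_spec")
}

#' Count trainable parameters of a layer specification
#'
#' @param spec A `conv_spec`, `rnn_spec` or `attention_spec`.
#' @param ... Unused.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec, ...) UseMethod("count_parameters")

#' @export
count_parameters.conv_spec <- function(spec, ...)
  spec$out_channels * (spec$in_channels * as.integer(prod(spec$kernel)) + 1L)

#' @export
count_parameters.rnn_spec <- function(spec, ...)
  spec$hidden * spec$input + spec$hidden * spec$hidden + 2L * spec$hidden

#' @export
count_parameters.attention_spec <- function(spec, ...) 4L * spec$d * spec$d

# ---- shape arithmetic ------------------------------------------------------

conv_out_dims <- function(in_dims, kernel) {
  out <- in_dims - kernel + 1L
  bad <- which(out < 1L)
  if (length(bad))
    stop(sprintf("input axis %d (extent %d) is smaller than kernel extent %d",
                 bad[1], in_dims[bad[1]], kernel[bad[1]]), call. = FALSE)
  out
}

pool_out_dims <- function(in_dims, pool) {
  out <- in_dims %/% pool
  bad <- which(out < 1L)
  if (length(bad))
    stop(sprintf("axis %d (extent %d) underflows pooling extent %d",
                 bad[1], in_dims[bad[1]], pool[bad[1]]), call. = FALSE)
  out
}

#' Output shapes of a convolution/pooling block
#'
#' Valid convolution followed by floor-division pooling, the only convention
#' consistent with the reference layer census (e.g. height 145 pools to 48).
#'
#' @param in_dims Integer vector of input spatial extents.
#' @param spec A [conv_spec()].
#' @return List with `conv` and `pool` spatial extents.
#' @export
conv_block_shape <- function(in_dims, spec) {
  cd <- conv_out_dims(as.integer(in_dims), spec$kernel)
  list(conv = cd, pool = pool_out_dims(cd, spec$pool))
}

# ---- im2col machinery ------------------------------------------------------

# Linear (1-based) gather indices for all sliding windows of `kernel` over a
# single-channel array of extents `in_dims`, moving with `stride`.
# Rows = output positions (first axis fastest), cols = within-window offsets.
patch_index <- function(in_dims, kernel, stride) {
  nd <- length(in_dims)
  mult <- cumprod(c(1L, in_dims[-nd]))
  starts <- lapply(seq_len(nd), function(a)
    seq.int(0L, by = stride[a], length.out = (in_dims[a] - kernel[a]) %/% stride[a] + 1L))
  base <- Reduce(function(x, y) outer(x, y, "+"),
                 Map(function(s, m) s * m, starts, as.list(mult)))
  offs <- Reduce(function(x, y) outer(x, y, "+"),
                 Map(function(k, m) (seq_len(k) - 1L) * m, as.list(kernel), as.list(mult)))
  outer(as.vector(base), as.vector(offs), "+") + 1L
}

# Gather an input array (spatial dims ..., C) into the im2col patch matrix:
# one row per output position, columns blocked by channel.
im2col <- function(x, kernel, stride) {
  dx <- dim(x)
  nd <- length(kernel)
  in_dims <- dx[seq_len(nd)]
  C <- if (length(dx) > nd) dx[nd + 1L] else 1L
  idx <- patch_index(in_dims, kernel, stride)
  npix <- prod(in_dims)
  pk <- ncol(idx)
  P <- matrix(0, nrow(idx), pk * C)
  xf <- as.vector(x)
  for (c in seq_len(C))
    P[, ((c - 1L) * pk + 1L):(c * pk)] <- xf[idx + (c - 1L) * npix]
  P
}

#' Apply one convolution + ReLU + max-pooling block
#'
#' The convolution realizes, for every output voxel and output channel, the
#' sum over input channels and kernel offsets of weight times input plus a
#' per-channel bias; the result passes through a ReLU and a non-overlapping
#' max-pool (stride = pool kernel).
#'
#' @param x Numeric array, spatial dims first, trailing channel axis
#'   (a bare 2-/3-D array is treated as single-channel).
#' @param weights List with `W` (matrix `in_channels*prod(kernel)` rows,
#'   `out_channels` columns, rows blocked by input channel) and `b`
#'   (length `out_channels`).
#' @param spec A [conv_spec()].
#' @return Array `(pooled spatial dims ..., out_channels)`.
#' @export
conv_block <- function(x, weights, spec) {
  nd <- length(spec$kernel)
  if (is.null(dim(x))) stop("'x' must be an array")
  if (length(dim(x)) == nd) dim(x) <- c(dim(x), 1L)
  dx <- dim(x)
  if (dx[nd + 1L] != spec$in_channels)
    stop(sprintf("input has %d channels, spec expects %d", dx[nd + 1L], spec$in_channels))
  sh <- conv_block_shape(dx[seq_len(nd)], spec)
  P <- im2col(x, spec$kernel, rep(1L, nd))
  Z <- P %*% weights$W
  Z <- sweep(Z, 2L, weights$b, "+")
  Z[Z < 0] <- 0                      # ReLU
  dim(Z) <- c(sh$conv, spec$out_channels)
  max_pool(Z, spec$pool)
}

#' Non-overlapping max-pooling
#'
#' @param x Array (spatial dims ..., channels).
#' @param pool Integer pooling extents per spatial axis; stride equals the
#'   pooling kernel and trailing remainders are dropped (floor division).
#' @return Pooled array with the same channel count.
#' @export
max_pool <- function(x, pool) {
  nd <- length(pool)
  dx <- dim(x)
  if (length(dx) == nd) dim(x) <- c(dim(x), 1L); dx <- dim(x)
  in_dims <- dx[seq_len(nd)]
  C <- dx[nd + 1L]
  out_dims <- pool_out_dims(in_dims, as.integer(pool))
  idx <- patch_index(in_dims, as.integer(pool), as.integer(pool))
  npix <- prod(in_dims)
  xf <- as.vector(x)
  out <- matrix(0, nrow(idx), C)
  for (c in seq_len(C)) {
    v <- xf[idx + (c - 1L) * npix]
    dim(v) <- dim(idx)
    out[, c] <- row_max(v)
  }
  dim(out) <- c(out_dims, C)
  out
}

# ---- recurrence ------------------------------------------------------------

#' Elman recurrence over a day-ordered sequence
#'
#' `h_t = tanh(W x_t + U h_{t-1} + b)` with `h_0 = 0`. Two masking contracts:
#' a day marked in `day_mask` propagates the previous hidden state unchanged
#' (the step is skipped entirely), and entries marked in `input_mask` are
#' zeroed before the input-to-hidden product so imputed values cannot affect
#' the result.
#'
#' @param X Matrix, one row per day (ordered), `spec$input` columns.
#' @param weights List with `W` (hidden x input), `U` (hidden x hidden),
#'   `b` (hidden).
#' @param spec An [rnn_spec()].
#' @param day_mask Logical vector, `TRUE` = whole day missing/imputed.
#' @param input_mask Logical matrix like `X`, `TRUE` = masked entry.
#' @param activation Elementwise activation, default [tanh].
#' @return Matrix of hidden states, one row per day.
#' @export
elman_forward <- function(X, weights, spec, day_mask = NULL, input_mask = NULL,
                          activation = tanh) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty sequence")
  if (ncol(X) != spec$input)
    stop(sprintf("input width %d, spec expects %d", ncol(X), spec$input))
  if (!is.null(input_mask)) X[input_mask] <- 0
  D <- nrow(X)
  H <- matrix(0, D, spec$hidden)
  h <- numeric(spec$hidden)
  for (t in seq_len(D)) {
    if (!is.null(day_mask) && isTRUE(day_mask[t])) {
      H[t, ] <- h
      next
    }
    h <- activation(drop(weights$W %*% X[t, ] + weights$U %*% h) + weights$b)
    H[t, ] <- h
  }
  H
}

# ---- attention -------------------------------------------------------------

#' Scaled dot-product multi-head attention
#'
#' Projects inputs with bias-free square matrices, splits them into heads,
#' applies `softmax(Q K^T / sqrt(d_k)) V` per head, concatenates the heads
#' and applies the output projection. `weights = NULL` uses identity
#' projections (useful for hand-checked examples).
#'
#' @param Q_in,K_in,V_in Matrices with `spec$d` columns; `K_in` and `V_in`
#'   must have the same number of rows.
#' @param weights `NULL` or list `Wq`, `Wk`, `Wv`, `Wo` (each `d x d`).
#' @param spec An [attention_spec()].
#' @return Matrix `nrow(Q_in) x spec$d`.
#' @export
scaled_dot_attention <- function(Q_in, K_in, V_in, weights = NULL, spec) {
  Q_in <- as.matrix(Q_in); K_in <- as.matrix(K_in); V_in <- as.matrix(V_in)
  for (nm in list(c("Q", ncol(Q_in)), c("K", ncol(K_in)), c("V", ncol(V_in))))
    if (as.integer(nm[2]) != spec$d)
      stop(sprintf("%s width %s does not match spec width %d", nm[1], nm[2], spec$d))
  if (nrow(K_in) != nrow(V_in)) stop("K and V must have the same number of rows")
  if (is.null(weights)) {
    Q <- Q_in; K <- K_in; V <- V_in
  } else {
    Q <- Q_in %*% weights$Wq; K <- K_in %*% weights$Wk; V <- V_in %*% weights$Wv
  }
  dk <- spec$d_k
  out <- matrix(0, nrow(Q), spec$d)
  for (h in seq_len(spec$heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    A <- softmax_rows(Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk))
    out[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  if (!is.null(weights)) out <- out %*% weights$Wo
  out
}

#' Attention weights (row-stochastic map) of one head
#'
#' Exposed for property checks: rows sum to one.
#' @inheritParams scaled_dot_attention
#' @return List of per-head attention matrices.
#' @export
attention_maps <- function(Q_in, K_in, weights = NULL, spec) {
  Q <- if (is.null(weights)) as.matrix(Q_in) else as.matrix(Q_in) %*% weights$Wq
  K <- if (is.null(weights)) as.matrix(K_in) else as.matrix(K_in) %*% weights$Wk
  dk <- spec$d_k
  lapply(seq_len(spec$heads), function(h) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    softmax_rows(Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk))
  })
}

# ---- initialization --------------------------------------------------------

# Scaled-uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in)),
# drawn from the current RNG stream (builders wrap in with_seed()).
init_mat <- function(nrow, ncol, fan_in) {
  lim <- 1 / sqrt(max(fan_in, 1))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# Conv biases start at zero (standard for rectified layers); with a large
# random bias a narrow scaled-down stage can be rectified into silence.
init_conv_weights <- function(spec) {
  fan <- spec$in_channels * prod(spec$kernel)
  list(W = init_mat(fan, spec$out_channels, fan),
       b = numeric(spec$out_channels))
}

init_rnn_weights <- function(spec) {
  list(W = init_mat(spec$hidden, spec$input, spec$input),
       U = init_mat(spec$hidden, spec$hidden, spec$hidden),
       b = stats::runif(spec$hidden, -1 / sqrt(spec$hidden), 1 / sqrt(spec$hidden)))
}

init_attention_weights <- function(spec) {
  d <- spec$d
  list(Wq = init_mat(d, d, d), Wk = init_mat(d, d, d),
       Wv = init_mat(d, d, d), Wo = init_mat(d, d, d))
}
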