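# Model assembly: configuration, parameter census (the reference layer-census
# conformance surface), seeded weight construction, and the forward passes of
# the four branches (MRI planes + time-elapsed attention, HPMRS, NMR,
# tumor-volume scalars) into the weighted binary classifier.

scale_width <- function(w, s) max(1L, as.integer(round(w * s)))

#' Model configuration
#'
#' Width-scale 1 reproduces every reference per-layer parameter count; a
#' smaller `width_scale` shrinks channel and embedding widths proportionally
#' (each kept integer >= 1) so the model trains on a desktop CPU in minutes.
#' The NMR recurrence is pinned at 9/9 (the panel width) and the volume
#' feature block at 3 regardless of scale.
#'
#' @param width_scale Width multiplier in (0, 1].
#' @param seed Seed for weight initialization.
#' @param heads Attention head count (default 2).
#' @return An object of class `tefuse_config` holding every layer spec.
#' @export
model_config <- function(width_scale = 1, seed = 1L, heads = 2L) {
  stopifnot(width_scale > 0, width_scale <= 1)
  s <- width_scale
  ch <- vapply(c(64L, 128L, 256L), scale_width, integer(1), s = s)
  d <- scale_width(256L, s)
  heads <- as.integer(heads)
  if (d %% heads != 0L) d <- d + (heads - d %% heads)   # keep heads divisible
  hp_ch <- vapply(c(8L, 16L), scale_width, integer(1), s = s)
  hp_hidden <- scale_width(128L, s)
  kernels <- list(c(2L, 3L, 3L), c(1L, 3L, 3L), c(1L, 3L, 3L))
  pools <- kernels
  plane_conv <- lapply(1:3, function(i)
    conv_spec(if (i == 1) 1L else ch[i - 1], ch[i], kernels[[i]], pools[[i]]))
  flat <- lapply(plane_shapes(), function(dm) {
    sh <- dm
    for (sp in plane_conv) sh <- conv_block_shape(sh, sp)$pool
    prod(sh) * ch[3]
  })
  hp_conv <- list(conv_spec(1L, hp_ch[1], c(3L, 3L), c(3L, 3L)),
                  conv_spec(hp_ch[1], hp_ch[2], c(3L, 3L), c(3L, 3L)))
  hp_sh <- hpmrs_shape()
  for (sp in hp_conv) hp_sh <- conv_block_shape(hp_sh, sp)$pool
  structure(list(
    width_scale = s, seed = as.integer(seed),
    plane_conv = plane_conv,
    plane_rnn = lapply(flat, function(f) rnn_spec(f, d)),
    attn = attention_spec(d, heads),
    hp_conv = hp_conv,
    hp_width = hp_sh[2],                       # spectral-time width after pooling
    hp_rnn = rnn_spec(hp_sh[2], hp_hidden),
    nmr_rnn = rnn_spec(9L, 9L),
    vol_width = 3L,
    d = d,
    fused_width = 9L * d,                      # three 3-unit blocks of width 3d
    head_hidden = 3L * d,
    head2_in = 3L * d + hp_hidden + 9L + 3L
  ), class = "tefuse_config")
}

# Block role orders: the anchor plane attends to itself first, then to the
# two other planes in the fixed block-internal order.
block_orders <- function() list(
  c("axial", "coronal", "sagittal"),
  c("coronal", "axial", "sagittal"),
  c("sagittal", "coronal", "axial"))

#' Per-layer parameter census
#'
#' Closed-form trainable parameter counts for every layer of the configured
#' model, the conformance surface against the reference layer census.
#'
#' @param config A [model_config()].
#' @return Data frame with columns `layer` and `params`.
#' @export
model_census <- function(config) {
  cs <- list()
  for (pl in names(plane_shapes()))
    for (i in 1:3)
      cs[[sprintf("%s_3d_encoder_%d", pl, i)]] <- count_parameters(config$plane_conv[[i]])
  for (pl in names(plane_shapes()))
    cs[[sprintf("%s_rnn", pl)]] <- count_parameters(config$plane_rnn[[pl]])
  for (i in 1:2)
    cs[[sprintf("hpmrs_2d_encoder_%d", i)]] <- count_parameters(config$hp_conv[[i]])
  for (b in 1:3) {
    ord <- block_orders()[[b]]
    for (u in seq_along(ord))
      cs[[sprintf("block%d_%s_attention", b, ord[u])]] <- count_parameters(config$attn)
    cs[[sprintf("time_elapsed_attention_%d", b)]] <- 3L * count_parameters(config$attn)
  }
  cs[["classification_1"]] <- config$head_hidden * (config$fused_width + 1L)
  cs[["hp_rnn"]] <- count_parameters(config$hp_rnn)
  cs[["nmr_rnn"]] <- count_parameters(config$nmr_rnn)
  cs[["classification_2"]] <- 2L * (config$head2_in + 1L)
  data.frame(layer = names(cs), params = as.integer(unname(unlist(cs))),
             stringsAsFactors = FALSE)
}

#' Reference encoder shape chain
#'
#' The conv / pool output shapes of each plane encoder stage and of the two
#' HPMRS stages, reported channel-first (channels, spatial dims...) to align
#' with the reference layer census.
#'
#' @param config A [model_config()].
#' @return Nested list: `plane$<name>` and `hpmrs`, each a list of stages
#'   with `conv` and `pool` integer vectors.
#' @export
model_shapes <- function(config) {
  planes <- lapply(plane_shapes(), function(dm) {
    sh <- dm
    out <- list()
    for (i in seq_along(config$plane_conv)) {
      sp <- config$plane_conv[[i]]
      st <- conv_block_shape(sh, sp)
      out[[i]] <- list(conv = c(sp$out_channels, st$conv),
                       pool = c(sp$out_channels, st$pool))
      sh <- st$pool
    }
    out
  })
  hp <- list(); sh <- hpmrs_shape()
  for (i in seq_along(config$hp_conv)) {
    sp <- config$hp_conv[[i]]
    st <- conv_block_shape(sh, sp)
    hp[[i]] <- list(conv = c(sp$out_channels, st$conv),
                    pool = c(sp$out_channels, st$pool))
    sh <- st$pool
  }
  list(plane = planes, hpmrs = hp)
}

#' Build the model
#'
#' Allocates every weight tensor with seeded scaled-uniform fan-in
#' initialization and attaches the parameter census. The classifier head is
#' the only part updated during training; the encoders, recurrences and
#' attention projections act as fixed random features (see the methods
#' vignette for the rationale).
#'
#' @param config A [model_config()].
#' @return An object of class `tefuse_model`.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "tefuse_config"))
  weights <- with_seed(config$seed, {
    planes <- names(plane_shapes())
    list(
      plane_conv = stats::setNames(lapply(planes, function(pl)
        lapply(config$plane_conv, init_conv_weights)), planes),
      plane_rnn = stats::setNames(lapply(planes, function(pl)
        init_rnn_weights(config$plane_rnn[[pl]])), planes),
      attn = lapply(1:3, function(b)
        lapply(1:3, function(u) init_attention_weights(config$attn))),
      hp_conv = lapply(config$hp_conv, init_conv_weights),
      hp_rnn = init_rnn_weights(config$hp_rnn),
      nmr_rnn = init_rnn_weights(config$nmr_rnn),
      head = init_head_weights(config)
    )
  })
  structure(list(config = config, weights = weights,
                 census = model_census(config)),
            class = "tefuse_model")
}

init_head_weights <- function(config) {
  list(W1 = init_mat(config$head_hidden, config$fused_width, config$fused_width),
       b1 = numeric(config$head_hidden),
       W2 = init_mat(2L, config$head2_in, config$head2_in),
       b2 = numeric(2L))
}

#' @export
print.tefuse_model <- function(x, ...) {
  cat(sprintf("tefuse model (width scale %.3g): %d layers, %s parameters\n",
              x$config$width_scale, nrow(x$census),
              format(sum(x$census$params), big.mark = ",")))
  invisible(x)
}

# ---- branch forward passes -------------------------------------------------

#' Encode one plane volume into its per-day feature vector
#'
#' Three stacked convolution/ReLU/max-pool blocks, then flattening of the
#' final map.
#'
#' @param volume Array with the plane's [plane_shapes()] geometry.
#' @param model A [build_model()] result.
#' @param plane `"sagittal"`, `"axial"` or `"coronal"`.
#' @return Numeric feature vector (flattened final map).
#' @export
plane_encoder <- function(volume, model, plane = c("sagittal", "axial", "coronal")) {
  plane <- match.arg(plane)
  expect <- plane_shapes()[[plane]]
  if (!identical(dim(volume), expect))
    stop(sprintf("%s volume must have shape (%s)", plane,
                 paste(expect, collapse = ",")))
  x <- volume
  for (i in seq_along(model$config$plane_conv))
    x <- conv_block(x, model$weights$plane_conv[[plane]][[i]],
                    model$config$plane_conv[[i]])
  as.vector(x)
}

#' Aggregate per-day plane vectors into a plane representation matrix
#'
#' Elman recurrence over the day-ordered feature vectors; days flagged in
#' `day_mask` (missing scans) propagate the previous hidden state, so row
#' `t` depends only on observed days `<= t`.
#'
#' @param day_vectors Matrix, one row per day.
#' @param model A `tefuse_model`.
#' @param plane Plane name.
#' @param day_mask Logical per-day missingness flags.
#' @return Matrix `days x d` of hidden states.
#' @export
temporal_aggregate <- function(day_vectors, model, plane, day_mask = NULL) {
  elman_forward(day_vectors, model$weights$plane_rnn[[plane]],
                model$config$plane_rnn[[plane]], day_mask = day_mask)
}

#' Encode one dynamic HPMRS matrix
#'
#' Each stage input is centered (its mean subtracted) before convolution:
#' for the raw matrix this is standard spectroscopy baseline/DC-offset
#' removal, and between stages it acts as a lightweight normalization that
#' keeps the narrow (1-2 channel) scaled-down encoder responsive to spectral
#' structure instead of being silenced by a rectifier acting on a large
#' positive offset. Each centered input then passes through a
#' convolution/ReLU/max-pool block; a final mean over the output channels
#' yields the width-280 per-day representation consumed by the HPMRS
#' recurrence.
#'
#' @param spectrum Matrix with the [hpmrs_shape()] geometry.
#' @param model A `tefuse_model`.
#' @return Numeric vector of length `model$config$hp_width`.
#' @export
hpmrs_encoder <- function(spectrum, model) {
  if (!identical(dim(spectrum), hpmrs_shape()))
    stop(sprintf("spectrum must have shape (%s)",
                 paste(hpmrs_shape(), collapse = ",")))
  x <- spectrum
  for (i in seq_along(model$config$hp_conv)) {
    x <- x - mean(x)
    x <- conv_block(x, model$weights$hp_conv[[i]], model$config$hp_conv[[i]])
  }
  # x is (1, width, channels): average over channels
  m <- apply(x, 2L, mean)
  as.vector(m)
}

#' Temporal aggregation of HPMRS day vectors
#'
#' @param day_vectors Matrix `days x hp_width`.
#' @param model A `tefuse_model`.
#' @param day_mask Logical per-day missingness flags.
#' @return Final hidden state (length `hp_rnn$hidden`).
#' @export
hp_temporal <- function(day_vectors, model, day_mask = NULL) {
  H <- elman_forward(day_vectors, model$weights$hp_rnn, model$config$hp_rnn,
                     day_mask = day_mask)
  H[nrow(H), ]
}

#' Temporal aggregation of NMR panels with entry masking
#'
#' Imputed-and-masked entries are zeroed before the input-to-hidden product,
#' so their numeric values cannot affect the output.
#'
#' @param panels Matrix `days x 9`.
#' @param model A `tefuse_model`.
#' @param entry_mask Logical matrix like `panels`, `TRUE` = masked.
#' @return Final hidden state (length 9).
#' @export
nmr_temporal <- function(panels, model, entry_mask = NULL) {
  H <- elman_forward(panels, model$weights$nmr_rnn, model$config$nmr_rnn,
                     input_mask = entry_mask)
  H[nrow(H), ]
}

#' One time-elapsed attention block
#'
#' The anchor plane (first entry of `role_order`) first attends to itself
#' (self-attention over days), then the self-attended anchor queries each of
#' the two other planes (cross-view attention). The last-day row of each of
#' the three attended matrices is taken as its temporal summary; the three
#' summaries are concatenated and rectified.
#'
#' @param plane_mats Named list of plane representation matrices
#'   (`axial`, `coronal`, `sagittal`), same day grid.
#' @param model A `tefuse_model`.
#' @param block Block index 1-3 (selects weights and role order).
#' @param role_order Optional explicit role order (anchor first).
#' @return Numeric vector of width `3 * d`.
#' @export
time_elapsed_block <- function(plane_mats, model, block,
                               role_order = block_orders()[[block]]) {
  D <- unique(vapply(plane_mats, nrow, integer(1)))
  if (length(D) != 1L) stop("plane matrices must share one day grid")
  spec <- model$config$attn
  w <- model$weights$attn[[block]]
  anchor <- plane_mats[[role_order[1]]]
  self_att <- scaled_dot_attention(anchor, anchor, anchor, w[[1]], spec)
  cross1 <- scaled_dot_attention(self_att, plane_mats[[role_order[2]]],
                                 plane_mats[[role_order[2]]], w[[2]], spec)
  cross2 <- scaled_dot_attention(self_att, plane_mats[[role_order[3]]],
                                 plane_mats[[role_order[3]]], w[[3]], spec)
  v <- c(self_att[D, ], cross1[D, ], cross2[D, ])
  pmax(v, 0)
}

#' Fuse the three attention blocks
#'
#' Plain concatenation of the three block outputs (width `9 * d`; 2304 at
#' width-scale 1).
#'
#' @param blocks List of exactly three block vectors.
#' @return Numeric vector of width `3 * length(blocks[[1]])`.
#' @export
fuse_views <- function(blocks) {
  if (length(blocks) != 3L) stop("exactly three block outputs are required")
  w <- unique(lengths(blocks))
  if (length(w) != 1L) stop("block outputs must share one width")
  unlist(blocks, use.names = FALSE)
}

#' Classifier forward pass
#'
#' Layer 1: affine `9d -> 3d` on the fused MRI representation, then ReLU.
#' Layer 2: affine on the concatenation of the rectified hidden vector with
#' the HPMRS, NMR and tumor-volume representations, giving two logits and
#' softmax probabilities.
#'
#' @param fused,hp,nmr,vol Branch representations with the configured widths.
#' @param head Head weights (`W1`, `b1`, `W2`, `b2`), e.g.
#'   `model$weights$head` or a trained head.
#' @param config A `tefuse_config`.
#' @return Named numeric vector `c(negative =, positive =)` summing to 1.
#' @export
fuse_and_classify <- function(fused, hp, nmr, vol, head, config) {
  if (length(fused) != config$fused_width)
    stop(sprintf("fused width %d, expected %d", length(fused), config$fused_width))
  if (length(hp) != config$hp_rnn$hidden || length(nmr) != 9L || length(vol) != 3L)
    stop("branch representation width mismatch")
  h <- pmax(drop(head$W1 %*% fused) + head$b1, 0)
  z <- drop(head$W2 %*% c(h, hp, nmr, vol)) + head$b2
  p <- drop(softmax_rows(matrix(z, 1)))
  stats::setNames(p, c("negative", "positive"))
}

#' Weighted binary cross-entropy
#'
#' `l = -w * (y log x + (1 - y) log(1 - x))`, with the predicted probability
#' clamped to `[1e-7, 1 - 1e-7]` for numerical stability.
#'
#' @param x Predicted positive-class probability in `[0, 1]`.
#' @param y True binary label (0/1).
#' @param w Positive scalar weight.
#' @return Loss value(s).
#' @export
weighted_bce <- function(x, y, w = 1) {
  if (any(w <= 0)) stop("'w' must be > 0")
  stopifnot(all(x >= 0 & x <= 1), all(y %in% c(0, 1)))
  x <- pmin(pmax(x, 1e-7), 1 - 1e-7)
  -w * (y * log(x) + (1 - y) * log(1 - x))
}
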