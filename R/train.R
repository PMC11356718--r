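# Classifier-head training. The encoders, recurrences and attention
# projections stay at their seeded random initialization (random-feature
# regime); the two classification layers are trained per fold by full-batch
# Adam on the class-weighted cross-entropy, with per-column standardization
# of the input features learned on the training fold.

#' Training control parameters
#'
#' @param lr Adam learning rate.
#' @param epochs Full-batch gradient steps.
#' @param weight_decay L2 penalty on the head weights.
#' @param seed Seed for head initialization.
#' @return List of class `train_control`.
#' @export
train_control <- function(lr = 0.01, epochs = 300L, weight_decay = 1e-3,
                          seed = 1L) {
  structure(list(lr = lr, epochs = as.integer(epochs),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_control")
}

# Column standardization helpers (constant columns pass through).
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv)
}
apply_scaler <- function(X, sc) sweep(sweep(X, 2L, sc$mu, "-"), 2L, sc$sd, "/")

#' Fit the classifier head on a feature matrix
#'
#' Trains layer 1 (`fused -> hidden`, ReLU) and layer 2 (concatenated
#' representations `-> 2` logits, softmax) by full-batch Adam on the
#' weighted cross-entropy; the positive-class weight is the inverse positive
#' prevalence of the training set, negatives weigh 1.
#'
#' @param X Feature matrix from [model_features()].
#' @param y Binary labels (0/1).
#' @param config A `tefuse_config`.
#' @param control A [train_control()].
#' @return Object of class `tefuse_head` (weights + scaler + pos weight).
#' @export
fit_head <- function(X, y, config, control = train_control()) {
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  blocks <- attr(X, "blocks")
  nf <- blocks[["fused"]]
  sc <- fit_scaler(X)
  Xs <- apply_scaler(X, sc)
  n <- nrow(Xs)
  w_pos <- n / max(sum(y == 1), 1)
  w <- ifelse(y == 1, w_pos, 1)
  H1 <- config$head_hidden
  pars <- with_seed(control$seed, list(
    W1 = init_mat(H1, nf, nf), b1 = numeric(H1),
    W2 = init_mat(2L, config$head2_in, config$head2_in), b2 = numeric(2L)))
  m <- lapply(pars, function(p) p * 0)
  v <- lapply(pars, function(p) p * 0)
  b1t <- 1; b2t <- 1
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  Xf <- Xs[, seq_len(nf), drop = FALSE]
  Xrest <- Xs[, -seq_len(nf), drop = FALSE]
  Y <- cbind(1 - y, y)                      # one-hot (negative, positive)
  for (it in seq_len(control$epochs)) {
    A1 <- Xf %*% t(pars$W1)
    A1 <- sweep(A1, 2L, pars$b1, "+")
    H <- pmax(A1, 0)
    Z2in <- cbind(H, Xrest)
    L <- Z2in %*% t(pars$W2)
    L <- sweep(L, 2L, pars$b2, "+")
    P <- softmax_rows(L)
    # d loss / d logits for weighted CE, averaged over samples
    G <- (P - Y) * w / n
    g <- list(W2 = t(G) %*% Z2in + control$weight_decay * pars$W2,
              b2 = colSums(G))
    dH <- G %*% pars$W2[, seq_len(H1), drop = FALSE]
    dA1 <- dH * (A1 > 0)
    g$W1 <- t(dA1) %*% Xf + control$weight_decay * pars$W1
    g$b1 <- colSums(dA1)
    b1t <- b1t * beta1; b2t <- b2t * beta2
    for (nm in names(pars)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
      pars[[nm]] <- pars[[nm]] - control$lr *
        (m[[nm]] / (1 - b1t)) / (sqrt(v[[nm]] / (1 - b2t)) + eps)
    }
  }
  structure(list(W1 = pars$W1, b1 = pars$b1, W2 = pars$W2, b2 = pars$b2,
                 scaler = sc, n_fused = nf, w_pos = w_pos),
            class = "tefuse_head")
}

#' Predict positive-class probabilities with a trained head
#'
#' @param head A [fit_head()] result.
#' @param X Feature matrix with the same layout as at fit time.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict_head <- function(head, X) {
  Xs <- apply_scaler(X, head$scaler)
  nf <- head$n_fused
  H <- pmax(sweep(Xs[, seq_len(nf), drop = FALSE] %*% t(head$W1), 2L, head$b1, "+"), 0)
  L <- sweep(cbind(H, Xs[, -seq_len(nf), drop = FALSE]) %*% t(head$W2), 2L, head$b2, "+")
  P <- softmax_rows(L)
  unname(P[, 2L])
}
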