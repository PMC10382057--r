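# Fully connected neural network: five hidden layers (50, 40, 30, 20, 10),
# ReLU activations, a single sigmoid output trained with binary
# cross-entropy and Adam (lr 1e-3, beta 0.9/0.999), full-batch, with early
# stopping on validation loss. Written directly on matrix operations; the
# problems here are tiny (tens to hundreds of rows, <= a few hundred
# inputs), so full-batch gradients are exact and fast.

fcnn_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(l) {
    fan_in <- sizes[l]
    list(
      W = matrix(rnorm(fan_in * sizes[l + 1], 0, sqrt(2 / fan_in)),
        fan_in, sizes[l + 1]),
      b = rep(0, sizes[l + 1])
    )
  })
}

fcnn_forward <- function(params, X) {
  acts <- list(X)
  nl <- length(params)
  for (l in seq_len(nl)) {
    z <- sweep(acts[[l]] %*% params[[l]]$W, 2, params[[l]]$b, `+`)
    acts[[l + 1]] <- if (l < nl) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  acts
}

fcnn_bce <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

fcnn_gradients <- function(params, acts, y) {
  nl <- length(params)
  n <- length(y)
  grads <- vector("list", nl)
  # output layer: sigmoid + BCE gives delta = (p - y) / n
  delta <- (acts[[nl + 1]] - matrix(y, ncol = 1)) / n
  for (l in rev(seq_len(nl))) {
    grads[[l]] <- list(
      W = crossprod(acts[[l]], delta),
      b = colSums(delta)
    )
    if (l > 1) {
      delta <- tcrossprod(delta, params[[l]]$W) * (acts[[l]] > 0)
    }
  }
  grads
}

#' Train the five-layer fully connected classifier
#'
#' @param X Numeric matrix or data frame of normalized, reduced features.
#' @param y Binary labels.
#' @param seed Integer seed controlling initialization (training is
#'   deterministic given the seed and data).
#' @param X_val,y_val Optional validation set for early stopping; when
#'   absent the full epoch budget is used.
#' @param hidden Hidden-layer sizes.
#' @param epochs Epoch budget.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); best-epoch weights are restored.
#' @param lr Adam learning rate.
#' @return An `fcnn_model`; `predict()` returns sigmoid scores in (0, 1).
#' @export
train_fcnn <- function(X, y, seed = 1L, X_val = NULL, y_val = NULL,
                       hidden = c(50, 40, 30, 20, 10), epochs = 200,
                       patience = 20, lr = 1e-3) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) rlang::abort("X must be finite")
  y <- as_binary_labels(y)
  sizes <- c(ncol(X), hidden, 1)
  params <- with_seed(seed, fcnn_init(sizes))
  mstate <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  vstate <- mstate
  b1 <- 0.9
  b2 <- 0.999
  eps <- 1e-8
  has_val <- !is.null(X_val) && !is.null(y_val)
  if (has_val) {
    X_val <- as.matrix(X_val)
    y_val <- as_binary_labels(y_val)
  }
  best <- list(loss = Inf, params = params, epoch = 0)
  stall <- 0
  t_adam <- 0
  for (epoch in seq_len(epochs)) {
    acts <- fcnn_forward(params, X)
    if (!all(is.finite(acts[[length(acts)]]))) {
      rlang::abort(sprintf("training diverged at epoch %d", epoch))
    }
    grads <- fcnn_gradients(params, acts, y)
    t_adam <- t_adam + 1
    for (l in seq_along(params)) {
      for (slot in c("W", "b")) {
        g <- grads[[l]][[slot]]
        mstate[[l]][[slot]] <- b1 * mstate[[l]][[slot]] + (1 - b1) * g
        vstate[[l]][[slot]] <- b2 * vstate[[l]][[slot]] + (1 - b2) * g^2
        mhat <- mstate[[l]][[slot]] / (1 - b1^t_adam)
        vhat <- vstate[[l]][[slot]] / (1 - b2^t_adam)
        params[[l]][[slot]] <- params[[l]][[slot]] -
          lr * mhat / (sqrt(vhat) + eps)
      }
    }
    if (has_val) {
      val_p <- fcnn_forward(params, X_val)[[length(sizes)]]
      val_loss <- fcnn_bce(val_p, y_val)
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= patience) break
      }
    }
  }
  final <- if (has_val) best$params else params
  structure(
    list(params = final, features = colnames(X), seed = seed,
      best_epoch = if (has_val) best$epoch else epochs,
      val_loss = if (has_val) best$loss else NA_real_),
    class = "fcnn_model"
  )
}

#' @export
predict.fcnn_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features %||% colnames(newdata),
    drop = FALSE])
  as.numeric(fcnn_forward(object$params, X)[[length(object$params) + 1]])
}
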