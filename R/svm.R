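# Linear support vector machine, effectively unregularized.
#
# The decision function f(x) = w.x + b minimizes the L2-slack (squared
# hinge) SVM objective with a negligible ridge term:
#   lambda * |w|^2 + (1/n) sum_i max(0, 1 - y_i f(x_i))^2
# With lambda -> 0 this approximates the hard-margin solution on separable
# data (the minimum-norm zero-loss solution is the max-margin one) and a
# pure slack-minimizing hyperplane otherwise. The objective is convex and
# piecewise quadratic, so damped Newton converges in a handful of exact
# steps, which keeps the 125 fits per experiment fast and deterministic.

#' Train a linear SVM
#'
#' @param X Numeric matrix or data frame (rows = samples), already
#'   normalized and reduced.
#' @param y Binary labels; the positive class is scored high.
#' @param lambda Ridge weight on `|w|^2` (kept tiny to approximate an
#'   unregularized margin classifier).
#' @return A `linear_svm` object with weights `w`, offset `b`.
#' @export
train_linear_svm <- function(X, y, lambda = 1e-6) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) rlang::abort("X must be finite")
  yy <- 2 * as_binary_labels(y) - 1
  if (length(unique(yy)) < 2) rlang::abort("both classes must be present")
  n <- nrow(X)
  p <- ncol(X)
  # damped Newton on the piecewise-quadratic objective: the active set of
  # margin violators stabilizes after a few iterations
  Xa <- cbind(X, 1)
  theta <- rep(0, p + 1)
  reg <- c(rep(2 * lambda, p), 1e-10) # ridge on w only; tiny jitter on b
  converged <- FALSE
  f_old <- Inf
  for (it in 1:100) {
    f <- as.numeric(Xa %*% theta)
    m <- pmax(0, 1 - yy * f)
    obj <- lambda * sum(theta[seq_len(p)]^2) + mean(m^2)
    g <- reg * theta - (2 / n) * as.numeric(crossprod(Xa, m * yy))
    if (max(abs(g)) < 1e-10 || abs(f_old - obj) < 1e-14 * (1 + obj)) {
      converged <- TRUE
      break
    }
    f_old <- obj
    act <- m > 0
    H <- (2 / n) * crossprod(Xa[act, , drop = FALSE])
    diag(H) <- diag(H) + reg + 1e-12
    step <- tryCatch(solve(H, -g), error = function(e) -g)
    # backtracking line search keeps the damped Newton step monotone
    t_ls <- 1
    repeat {
      theta_new <- theta + t_ls * step
      m_new <- pmax(0, 1 - yy * as.numeric(Xa %*% theta_new))
      obj_new <- lambda * sum(theta_new[seq_len(p)]^2) + mean(m_new^2)
      if (obj_new <= obj + 1e-4 * t_ls * sum(g * step) || t_ls < 1e-8) break
      t_ls <- t_ls / 2
    }
    theta <- theta_new
  }
  structure(
    list(w = unname(theta[seq_len(p)]), b = unname(theta[p + 1]),
      features = colnames(X), converged = converged),
    class = "linear_svm"
  )
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features %||% colnames(newdata),
    drop = FALSE])
  as.numeric(X %*% object$w + object$b)
}
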