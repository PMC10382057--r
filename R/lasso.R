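# LASSO-based feature selection at a relaxed penalty: the largest lambda
# on the regularization path whose active set exceeds a feature-count
# target (over one hundred by default).

#' LASSO feature selection with a feature-count target
#'
#' Fits an L1-penalized least-squares regression of the +/-1 labels on the
#' normalized features along a decreasing lambda path (100 log-spaced
#' values from `lambda_max` down to `1e-3 * lambda_max`, coordinate
#' descent via glmnet) and selects the largest lambda whose active set
#' exceeds `target_min` features.
#'
#' @param X Numeric matrix or data frame of normalized features.
#' @param y Binary labels (converted internally to -1/+1).
#' @param target_min Minimum active-set size to exceed.
#' @return A `reduction_result` with `features`, absolute-coefficient
#'   `scores`, the chosen `lambda`, and the full `path` (lambda,
#'   active-set size).
#' @export
lasso_select <- function(X, y, target_min = 100) {
  X <- as.matrix(X)
  if (anyNA(X)) rlang::abort("X must not contain missing values")
  yy <- 2 * as_binary_labels(y) - 1
  if (length(unique(yy)) < 2) rlang::abort("both classes must be present")
  fit <- glmnet::glmnet(X, yy, family = "gaussian", alpha = 1,
    nlambda = 100, lambda.min.ratio = 1e-3, standardize = FALSE,
    intercept = TRUE, thresh = 1e-10)
  df <- fit$df
  lambda <- fit$lambda
  idx <- which(df > target_min)
  if (!length(idx)) {
    if (ncol(X) <= target_min) {
      rlang::warn(sprintf(
        "only %d features available (<= target %d); returning all",
        ncol(X), target_min))
    } else {
      rlang::warn("path never exceeded the target; returning largest active set")
    }
    idx <- which.max(df)
  } else {
    idx <- idx[1] # largest lambda exceeding the target
  }
  beta <- as.numeric(fit$beta[, idx])
  active <- which(beta != 0)
  if (!length(active)) active <- seq_len(ncol(X))
  ord <- active[order(-abs(beta[active]), active)]
  structure(
    list(
      method = "lasso",
      features = colnames(X)[ord],
      scores = abs(beta[ord]),
      lambda = lambda[idx],
      path = tibble::tibble(lambda = lambda, n_active = df),
      params = list(target_min = target_min)
    ),
    class = "reduction_result"
  )
}

# Active set at a single fixed lambda (used for closed-form verification
# on orthonormal designs).
lasso_active_set <- function(X, y, lambda) {
  X <- as.matrix(X)
  yy <- 2 * as_binary_labels(y) - 1
  fit <- glmnet::glmnet(X, yy, family = "gaussian", alpha = 1,
    standardize = FALSE, intercept = FALSE, thresh = 1e-12,
    lambda = c(lambda * 2, lambda))
  beta <- as.numeric(fit$beta[, 2])
  which(beta != 0)
}
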