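# ReliefF feature weighting: rewards features that agree between nearest
# same-class neighbors (hits) and differ between nearest other-class
# neighbors (misses).

#' ReliefF feature selection
#'
#' Deterministic ReliefF over all rows: for every row, the `k` nearest
#' hits and `k` nearest misses (Euclidean distance over the supplied,
#' already-normalized features) update each feature weight by
#' `+ sum(|x - miss|) / (m k) - sum(|x - hit|) / (m k)`. The top
#' `n_select` features by weight are returned, ties broken by column
#' (inventory) order.
#'
#' @param X Numeric matrix or data frame of normalized features (rows =
#'   tumors).
#' @param y Binary labels (logical, 0/1, or two-level factor).
#' @param k_neighbors Neighbors per class (reduced with a warning when a
#'   class is too small).
#' @param n_select Number of features to keep.
#' @return A `reduction_result`: list with `method`, `features` (ordered
#'   selected names), `scores` (their weights), `weights` (all features),
#'   and `params`.
#' @export
relieff <- function(X, y, k_neighbors = 10, n_select = 32) {
  X <- as.matrix(X)
  if (anyNA(X)) rlang::abort("X must not contain missing values")
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2) rlang::abort("both classes must be present")
  n <- nrow(X)
  k_max <- min(table(y)) - 1L
  k <- k_neighbors
  if (k > k_max) {
    rlang::warn(sprintf("k_neighbors reduced from %d to %d (small class)",
      k, k_max))
    k <- max(k_max, 1L)
  }
  D <- as.matrix(stats::dist(X))
  w <- numeric(ncol(X))
  for (i in seq_len(n)) {
    same <- which(y == y[i])
    same <- same[same != i]
    diff_ <- which(y != y[i])
    hits <- same[order(D[i, same], same)][seq_len(min(k, length(same)))]
    misses <- diff_[order(D[i, diff_], diff_)][seq_len(min(k, length(diff_)))]
    if (length(hits)) {
      w <- w - colSums(abs(X[hits, , drop = FALSE] -
        matrix(X[i, ], length(hits), ncol(X), byrow = TRUE))) /
        (n * length(hits))
    }
    if (length(misses)) {
      w <- w + colSums(abs(X[misses, , drop = FALSE] -
        matrix(X[i, ], length(misses), ncol(X), byrow = TRUE))) /
        (n * length(misses))
    }
  }
  names(w) <- colnames(X)
  n_select <- min(n_select, ncol(X))
  ord <- order(-w, seq_along(w))
  sel <- ord[seq_len(n_select)]
  structure(
    list(
      method = "relieff",
      features = colnames(X)[sel],
      scores = unname(w[sel]),
      weights = w,
      params = list(k_neighbors = k, n_select = n_select)
    ),
    class = "reduction_result"
  )
}

as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) rlang::abort("labels must be binary")
  as.integer(y)
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("<reduction_result: %s, %d features>\n", x$method,
    length(x$features)))
  cat("top features:", paste(head(x$features, 5), collapse = ", "), "...\n")
  invisible(x)
}

#' Restrict a feature table to a frozen selection
#'
#' Test rows are reduced by name lookup only; no labels are consulted.
#'
#' @param result A `reduction_result`.
#' @param data Tibble with the feature columns.
#' @return `data` with only the selected feature columns (order preserved).
#' @export
apply_reduction <- function(result, data) {
  missing <- setdiff(result$features, names(data))
  if (length(missing)) {
    rlang::abort(paste0("selected features absent from data: ",
      toString(head(missing, 5))))
  }
  data[, result$features, drop = FALSE]
}
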