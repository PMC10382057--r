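# Z-score normalization fitted on the combined train + validation rows and
# frozen for the test rows.

#' Fit z-score normalization parameters
#'
#' @param data Tibble or data frame of feature columns (plus optional id
#'   columns, ignored via `feature_cols`).
#' @param feature_cols Character vector of feature column names; defaults
#'   to all numeric columns.
#' @return A `zscore_params` tibble with `feature`, `mean`, `sd`,
#'   `zero_sd`.
#' @export
zscore_fit <- function(data, feature_cols = NULL) {
  if (nrow(data) < 2) rlang::abort("need at least 2 rows to fit z-scores")
  feature_cols <- feature_cols %||%
    names(data)[vapply(data, is.numeric, logical(1))]
  mu <- unname(vapply(feature_cols, function(f) mean(data[[f]]), numeric(1)))
  sdev <- unname(vapply(feature_cols, function(f) sd(data[[f]]), numeric(1)))
  out <- tibble::tibble(
    feature = feature_cols, mean = mu, sd = sdev,
    zero_sd = !is.finite(sdev) | sdev <= 0
  )
  class(out) <- c("zscore_params", class(out))
  out
}

#' Apply frozen z-score parameters
#'
#' Features with zero training standard deviation map to 0 (they carry no
#' information on the fitting population).
#'
#' @param params A `zscore_params` object from [zscore_fit()].
#' @param data Rows to normalize (train, validation, or test).
#' @return `data` with the parameterized columns standardized.
#' @export
zscore_apply <- function(params, data) {
  for (k in seq_len(nrow(params))) {
    f <- params$feature[k]
    if (params$zero_sd[k]) {
      data[[f]] <- rep(0, nrow(data))
    } else {
      data[[f]] <- (data[[f]] - params$mean[k]) / params$sd[k]
    }
  }
  data
}
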