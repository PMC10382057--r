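# broom-style tidiers for fitted experiment objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-fold results of an experiment
#'
#' @param x A `radiomics_experiment`.
#' @param ... Unused.
#' @return One row per test fold: `fold`, `n_test`, `test_auc`,
#'   `best_split`, `best_val_auc`, `n_selected`, plus identifying columns.
#' @method tidy radiomics_experiment
#' @export
tidy.radiomics_experiment <- function(x, ...) {
  x$folds %>%
    dplyr::mutate(
      task = x$task,
      combo = pretty_combo(x$contrasts),
      methodology = pretty_method(x$reduction, x$classifier),
      .before = 1
    )
}

#' One-row summary of an experiment
#'
#' @param x A `radiomics_experiment`.
#' @param ... Unused.
#' @return A single row with the task, contrast combination, methodology,
#'   mean test and validation AUCs, fold count, tumor count, and the
#'   number of candidate models trained.
#' @method glance radiomics_experiment
#' @export
glance.radiomics_experiment <- function(x, ...) {
  tibble::tibble(
    task = x$task,
    combo = pretty_combo(x$contrasts),
    methodology = pretty_method(x$reduction, x$classifier),
    mean_test_auc = x$mean_test_auc,
    mean_val_auc = x$mean_val_auc,
    n_folds = nrow(x$folds),
    n_tumors = x$n_tumors,
    n_trainings = x$n_trainings
  )
}
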