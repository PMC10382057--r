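# AUROC and report tables: results across contrast
# combinations, selected-feature category summaries, selection stability,
# and the leakage audit.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic divided by `n_pos * n_neg`;
#' tied scores contribute 1/2. Exactly the probability that a random
#' positive outranks a random negative.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (!all(is.finite(scores))) rlang::abort("scores must be finite")
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("both classes must be present to compute AUC")
  }
  r <- rank(scores) # average ranks handle ties as 1/2
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

combo_levels <- function() {
  c("DCE", "Sub", "T2", "DCE+Sub", "DCE+T2", "Sub+T2", "DCE+Sub+T2")
}

pretty_combo <- function(contrasts) {
  map <- c(dce = "DCE", sub = "Sub", t2 = "T2")
  paste(map[contrasts], collapse = "+")
}

pretty_method <- function(reduction, classifier) {
  paste(
    c(relieff = "ReliefF", lasso = "LASSO")[reduction],
    c(svm = "SVM", fcnn = "FCNN")[classifier],
    sep = " + "
  )
}

#' Result table across contrast combinations
#'
#' Reshapes a grid of experiments into the standard layout: rows = task x
#' methodology, one column per contrast combination (DCE, Sub, T2 and
#' their unions), cells = mean AUC over the five test folds (or the mean
#' best-validation AUC).
#'
#' @param grid Output of [run_experiment_grid()].
#' @param metric `"test"` or `"validation"`.
#' @return A tibble mirroring the standard result-table layout.
#' @export
result_table <- function(grid, metric = c("test", "validation")) {
  metric <- match.arg(metric)
  value_col <- if (metric == "test") "mean_test_auc" else "mean_val_auc"
  tbl <- grid %>%
    dplyr::mutate(
      combo_pretty = purrr::map_chr(.data$contrasts, pretty_combo),
      methodology = pretty_method(.data$reduction, .data$classifier)
    ) %>%
    dplyr::select("task", "methodology", "combo_pretty",
      value = dplyr::all_of(value_col)) %>%
    dplyr::mutate(value = round(.data$value, 2)) %>%
    tidyr::pivot_wider(names_from = "combo_pretty",
      values_from = "value")
  keep <- intersect(combo_levels(), names(tbl))
  tbl[, c("task", "methodology", keep)]
}

#' Category summary of selected features
#'
#' Counts the features retained by the reduction in each inventory
#' category, per fold. Counts always sum to the selection size (32 for
#' ReliefF; the active-set size for LASSO).
#'
#' @param experiment A `radiomics_experiment`.
#' @param inventory Feature inventory.
#' @return Tibble `fold`, `category`, `n`.
#' @export
category_summary <- function(experiment, inventory = feature_inventory()) {
  lookup <- setNames(inventory$category, inventory$name)
  purrr::imap_dfr(experiment$selections, function(red, fold) {
    if (is.null(red)) return(NULL)
    cats <- lookup[strip_contrast_prefix(red$features)]
    tibble::tibble(fold = as.integer(fold)) %>%
      tidyr::expand_grid(category = unique(inventory$category)) %>%
      dplyr::left_join(
        tibble::tibble(category = cats) %>% dplyr::count(.data$category),
        by = "category"
      ) %>%
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  })
}

#' Selection stability across folds
#'
#' Frequency with which each feature was selected across the fold-wise
#' reductions, and the fraction of ever-selected features retained in at
#' least `ceiling(0.8 * n_folds)` folds.
#'
#' @param experiment A `radiomics_experiment`.
#' @return Tibble `feature`, `frequency`, with the summary fraction as
#'   attribute `stable_fraction`.
#' @export
feature_stability <- function(experiment) {
  sels <- purrr::compact(experiment$selections)
  if (length(sels) < 2) rlang::abort("need selections from >= 2 folds")
  all_feats <- unlist(purrr::map(sels, "features"))
  freq <- table(all_feats) / length(sels)
  out <- tibble::tibble(
    feature = names(freq),
    frequency = as.numeric(freq)
  ) %>% dplyr::arrange(dplyr::desc(.data$frequency), .data$feature)
  thresh <- ceiling(0.8 * length(sels)) / length(sels)
  attr(out, "stable_fraction") <- mean(out$frequency >= thresh)
  out
}

#' Audit an experiment for train/test leakage
#'
#' Recomputes, from the stored fold plan structures, that no patient
#' appears in more than one of train/validation/test for any split, and
#' that every patient's tumors share a fold.
#'
#' @param plan A [make_fold_plan()].
#' @param cohort The cohort the plan was built for.
#' @return Tibble `check`, `n_violations`; all zeros in a sound setup.
#' @export
audit_leakage <- function(plan, cohort) {
  fold_of <- setNames(plan$folds$fold, plan$folds$patient_id)
  # every tumor's patient mapped to exactly one fold
  tumor_folds <- cohort %>%
    dplyr::mutate(fold = fold_of[.data$patient_id]) %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::summarise(n_folds = dplyr::n_distinct(.data$fold))
  v1 <- sum(tumor_folds$n_folds != 1)
  # split roles disjoint from the test fold and from each other
  v2 <- plan$splits %>%
    dplyr::mutate(in_test = fold_of[.data$patient_id] == .data$test_fold) %>%
    dplyr::summarise(n = sum(.data$in_test)) %>%
    dplyr::pull("n")
  v3 <- plan$splits %>%
    dplyr::group_by(.data$test_fold, .data$split, .data$patient_id) %>%
    dplyr::summarise(n_roles = dplyr::n_distinct(.data$role),
      .groups = "drop") %>%
    dplyr::summarise(n = sum(.data$n_roles != 1)) %>%
    dplyr::pull("n")
  tibble::tibble(
    check = c("patient in one fold", "train/val disjoint from test",
      "train disjoint from validation"),
    n_violations = c(v1, v2, v3)
  )
}
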