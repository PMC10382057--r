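# The full experimental protocol: per test fold, fit normalization and
# reduction on train+validation only, train 25 candidate models on seeded
# 75/25 resamples, keep the best on validation AUC, and evaluate it once
# on the held-out test fold; average over the 5 fold cycles.

task_column <- function(task) {
  switch(task,
    er = "er", pr = "pr", her2 = "her2", idc_ilc = "histotype",
    rlang::abort(paste0("unknown task: ", task))
  )
}

task_positive <- function(task) {
  # positive class scored high: ER+/PR+/HER2+ and ILC
  switch(task, er = "+", pr = "+", her2 = "+", idc_ilc = "ILC")
}

#' Assemble the design table for one task and contrast combination
#'
#' Joins per-contrast feature rows into one wide row per tumor (feature
#' names prefixed by contrast), attaches the binary task label, and drops
#' tumors with a missing label.
#'
#' @param features Feature tibble from [extract_cohort_features()].
#' @param cohort Cohort tibble with labels and `patient_id`.
#' @param task One of `"er"`, `"pr"`, `"her2"`, `"idc_ilc"`.
#' @param contrasts Character subset of `c("dce", "sub", "t2")`.
#' @return Tibble with `tumor_id`, `patient_id`, `y` (1 = positive class)
#'   and the prefixed feature columns.
#' @export
assemble_design <- function(features, cohort, task,
                            contrasts = c("dce", "sub", "t2")) {
  contrasts <- match.arg(contrasts, c("dce", "sub", "t2"),
    several.ok = TRUE)
  col <- task_column(task)
  pos <- task_positive(task)
  wide <- features %>%
    dplyr::filter(.data$contrast %in% contrasts) %>%
    tidyr::pivot_wider(
      id_cols = "tumor_id", names_from = "contrast",
      values_from = -dplyr::all_of(c("tumor_id", "contrast")),
      names_glue = "{contrast}_{.value}"
    )
  labels <- cohort %>%
    dplyr::select("tumor_id", "patient_id", label = dplyr::all_of(col)) %>%
    dplyr::filter(!is.na(.data$label))
  labels %>%
    dplyr::mutate(y = as.integer(.data$label == pos)) %>%
    dplyr::select(-"label") %>%
    dplyr::inner_join(wide, by = "tumor_id")
}

fit_one_model <- function(classifier, X_train, y_train, X_val, y_val,
                          seed, fcnn_epochs = 200, fcnn_patience = 20) {
  if (classifier == "svm") {
    train_linear_svm(X_train, y_train)
  } else {
    train_fcnn(X_train, y_train, seed = seed, X_val = X_val, y_val = y_val,
      epochs = fcnn_epochs, patience = fcnn_patience)
  }
}

#' Run one experiment under the fold/resample protocol
#'
#' For each of the `n_folds` test folds: z-score normalization and the
#' dimension reduction are fitted on the train+validation tumors only and
#' frozen; `n_splits` candidate models are trained on seeded 75/25
#' patient-wise train/validation resamples; the candidate with the best
#' validation AUC (ties: lowest split index) is evaluated once on the test
#' fold. Patient-wise disjointness of train/validation/test is asserted at
#' run time for every split.
#'
#' @param features Feature tibble from [extract_cohort_features()].
#' @param cohort Cohort tibble.
#' @param task,contrasts See [assemble_design()].
#' @param reduction `"relieff"` or `"lasso"`.
#' @param classifier `"svm"` or `"fcnn"`.
#' @param plan A [make_fold_plan()] for this cohort.
#' @param seed Seed stream for classifier initialization.
#' @param relieff_k,relieff_n,lasso_target Reduction parameters.
#' @param fcnn_epochs,fcnn_patience FCNN training budget and early-stopping
#'   patience.
#' @return A `radiomics_experiment` object; see [tidy.radiomics_experiment()].
#' @export
run_protocol <- function(features, cohort, task,
                         contrasts = c("dce", "sub", "t2"),
                         reduction = c("relieff", "lasso"),
                         classifier = c("svm", "fcnn"),
                         plan, seed = 1L,
                         relieff_k = 10, relieff_n = 32,
                         lasso_target = 100,
                         fcnn_epochs = 200, fcnn_patience = 20) {
  reduction <- match.arg(reduction)
  classifier <- match.arg(classifier)
  design <- assemble_design(features, cohort, task, contrasts)
  if (!nrow(design)) rlang::abort("no labeled tumors for this task")
  feature_cols <- setdiff(names(design), c("tumor_id", "patient_id", "y"))
  fold_of <- setNames(plan$folds$fold, plan$folds$patient_id)

  fold_rows <- list()
  selections <- list()
  fit_populations <- list()
  val_auc_mat <- matrix(NA_real_, plan$n_folds, plan$n_splits)
  n_trainings <- 0L
  for (tf in seq_len(plan$n_folds)) {
    is_test <- fold_of[design$patient_id] == tf
    trainval <- design[!is_test, , drop = FALSE]
    test <- design[is_test, , drop = FALSE]
    if (nrow(trainval) < 4 || length(unique(trainval$y)) < 2) {
      fold_rows[[tf]] <- tibble::tibble(
        fold = tf, n_test = nrow(test), test_auc = NA_real_,
        best_split = NA_integer_, best_val_auc = NA_real_,
        n_selected = NA_integer_
      )
      next
    }
    stopifnot(length(intersect(trainval$patient_id, test$patient_id)) == 0)

    params <- zscore_fit(trainval, feature_cols)
    trainval_z <- zscore_apply(params, trainval)
    red <- suppressWarnings(if (reduction == "relieff") {
      relieff(trainval_z[, feature_cols], trainval_z$y,
        k_neighbors = relieff_k, n_select = relieff_n)
    } else {
      lasso_select(trainval_z[, feature_cols], trainval_z$y,
        target_min = lasso_target)
    })

    splits <- plan$splits[plan$splits$test_fold == tf, , drop = FALSE]
    best <- list(split = NA_integer_, val_auc = -Inf, model = NULL)
    for (s in seq_len(plan$n_splits)) {
      sp <- splits[splits$split == s, , drop = FALSE]
      train_pat <- sp$patient_id[sp$role == "train"]
      val_pat <- sp$patient_id[sp$role == "validation"]
      stopifnot(
        length(intersect(train_pat, val_pat)) == 0,
        length(intersect(c(train_pat, val_pat), test$patient_id)) == 0
      )
      tr <- trainval_z[trainval_z$patient_id %in% train_pat, , drop = FALSE]
      va <- trainval_z[trainval_z$patient_id %in% val_pat, , drop = FALSE]
      if (length(unique(tr$y)) < 2 || nrow(va) == 0) next
      X_tr <- apply_reduction(red, tr)
      X_va <- apply_reduction(red, va)
      model <- fit_one_model(classifier, X_tr, tr$y, X_va, va$y,
        seed = child_seed(seed, tf * 100L + s),
        fcnn_epochs = fcnn_epochs, fcnn_patience = fcnn_patience)
      n_trainings <- n_trainings + 1L
      if (length(unique(va$y)) < 2) next
      v_auc <- auc(predict(model, X_va), va$y)
      val_auc_mat[tf, s] <- v_auc
      if (v_auc > best$val_auc) {
        best <- list(split = s, val_auc = v_auc, model = model)
      }
    }
    test_auc <- NA_real_
    if (!is.null(best$model) && nrow(test) > 0 &&
        length(unique(test$y)) >= 2) {
      X_te <- apply_reduction(red, zscore_apply(params, test))
      test_auc <- auc(predict(best$model, X_te), test$y)
    } else if (nrow(test) > 0 && length(unique(test$y)) < 2) {
      rlang::warn(sprintf(
        "fold %d: single-class test labels; AUC undefined, excluded", tf))
    }
    selections[[tf]] <- red
    fit_populations[[tf]] <- list(
      fit_patients = unique(trainval$patient_id),
      test_patients = unique(test$patient_id)
    )
    fold_rows[[tf]] <- tibble::tibble(
      fold = tf, n_test = nrow(test), test_auc = test_auc,
      best_split = best$split,
      best_val_auc = if (is.finite(best$val_auc)) best$val_auc else NA_real_,
      n_selected = length(red$features)
    )
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  structure(
    list(
      task = task,
      contrasts = contrasts,
      reduction = reduction,
      classifier = classifier,
      folds = folds_tbl,
      mean_test_auc = mean(folds_tbl$test_auc, na.rm = TRUE),
      mean_val_auc = mean(folds_tbl$best_val_auc, na.rm = TRUE),
      val_auc = val_auc_mat,
      selections = selections,
      fit_populations = fit_populations,
      n_trainings = n_trainings,
      seed = as.integer(seed),
      plan_seed = plan$seed,
      n_tumors = nrow(design)
    ),
    class = "radiomics_experiment"
  )
}

#' @export
print.radiomics_experiment <- function(x, ...) {
  cat(sprintf(
    "<radiomics_experiment: %s | %s | %s + %s>\n", x$task,
    paste(x$contrasts, collapse = "+"), x$reduction, x$classifier))
  cat(sprintf("  mean test AUC over %d folds: %.3f (val %.3f), %d tumors\n",
    nrow(x$folds), x$mean_test_auc, x$mean_val_auc, x$n_tumors))
  invisible(x)
}

#' Run a grid of experiments
#'
#' @param features,cohort,plan,seed As in [run_protocol()].
#' @param tasks Tasks to run.
#' @param contrast_sets List of contrast combinations (character vectors).
#' @param methods Tibble with columns `reduction`, `classifier`; defaults
#'   to all four combinations.
#' @param ... Passed to [run_protocol()].
#' @return A tibble with one row per experiment and a list-column
#'   `result` of `radiomics_experiment` objects.
#' @export
run_experiment_grid <- function(features, cohort, plan,
                                tasks = c("er", "pr", "her2", "idc_ilc"),
                                contrast_sets = list("dce", "sub", "t2",
                                  c("dce", "sub"), c("dce", "t2"),
                                  c("sub", "t2"), c("dce", "sub", "t2")),
                                methods = tidyr::expand_grid(
                                  reduction = c("relieff", "lasso"),
                                  classifier = c("fcnn", "svm")),
                                seed = 1L, ...) {
  grid <- tidyr::expand_grid(
    task = tasks,
    combo = purrr::map_chr(contrast_sets, paste, collapse = "+"),
    methods
  ) %>%
    dplyr::mutate(contrasts = rep(contrast_sets,
      each = nrow(methods), times = length(tasks)))
  grid$result <- purrr::pmap(
    list(grid$task, grid$contrasts, grid$reduction, grid$classifier,
      seq_len(nrow(grid))),
    function(task, contrasts, reduction, classifier, i) {
      run_protocol(features, cohort, task, contrasts, reduction,
        classifier, plan, seed = child_seed(seed, i), ...)
    }
  )
  grid %>%
    dplyr::mutate(
      mean_test_auc = purrr::map_dbl(.data$result, "mean_test_auc"),
      mean_val_auc = purrr::map_dbl(.data$result, "mean_val_auc")
    )
}
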