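# Patient-wise fold plan: 5 folds partitioning patients (all of a
# patient's tumors share a fold), and for each choice of test fold, 25
# seeded 75/25 train/validation splits of the remaining patients.

#' Build the patient-wise fold plan
#'
#' @param cohort Cohort tibble with `patient_id`.
#' @param n_folds Number of folds (the protocol default is 5).
#' @param n_splits Train/validation resamples per test fold (default 25).
#' @param seed Integer seed; the plan is a pure function of the inputs.
#' @param train_frac Fraction of train+validation patients assigned to
#'   train in each split (by patient count, +/- 1).
#' @return A `fold_plan`: list with `folds` (tibble `patient_id`, `fold`)
#'   and `splits` (tibble `test_fold`, `split`, `patient_id`, `role`).
#' @export
make_fold_plan <- function(cohort, n_folds = 5, n_splits = 25, seed = 1L,
                           train_frac = 0.75) {
  patients <- sort(unique(cohort$patient_id))
  if (length(patients) < n_folds) {
    rlang::abort("fewer patients than folds")
  }
  folds <- with_seed(seed, {
    shuffled <- sample(patients)
    tibble::tibble(
      patient_id = shuffled,
      fold = rep(seq_len(n_folds), length.out = length(shuffled))
    ) %>% dplyr::arrange(.data$patient_id)
  })
  splits <- purrr::map_dfr(seq_len(n_folds), function(tf) {
    rest <- folds$patient_id[folds$fold != tf]
    purrr::map_dfr(seq_len(n_splits), function(s) {
      sseed <- child_seed(seed, tf * 1000L + s)
      with_seed(sseed, {
        shuffled <- sample(rest)
        n_train <- round(train_frac * length(rest))
        tibble::tibble(
          test_fold = tf, split = s, patient_id = shuffled,
          role = c(rep("train", n_train),
            rep("validation", length(rest) - n_train))
        )
      })
    })
  })
  structure(
    list(folds = folds, splits = splits, n_folds = n_folds,
      n_splits = n_splits, seed = as.integer(seed)),
    class = "fold_plan"
  )
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan: %d patients, %d folds x %d splits, seed %d>\n",
    nrow(x$folds), x$n_folds, x$n_splits, x$seed))
  invisible(x)
}
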