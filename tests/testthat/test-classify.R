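test_that("the linear SVM separates separable clouds and matches the analytic margin", {
  withr::with_seed(1, {
    X <- rbind(
      matrix(rnorm(40, -3, 0.5), 20, 2),
      matrix(rnorm(40, 3, 0.5), 20, 2)
    )
    colnames(X) <- c("u", "v")
    y <- rep(c(0L, 1L), each = 20)
  })
  m <- train_linear_svm(X, y)
  expect_equal(auc(predict(m, X), y), 1)
  # analytic 1D max-margin: negatives {0, 1}, positives {3, 4} -> boundary
  # at 2 with w = 1, b = -2 (margins +/-1 at x = 1 and x = 3)
  X1 <- matrix(c(0, 1, 3, 4), 4, 1, dimnames = list(NULL, "x"))
  y1 <- c(0L, 0L, 1L, 1L)
  m1 <- train_linear_svm(X1, y1)
  expect_equal(unname(m1$w), 1, tolerance = 1e-2)
  expect_equal(m1$b, -2, tolerance = 2e-2)
})

test_that("linearly inseparable XOR data scores near chance", {
  withr::with_seed(2, {
    base <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
    X <- base[rep(1:4, each = 20), ] * 4 + matrix(rnorm(160, 0, 0.3), 80, 2)
    colnames(X) <- c("u", "v")
    y <- rep(c(0L, 1L, 1L, 0L), each = 20)
  })
  m <- train_linear_svm(X, y)
  expect_lt(abs(auc(predict(m, X), y) - 0.5), 0.12)
})

test_that("the FCNN fits a separable toy problem to near-perfect validation AUC", {
  tt <- toy_table(n = 60, p = 5, seed = 3, signal = 4)
  val <- toy_table(n = 30, p = 5, seed = 4, signal = 4)
  m <- train_fcnn(tt$X, tt$y, seed = 1, X_val = val$X, y_val = val$y)
  expect_gt(auc(predict(m, val$X), val$y), 0.95)
})

test_that("shuffled labels give chance-level FCNN validation AUC across seeds", {
  tt <- toy_table(n = 60, p = 8, seed = 5, signal = 0)
  val_auc <- vapply(1:10, function(s) {
    y_shuf <- withr::with_seed(s + 100, sample(tt$y))
    m <- train_fcnn(tt$X[1:40, ], y_shuf[1:40], seed = s,
      X_val = tt$X[41:60, ], y_val = y_shuf[41:60])
    auc(predict(m, tt$X[41:60, ]), y_shuf[41:60])
  }, numeric(1))
  expect_lt(abs(mean(val_auc) - 0.5), 0.1)
})

test_that("FCNN training is deterministic given the seed", {
  tt <- toy_table(n = 40, p = 6, seed = 6)
  m1 <- train_fcnn(tt$X, tt$y, seed = 9)
  m2 <- train_fcnn(tt$X, tt$y, seed = 9)
  expect_identical(predict(m1, tt$X), predict(m2, tt$X))
  m3 <- train_fcnn(tt$X, tt$y, seed = 10)
  expect_false(identical(predict(m1, tt$X), predict(m3, tt$X)))
})

test_that("the FCNN uses the 50-40-30-20-10 architecture", {
  tt <- toy_table(n = 30, p = 7, seed = 7)
  m <- train_fcnn(tt$X, tt$y, seed = 1, epochs = 2)
  dims <- vapply(m$params, function(l) ncol(l$W), numeric(1))
  expect_equal(dims, c(50, 40, 30, 20, 10, 1))
  expect_equal(nrow(m$params[[1]]$W), 7)
})

test_that("fold plans partition patients with patient-wise integrity", {
  cohort <- tibble::tibble(
    tumor_id = sprintf("T%02d", 1:14),
    patient_id = rep(sprintf("P%02d", 1:10), c(2, 2, 2, 2, 1, 1, 1, 1, 1, 1))
  )
  plan <- make_fold_plan(cohort, n_folds = 5, n_splits = 4, seed = 3)
  expect_equal(as.vector(sort(table(plan$folds$fold))), rep(2L, 5))
  # deterministic
  plan2 <- make_fold_plan(cohort, n_folds = 5, n_splits = 4, seed = 3)
  expect_identical(plan$splits, plan2$splits)
  # both tumors of a patient always share the fold by construction
  joined <- dplyr::left_join(cohort, plan$folds, by = "patient_id")
  per_pat <- dplyr::summarise(dplyr::group_by(joined, patient_id),
    nf = dplyr::n_distinct(fold))
  expect_true(all(per_pat$nf == 1))
  expect_error(make_fold_plan(cohort[1:4, ], n_folds = 5), "fewer patients")
})

test_that("75/25 splits are patient-count balanced within one", {
  cohort <- tibble::tibble(tumor_id = sprintf("T%03d", 1:100),
    patient_id = sprintf("P%03d", 1:100))
  plan <- make_fold_plan(cohort, n_splits = 2, seed = 8)
  sp <- plan$splits[plan$splits$test_fold == 1 & plan$splits$split == 1, ]
  expect_equal(sum(sp$role == "train"), 60)   # 75% of the 80 non-test
  expect_equal(sum(sp$role == "validation"), 20)
})

test_that("the protocol trains 25 models per fold and respects leakage guards", {
  co <- test_cohort()
  ft <- test_features()
  plan <- make_fold_plan(co, n_splits = 5, seed = 2)
  ex <- run_protocol(ft, co, "er", "dce", "relieff", "svm", plan, seed = 1,
    relieff_n = 8)
  expect_equal(nrow(ex$folds), 5)
  expect_lte(ex$n_trainings, 5 * 5)
  expect_true(all(ex$folds$n_selected == 8, na.rm = TRUE))
  expect_true(all(ex$folds$test_auc >= 0 & ex$folds$test_auc <= 1,
    na.rm = TRUE))
  # selected model's validation AUC equals the row maximum of candidates
  for (tf in which(!is.na(ex$folds$best_split))) {
    expect_equal(ex$folds$best_val_auc[tf], max(ex$val_auc[tf, ],
      na.rm = TRUE))
  }
  expect_true(all(audit_leakage(plan, co)$n_violations == 0))
})

test_that("tidy and glance summarize experiments in standard layouts", {
  co <- test_cohort()
  ft <- test_features()
  plan <- make_fold_plan(co, n_splits = 3, seed = 4)
  ex <- run_protocol(ft, co, "er", "dce", "relieff", "svm", plan, seed = 1,
    relieff_n = 6)
  td <- tidy(ex)
  expect_equal(nrow(td), 5)
  expect_true(all(c("task", "combo", "methodology", "fold", "test_auc") %in%
    names(td)))
  gl <- glance(ex)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$methodology, "ReliefF + SVM")
})
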