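# ReliefF against a hand-enumerated oracle; LASSO against the orthonormal
# soft-threshold closed form.

test_that("ReliefF weights equal the hand-enumerated update on an 8-row table", {
  withr::with_seed(10, {
    X <- matrix(rnorm(8 * 3), 8, 3)
    colnames(X) <- c("a", "b", "c")
    y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  })
  res <- relieff(X, y, k_neighbors = 2, n_select = 3)
  expect_equal(unname(res$weights), oracle_relieff(X, y, 2),
    tolerance = 1e-12)
})

test_that("a perfectly separating feature ranks first among noise", {
  withr::with_seed(4, {
    y <- rep(c(0L, 1L), each = 15)
    X <- cbind(sep = y * 4 + rnorm(30, 0, 0.05),
      matrix(rnorm(30 * 9), 30, 9))
    colnames(X) <- c("sep", paste0("n", 1:9))
  })
  res <- relieff(X, y, k_neighbors = 5, n_select = 3)
  expect_equal(res$features[1], "sep")
})

test_that("permutation-null ReliefF weights center on zero", {
  withr::with_seed(6, {
    X <- matrix(rnorm(24 * 4), 24, 4)
    colnames(X) <- paste0("f", 1:4)
    y <- rep(c(0L, 1L), 12)
    w_bar <- rowMeans(replicate(100, {
      relieff(X, sample(y), k_neighbors = 3, n_select = 4)$weights
    }))
  })
  expect_true(all(abs(w_bar) < 0.05))
})

test_that("ReliefF selection size and tie-breaking are deterministic", {
  tt <- toy_table(n = 30, p = 40, seed = 2)
  r1 <- relieff(tt$X, tt$y, n_select = 12)
  r2 <- relieff(tt$X, tt$y, n_select = 12)
  expect_identical(r1$features, r2$features)
  expect_length(r1$features, 12)
  expect_warning(relieff(tt$X[1:6, ], tt$y[1:6], k_neighbors = 10),
    "reduced")
})

test_that("no active features survive above the closed-form lambda_max", {
  tt <- toy_table(n = 50, p = 10, seed = 3)
  y_pm <- 2 * tt$y - 1
  Xc <- scale(tt$X, scale = FALSE)
  lambda_max <- max(abs(crossprod(Xc, y_pm - mean(y_pm)))) / nrow(Xc)
  act <- phantomics:::lasso_active_set(Xc, tt$y, lambda_max * 1.01)
  expect_length(act, 0)
})

test_that("orthonormal designs reproduce the soft-threshold active set", {
  withr::with_seed(12, {
    n <- 64
    p <- 16
    Q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))[, 1:p] * sqrt(n)
    colnames(Q) <- paste0("q", 1:p)
    y <- rbinom(n, 1, 0.5)
  })
  y_pm <- 2 * y - 1
  corr <- abs(crossprod(Q, y_pm)) / n # X'y / n for columns with X'X = n I
  for (lam in quantile(corr, c(0.25, 0.6, 0.9))) {
    expected <- which(corr > lam)
    got <- phantomics:::lasso_active_set(Q, y, lam)
    expect_setequal(got, expected)
  }
})

test_that("the relaxed penalty retains over one hundred features", {
  # the relaxed-penalty rule operates on clinical-scale folds where the
  # row count comfortably exceeds the 100-feature target
  withr::with_seed(13, {
    n <- 160
    p <- 342
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- sprintf("v%03d", 1:p)
    y <- rbinom(n, 1, 0.5)
  })
  res <- lasso_select(X, y, target_min = 100)
  expect_gt(length(res$features), 100)
  expect_lte(length(res$features), p)
  expect_true(all(res$scores > 0))
  # the chosen lambda is the path's first crossing of the target, and the
  # active-set size grows (overall) as lambda decreases
  path <- res$path
  i <- which(path$lambda == res$lambda)
  expect_gt(path$n_active[i], 100)
  expect_true(all(path$n_active[seq_len(i - 1)] <= 100))
  expect_lt(stats::cor(path$lambda, path$n_active, method = "spearman"), -0.9)
})

test_that("small feature sets fall back to all features with a warning", {
  tt <- toy_table(n = 40, p = 8, seed = 5)
  expect_warning(res <- lasso_select(tt$X, tt$y, target_min = 100),
    "returning all")
  expect_length(res$features, 8)
})

test_that("frozen selections apply to new rows by name only", {
  tt <- toy_table(n = 30, p = 20, seed = 6)
  res <- relieff(tt$X, tt$y, n_select = 5)
  newdata <- tibble::as_tibble(as.data.frame(tt$X[1:3, ]))
  out <- apply_reduction(res, newdata)
  expect_equal(names(out), res$features)
  expect_error(apply_reduction(res, newdata[, 1:2]), "absent")
})
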