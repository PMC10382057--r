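# Shared small phantom cohort, generated once per test session and cached,
# so several test files can exercise cohort-level behavior cheaply.

.test_cache <- new.env(parent = emptyenv())

test_cohort <- function() {
  if (is.null(.test_cache$cohort)) {
    dir <- file.path(tempdir(), "phantomics-test-cohort")
    cohort <- generate_cohort(14, dir, profile = class_effect_profile(),
      seed = 20260920L)
    .test_cache$cohort <- apply_exclusions(cohort)
  }
  .test_cache$cohort
}

test_features <- function() {
  if (is.null(.test_cache$features)) {
    .test_cache$features <- extract_cohort_features(test_cohort())
  }
  .test_cache$features
}

# A tiny labeled feature table for reduction/classifier tests.
toy_table <- function(n = 40, p = 12, seed = 1, signal = 2) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + signal * y
    colnames(X) <- sprintf("f%02d", seq_len(p))
    list(X = X, y = y)
  })
}
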