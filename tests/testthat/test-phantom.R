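test_that("spec validation enforces the geometric and intensity invariants", {
  expect_error(phantom_spec(shape_irregularity = 1.5), "irregularity")
  expect_error(phantom_spec(noise_sd = c(dce = -1, t1 = 1, t2 = 1)), ">= 0")
  expect_error(phantom_spec(tumor_level = c(dce = 90, t1 = 100, t2 = 160)),
    "exceed")
  expect_error(
    generate_tumor_mask(phantom_spec(tumor_size_mm = 200), 1),
    "cannot fit"
  )
})

test_that("masks are deterministic, connected, and size-calibrated", {
  spec <- phantom_spec(tumor_size_mm = 20, shape_irregularity = 0.4)
  m1 <- generate_tumor_mask(spec, 9)
  m2 <- generate_tumor_mask(spec, 9)
  expect_identical(as.vector(m1), as.vector(m2))
  expect_lt(abs(tumor_size_mm(m1) - 20) / 20, 0.1)
  # connectivity: one 26-connected component
  q <- array(0L, dim = dim(m1))
  q[m1] <- 1L
  zones <- phantomics:::cpp_zones(as.integer(q), as.integer(dim(q)), FALSE)
  expect_equal(nrow(zones), 1)
})

test_that("an unperturbed ellipsoid at fine spacing hits its target size", {
  spec <- phantom_spec(grid_shape = c(40, 40, 40), spacing_mm = c(1, 1, 1),
    tumor_size_mm = 20, shape_irregularity = 0, t2_grid = NULL)
  for (seed in c(1, 5)) {
    m <- generate_tumor_mask(spec, seed)
    expect_lt(abs(tumor_size_mm(m) - 20), 2)
  }
})

test_that("a 4 mm target yields a sub-5 mm mask that the exclusion rule drops", {
  spec <- phantom_spec(tumor_size_mm = 4)
  m <- generate_tumor_mask(spec, 3)
  expect_lt(tumor_size_mm(m), 5)
})

test_that("volume sets are deterministic with the expected structure", {
  spec <- phantom_spec()
  m <- generate_tumor_mask(spec, 5)
  v1 <- generate_volume_set(m, spec, seed = 6)
  v2 <- generate_volume_set(m, spec, seed = 6)
  expect_identical(v1$dce, v2$dce)
  expect_identical(v1$t2, v2$t2)
  expect_setequal(names(v1), c("dce", "sub", "t2"))
  expect_true(all(v1$sub >= 0)) # clipped subtraction
  # lesions enhance on DCE
  expect_gt(mean(v1$dce[m]), mean(v1$dce[!m]) + 30)
})

test_that("the noiseless infinite-granularity limit is exactly flat", {
  spec <- phantom_spec(
    noise_sd = c(dce = 0, t1 = 0, t2 = 0),
    texture_granularity_mm = 1e9, t2_grid = NULL
  )
  m <- generate_tumor_mask(spec, 2)
  v <- generate_volume_set(m, spec, seed = 3)
  expect_equal(unname(diff(range(v$dce[m]))), 0)
  expect_equal(unname(mean(v$dce[m])), unname(spec$tumor_level[["dce"]]))
})

test_that("class effects shift only positive-class tumors and vanish at zero effect", {
  spec <- phantom_spec()
  prof <- er_texture_profile(granularity_delta = 3)
  pos <- phantomics:::apply_class_effects(spec, prof,
    list(er = "+", pr = "-", her2 = "-", histotype = "IDC"))
  neg <- phantomics:::apply_class_effects(spec, prof,
    list(er = "-", pr = "-", her2 = "-", histotype = "IDC"))
  expect_equal(pos$texture_granularity_mm[["dce"]],
    spec$texture_granularity_mm[["dce"]] + 3)
  expect_identical(neg, spec)
  null <- phantomics:::apply_class_effects(spec, null_profile(),
    list(er = "+", pr = "+", her2 = "+", histotype = "ILC"))
  expect_identical(null, spec)
})

test_that("cohort generation is byte-reproducible and obeys the size law", {
  dir1 <- file.path(tempdir(), "coh-a")
  dir2 <- file.path(tempdir(), "coh-b")
  c1 <- generate_cohort(12, dir1, seed = 77)
  c2 <- generate_cohort(12, dir2, seed = 77)
  expect_identical(
    readLines(file.path(dir1, "cohort.csv")),
    readLines(file.path(dir2, "cohort.csv"))
  )
  expect_true(all(file.exists(c1$dce_path)))
  expect_false(anyDuplicated(c1$tumor_id) > 0)
  # patients may own two tumors; all label cells equal within a patient
  per_pat <- dplyr::count(c1, patient_id)
  expect_true(all(per_pat$n %in% 1:2))
})

test_that("the log-normal size law matches the clinical summary at scale", {
  # Monte-Carlo of the fitted law itself (no imaging): mean 24.6, med 20.3
  withr::with_seed(99, {
    meds <- replicate(200, median(rlnorm(429, log(20.3),
      sqrt(2 * log(24.6 / 20.3)))))
  })
  expect_true(all(meds > 17 & meds < 24))
  # realized cohort sizes follow the law (truncation aside)
  dir <- file.path(tempdir(), "coh-ks")
  co <- generate_cohort(40, dir, seed = 123)
  ks <- suppressWarnings(stats::ks.test(co$size_mm,
    function(qq) stats::plnorm(qq, log(20.3), sqrt(2 * log(24.6 / 20.3)))))
  expect_lt(unname(ks$statistic), 0.15)
})

test_that("tumor multiplicity reproduces the 429-from-323 cohort scale", {
  # simulate the per-patient tumor-count law at the clinical cohort size
  counts <- vapply(1:3, function(s) {
    n <- 0L
    for (i in 1:323) {
      ps <- phantomics:::child_seed(s, i)
      n <- n + withr::with_seed(ps, {
        runif(4)
        1L + rbinom(1L, 1L, 0.33)
      })
    }
    n
  }, integer(1))
  expect_true(all(abs(counts - 429) / 429 < 0.05))
})

test_that("label missingness appears at roughly the configured rate", {
  dir <- file.path(tempdir(), "coh-miss")
  co <- generate_cohort(60, dir, seed = 5, missing_frac = 0.15)
  miss_rate <- mean(is.na(c(co$er, co$pr, co$her2, co$histotype)))
  expect_gt(miss_rate, 0.05)
  expect_lt(miss_rate, 0.30)
})

test_that("cohort CSV round-trips through read_cohort", {
  co <- test_cohort()
  dir <- dirname(co$dce_path[1])
  back <- read_cohort(file.path(dir, "cohort.csv"))
  expect_equal(nrow(back) >= nrow(co), TRUE)
  expect_true(all(file.exists(back$mask_path)))
})
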