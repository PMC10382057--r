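digital_ball <- function(r_vox, grid, spacing = 1) {
  ctr <- (grid + 1) / 2
  g <- expand.grid(x = 1:grid, y = 1:grid, z = 1:grid)
  inside <- (g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= r_vox^2
  phantomics:::set_spacing(array(inside, dim = rep(grid, 3)),
    rep(spacing, 3))
}

test_that("a digital ball has near-analytic volume and near-unit sphericity", {
  m <- digital_ball(10, 25)
  v <- array(1, dim = dim(m))
  f <- shape_intensity_features(v, m)
  expect_lt(abs(f[["conv_volume_mm3"]] - 4 / 3 * pi * 1000) /
    (4 / 3 * pi * 1000), 0.05)
  expect_lt(abs(f[["conv_sphericity"]] - 1), 0.08)
  expect_lt(abs(f[["conv_max_diameter_mm"]] - 20) / 20, 0.1)
  expect_equal(unname(f[["conv_bbox_extent_x"]]), 21)
  # ball: elongation and flatness near 1
  expect_gt(f[["conv_elongation"]], 0.95)
  expect_gt(f[["conv_flatness"]], 0.95)
})

test_that("sphericity approaches 1 from below as resolution increases", {
  s <- vapply(c(5, 10, 16), function(r) {
    m <- digital_ball(r, 2 * r + 5)
    shape_intensity_features(array(1, dim(m)), m)[["conv_sphericity"]]
  }, numeric(1))
  expect_lt(abs(s[3] - 1), abs(s[1] - 1) + 0.02)
  expect_lt(s[3], 1.06)
})

test_that("intensity shifts leave dispersion and shape statistics unchanged", {
  withr::with_seed(3, {
    v <- array(rnorm(13^3, 50, 12), dim = c(13, 13, 13))
  })
  m <- digital_ball(5, 13)
  f1 <- shape_intensity_features(v, m)
  f2 <- shape_intensity_features(v + 37.5, m)
  for (nm in c("conv_sd", "conv_skewness", "conv_kurtosis", "conv_iqr",
    "conv_range", "conv_mad")) {
    expect_equal(f1[[nm]], f2[[nm]], tolerance = 1e-10)
  }
  expect_equal(f2[["conv_mean"]], f1[["conv_mean"]] + 37.5)
})

test_that("skewness and kurtosis match direct moment formulas on 27 voxels", {
  vals <- c(
    3, 7, 1, 9, 4, 4, 6, 2, 8, 5, 5, 7, 3, 9, 1, 2, 6, 8, 4, 7, 5, 3, 6, 2,
    9, 1, 30
  )
  v <- array(vals, dim = c(3, 3, 3))
  m <- phantomics:::set_spacing(array(TRUE, dim = c(3, 3, 3)), c(1, 1, 1))
  f <- shape_intensity_features(v, m)
  mu <- mean(vals)
  m2 <- mean((vals - mu)^2)
  expect_equal(unname(f[["conv_skewness"]]), mean((vals - mu)^3) / m2^1.5)
  expect_equal(unname(f[["conv_kurtosis"]]), mean((vals - mu)^4) / m2^2)
  expect_equal(unname(f[["conv_energy"]]), sum(vals^2))
  expect_equal(unname(f[["conv_rms"]]), sqrt(mean(vals^2)))
})

test_that("moment invariants are invariant to translation and axis permutation", {
  withr::with_seed(8, {
    base <- generate_tumor_mask(phantom_spec(shape_irregularity = 0.5), 21)
  })
  sp <- c(2, 2, 2)
  f1 <- phantomics:::moment_features(base, sp)
  # translate by padding shift
  shifted <- array(FALSE, dim = dim(base) + c(4, 0, 0))
  shifted[5:(4 + dim(base)[1]), , ] <- base
  f2 <- phantomics:::moment_features(shifted, sp)
  expect_equal(f1[c("mom_inv_j1", "mom_inv_j2", "mom_inv_j3")],
    f2[c("mom_inv_j1", "mom_inv_j2", "mom_inv_j3")], tolerance = 1e-10)
  # permute axes: invariants of the moment tensor are unchanged
  perm <- aperm(base, c(2, 3, 1))
  f3 <- phantomics:::moment_features(perm, sp)
  expect_equal(f1[c("mom_inv_j1", "mom_inv_j2", "mom_inv_j3", "mom_anisotropy")],
    f3[c("mom_inv_j1", "mom_inv_j2", "mom_inv_j3", "mom_anisotropy")],
    tolerance = 1e-10)
})

test_that("moment invariants are scale-invariant", {
  m1 <- digital_ball(5, 13)
  m2 <- digital_ball(10, 25)
  f1 <- phantomics:::moment_features(m1, c(1, 1, 1))
  f2 <- phantomics:::moment_features(m2, c(1, 1, 1))
  expect_equal(unname(f1["mom_inv_j1"]), unname(f2["mom_inv_j1"]),
    tolerance = 0.05)
})

test_that("Haar band energies concentrate in the low-pass band for smooth fields", {
  withr::with_seed(5, {
    sm <- phantomics:::gaussian_random_field(c(12, 12, 12), c(1, 1, 1), 4)
  })
  m <- phantomics:::set_spacing(array(TRUE, dim = c(12, 12, 12)), c(1, 1, 1))
  w <- phantomics:::wavelet_features(sm + 10, m,
    c("energy_frac", "mean_abs", "sd", "entropy"))
  fracs <- w[grep("_energy_frac$", names(w))]
  expect_equal(sum(fracs), 1, tolerance = 1e-10)
  expect_gt(w[["wav_lll_energy_frac"]], 0.9)
})
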