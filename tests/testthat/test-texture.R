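# Texture matrices against brute-force enumeration, and the scalar feature
# formulas on hand-checkable inputs.

glcm_features_of <- function(P) phantomics:::glcm_scalar_features(P)

test_that("texture matrices equal brute-force enumeration on random volumes", {
  for (seed in 1:4) {
    dims <- c(5, 6, 5)
    L <- 4
    q <- random_quantized(dims, L, seed)
    mats <- compute_texture_matrices(q, glcm_distances = c(1, 2),
      ngtdm_distances = c(1, 2))
    # the implementation crops to the mask bounding box; crop the oracle too
    idx <- arrayInd(which(q > 0), dims)
    rng <- lapply(1:3, function(a) range(idx[, a]))
    qc <- q[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
      rng[[3]][1]:rng[[3]][2], drop = FALSE]
    for (d in 1:2) {
      expect_equal(mats$glcm[[paste0("d", d)]], oracle_glcm(qc, L, d),
        tolerance = 1e-10)
      expect_equal(mats$ngtdm[[paste0("d", d)]], oracle_ngtdm(qc, L, d),
        tolerance = 1e-10)
    }
    off3 <- oracle_offsets_3d()
    expect_equal(
      unname(mats$glrlm[["3d"]][, seq_len(max(dim(qc)))]),
      unname(oracle_glrlm(qc, L, off3)[, seq_len(max(dim(qc)))])
    )
    off2 <- off3[off3[, 3] == 0, , drop = FALSE]
    expect_equal(
      unname(mats$glrlm[["2d"]][, seq_len(max(dim(qc)))]),
      unname(oracle_glrlm(qc, L, off2)[, seq_len(max(dim(qc)))])
    )
    z3 <- oracle_glszm(qc, L, planar = FALSE)
    expect_equal(unname(mats$glszm[["3d"]][, seq_len(ncol(z3))]), unname(z3))
    z2 <- oracle_glszm(qc, L, planar = TRUE)
    expect_equal(unname(mats$glszm[["2d"]][, seq_len(ncol(z2))]), unname(z2))
  }
})

test_that("a constant region gives a single-cell diagonal GLCM", {
  q <- array(1L, dim = c(4, 4, 4))
  attr(q, "levels") <- 8L
  mats <- compute_texture_matrices(q, glcm_distances = 1)
  P <- mats$glcm$d1
  expect_equal(P[1, 1], 1)
  expect_equal(sum(P), 1)
  f <- glcm_features_of(P)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["joint_energy"]], 1)
  expect_equal(f[["joint_entropy"]], 0)
  expect_equal(f[["inverse_difference"]], 1)
  expect_equal(f[["correlation"]], 0) # zero-variance limit
})

test_that("an alternating pattern along x puts GLCM mass off the diagonal", {
  q <- array(rep(c(1L, 2L), 8), dim = c(16, 1, 1))
  attr(q, "levels") <- 2L
  mats <- compute_texture_matrices(q, glcm_distances = 1)
  P <- mats$glcm$d1
  expect_equal(P[1, 1] + P[2, 2], 0)
  expect_equal(P[1, 2] + P[2, 1], 1)
})

test_that("GLCM features match hand arithmetic on a 3x3 matrix", {
  # hand-written symmetric normalized co-occurrence matrix
  P <- matrix(c(
    0.2, 0.1, 0.0,
    0.1, 0.3, 0.1,
    0.0, 0.1, 0.1
  ), 3, 3, byrow = TRUE)
  f <- glcm_features_of(P)
  # by hand: energy = sum of squares
  expect_equal(f[["joint_energy"]], 0.04 + 0.01 + 0 + 0.01 + 0.09 + 0.01 +
    0 + 0.01 + 0.01)
  # contrast = sum (i-j)^2 p = 1*(0.1+0.1+0.1+0.1) + 4*0
  expect_equal(f[["contrast"]], 0.4)
  # maximum probability and diagonal mass
  expect_equal(f[["maximum_probability"]], 0.3)
  expect_equal(f[["same_level_probability"]], 0.6)
  # marginals: px = (0.3, 0.5, 0.2); mu = 1.9
  expect_equal(f[["joint_average"]], 1.9)
  expect_equal(f[["autocorrelation"]],
    sum(outer(1:3, 1:3) * P))
  expect_equal(f[["joint_entropy"]],
    -sum(P[P > 0] * log2(P[P > 0])))
})

test_that("run-length features match hand counting on a tiny pattern", {
  # one row: 1 1 2 2 2 1 -> runs: (1,2) (2,3) (1,1) along x only
  q <- array(c(1L, 1L, 2L, 2L, 2L, 1L), dim = c(6, 1, 1))
  attr(q, "levels") <- 2L
  mats <- compute_texture_matrices(q)
  R <- mats$glrlm[["3d"]]
  # along x: runs (1,2), (2,3), (1,1); each of the other 12 directions sees
  # every voxel as a length-1 run (3 of level 1, 3 of level 2)
  expect_equal(R[1, 2], 1)
  expect_equal(R[2, 3], 1)
  expect_equal(R[1, 1], 1 + 12 * 3)
  expect_equal(R[2, 1], 12 * 3)
  expect_equal(sum(R), 3 + 12 * 6)
  f <- phantomics:::rl_scalar_features(R, mats$n_voxels, "glrlm")
  expect_equal(unname(f["rp"]), sum(R) / 6)
})

test_that("degenerate distributions take their documented limits", {
  empty <- matrix(0, 4, 3)
  f <- phantomics:::rl_scalar_features(empty, 10, "glszm")
  expect_true(all(f == 0))
  ng0 <- matrix(0, 4, 2)
  f2 <- phantomics:::ngtdm_scalar_features(ng0, 10)
  expect_true(all(f2 == 0))
  # constant region: single occupied level, no gray-tone differences
  q <- array(1L, dim = c(3, 3, 3))
  attr(q, "levels") <- 4L
  mats <- compute_texture_matrices(q, ngtdm_distances = 1)
  f3 <- phantomics:::ngtdm_scalar_features(mats$ngtdm$d1, mats$n_voxels)
  expect_equal(unname(f3["coarseness"]), 1e6) # zero-difference cap
  expect_equal(unname(f3["busyness"]), 0)
  expect_true(all(is.finite(f3)))
})

test_that("direction-aggregated texture features are invariant to axial 90-degree rotation", {
  withr::with_seed(42, {
    v <- array(rnorm(6 * 6 * 4), dim = c(6, 6, 4))
    m <- array(runif(144) < 0.85, dim = c(6, 6, 4))
  })
  rot <- function(a) {
    out <- array(0, dim = c(dim(a)[2], dim(a)[1], dim(a)[3]))
    for (z in seq_len(dim(a)[3])) out[, , z] <- t(a[dim(a)[1]:1, , z])
    out
  }
  q1 <- quantize(v, m, 4)
  q2 <- quantize(rot(v), rot(m) > 0, 4)
  m1 <- compute_texture_matrices(q1, glcm_distances = 1, ngtdm_distances = 1)
  m2 <- compute_texture_matrices(q2, glcm_distances = 1, ngtdm_distances = 1)
  expect_equal(phantomics:::glcm_scalar_features(m1$glcm$d1),
    phantomics:::glcm_scalar_features(m2$glcm$d1), tolerance = 1e-12)
  expect_equal(
    phantomics:::rl_scalar_features(m1$glrlm[["3d"]], m1$n_voxels, "glrlm"),
    phantomics:::rl_scalar_features(m2$glrlm[["3d"]], m2$n_voxels, "glrlm"),
    tolerance = 1e-12
  )
  expect_equal(
    phantomics:::ngtdm_scalar_features(m1$ngtdm$d1, m1$n_voxels),
    phantomics:::ngtdm_scalar_features(m2$ngtdm$d1, m2$n_voxels),
    tolerance = 1e-12
  )
})
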