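cube_mask <- function(side, grid = side + 4, spacing = 1) {
  m <- array(FALSE, dim = rep(grid, 3))
  lo <- floor((grid - side) / 2) + 1
  m[lo:(lo + side - 1), lo:(lo + side - 1), lo:(lo + side - 1)] <- TRUE
  phantomics:::set_spacing(m, rep(spacing, 3))
}

test_that("smoothing leaves a solid cube unchanged and is idempotent", {
  m <- cube_mask(10)
  s1 <- smooth_mask(m)
  expect_equal(as.vector(s1), as.vector(m))
  # idempotence on an irregular but smooth-able mask
  irr <- generate_tumor_mask(phantom_spec(shape_irregularity = 0.6), 3)
  s2 <- smooth_mask(irr)
  expect_equal(smooth_mask(s2), s2)
})

test_that("smoothing removes a single-voxel spur (hand-checked opening)", {
  m <- cube_mask(6, grid = 12)
  # protruding spur: one voxel attached to a face
  m[10, 6, 6] <- TRUE
  s <- smooth_mask(m)
  expect_false(s[10, 6, 6])
  # the cube body survives
  expect_true(all(s[4:9, 4:9, 4:9]))
})

test_that("an isolated voxel degenerates under opening", {
  m <- array(FALSE, dim = c(9, 9, 9))
  m[5, 5, 5] <- TRUE
  m <- phantomics:::set_spacing(m, c(1, 1, 1))
  expect_error(smooth_mask(m), class = "phantomics_degenerate_mask")
})

test_that("resampling is the identity on matching grids and preserves constants", {
  v <- phantomics:::set_spacing(array(rnorm(27), dim = c(3, 3, 3)), c(1, 1, 1))
  expect_equal(resample_to_reference(v, c(3, 3, 3), c(1, 1, 1)),
    v, ignore_attr = TRUE)
  const <- phantomics:::set_spacing(array(7, dim = c(8, 8, 8)), c(1, 1, 1))
  out <- resample_to_reference(const, c(5, 6, 3), c(1.3, 0.9, 2.2))
  expect_equal(max(abs(out - 7)), 0, tolerance = 1e-12)
})

test_that("downsampling a linear ramp matches closed-form trilinear values", {
  # ramp along x: value = physical x coordinate of the voxel center
  v <- array(rep((1:16 - 0.5) * 1, times = 16), dim = c(16, 4, 4))
  v <- phantomics:::set_spacing(v, c(1, 1, 1))
  out <- resample_to_reference(v, c(8, 4, 4), c(2, 1, 1))
  # trilinear interpolation reproduces a linear field exactly at every new
  # voxel center (all of which lie inside the source center range here)
  expected_x <- (1:8 - 0.5) * 2
  expect_equal(out[, 1, 1], expected_x)
})

test_that("tumor size is the mean bounding-box extent and scales with spacing", {
  m <- array(FALSE, dim = c(40, 40, 40))
  m[1:10, 1:20, 1:30] <- TRUE
  expect_equal(tumor_size_mm(m, c(1, 1, 1)), 20)
  expect_equal(tumor_size_mm(m, c(0.5, 0.5, 0.5)), 10)
  # translation invariance
  m2 <- array(FALSE, dim = c(40, 40, 40))
  m2[6:15, 11:30, 7:36] <- TRUE
  expect_equal(tumor_size_mm(m2, c(1, 1, 1)), 20)
  expect_error(tumor_size_mm(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), "empty")
})

test_that("a digital ball's size equals its bounding box diameter", {
  r <- 5
  g <- 13
  ctr <- (g + 1) / 2
  coords <- expand.grid(x = 1:g, y = 1:g, z = 1:g)
  inside <- (coords$x - ctr)^2 + (coords$y - ctr)^2 + (coords$z - ctr)^2 <= r^2
  m <- array(inside, dim = c(g, g, g))
  expect_equal(tumor_size_mm(m, c(1, 1, 1)), 11) # 11 voxels per axis
})

test_that("exclusion rules follow the strict <5 mm and inclusive window reading", {
  cohort <- tibble::tibble(
    tumor_id = paste0("T", 1:5),
    patient_id = paste0("P", 1:5),
    size_mm = c(4.9, 5.0, 30, 10, 31),
    dce_path = "a", sub_path = "a", t2_path = c("a", "a", "a", "a", "a")
  )
  kept <- apply_exclusions(cohort)
  expect_setequal(kept$tumor_id, c("T2", "T3", "T4", "T5"))
  expect_equal(exclusion_log(kept)$tumor_id, "T1")

  win <- apply_exclusions(cohort, size_window = c(10, 30))
  expect_setequal(win$size_mm, c(30, 10)) # inclusive bounds, 5.0 < 10 out
})

test_that("tumors missing a contrast or manually flagged are dropped with reasons", {
  cohort <- tibble::tibble(
    tumor_id = paste0("T", 1:3),
    patient_id = paste0("P", 1:3),
    size_mm = c(20, 25, 30),
    dce_path = "a", sub_path = "a",
    t2_path = c("a", NA, "a"),
    exclude = c(FALSE, FALSE, TRUE)
  )
  kept <- apply_exclusions(cohort)
  expect_equal(kept$tumor_id, "T1")
  log <- exclusion_log(kept)
  expect_equal(log$reason[log$tumor_id == "T2"], "missing contrast")
  expect_equal(log$reason[log$tumor_id == "T3"], "manual exclusion")
})
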