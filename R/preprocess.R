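# Mask and volume conditioning: morphological smoothing, resampling to a
# common reference grid, size computation, and cohort-level exclusions.

#' Smooth a segmentation mask by sequential opening and closing
#'
#' Applies a morphological opening followed by a closing, both with a
#' 3 x 3 x 3 cubic structuring element, removing spurs and thin gaps left
#' by delineation. Idempotent on already-smooth masks.
#'
#' @param mask Binary 3D array (logical or 0/1).
#' @return Logical array of the same shape (spacing attribute preserved).
#' @export
smooth_mask <- function(mask) {
  assert_binary_mask(mask)
  sp <- attr(mask, "spacing")
  m <- as.logical(mask)
  dm <- as.integer(dim(mask))
  opened <- cpp_morph(cpp_morph(m, dm, 1L, TRUE), dm, 1L, FALSE)
  if (!any(opened)) {
    rlang::abort("mask degenerates to empty after opening",
      class = "phantomics_degenerate_mask")
  }
  closed <- cpp_morph(cpp_morph(opened, dm, 1L, FALSE), dm, 1L, TRUE)
  out <- array(closed, dim = dm)
  if (!is.null(sp)) out <- set_spacing(out, sp)
  out
}

# Physical coordinate of voxel centers: (i - 0.5) * spacing, shared origin.
voxel_centers <- function(n, spacing) (seq_len(n) - 0.5) * spacing

#' Resample a volume or mask onto a reference grid
#'
#' Maps reference voxel centers into the source grid (both grids share a
#' physical origin at the corner of the first voxel) and interpolates:
#' trilinear for intensity volumes, nearest neighbor (then re-binarized)
#' for masks. Coordinates beyond the source extent are clamped to the edge
#' (constant extrapolation).
#'
#' @param x Source 3D array with a `spacing` attribute (or `spacing` given).
#' @param reference_shape Integer vector, voxels per axis of the target grid.
#' @param reference_spacing Numeric vector, mm per voxel of the target grid.
#' @param kind `"volume"` (trilinear) or `"mask"` (nearest neighbor).
#' @param spacing Source spacing override.
#' @return Array on the reference grid with its spacing attached.
#' @export
resample_to_reference <- function(x, reference_shape, reference_spacing,
                                  kind = c("volume", "mask"),
                                  spacing = NULL) {
  kind <- match.arg(kind)
  sp <- spacing_of(x, spacing)
  src_shape <- dim(x)
  reference_shape <- as.integer(reference_shape)
  if (length(reference_spacing) == 1L) {
    reference_spacing <- rep(reference_spacing, 3L)
  }
  if (all(src_shape == reference_shape) && all(sp == reference_spacing)) {
    return(set_spacing(array(if (kind == "mask") as.logical(x) else
      as.numeric(x), dim = src_shape), sp))
  }
  if (any(src_shape * sp <= 0) || any(reference_shape * reference_spacing <= 0)) {
    rlang::abort("grids must have positive physical extent")
  }
  # fractional source index of each reference voxel center
  src_index <- lapply(1:3, function(a) {
    (voxel_centers(reference_shape[a], reference_spacing[a]) / sp[a]) + 0.5
  })
  if (kind == "mask") {
    idx <- lapply(1:3, function(a) {
      pmin(pmax(round(src_index[[a]]), 1L), src_shape[a])
    })
    xb <- array(as.logical(x), dim = src_shape)
    out <- array(xb[cbind(
      rep(idx[[1]], times = reference_shape[2] * reference_shape[3]),
      rep(rep(idx[[2]], each = reference_shape[1]),
        times = reference_shape[3]),
      rep(idx[[3]], each = reference_shape[1] * reference_shape[2])
    )], dim = reference_shape)
    return(set_spacing(out, reference_spacing))
  }
  # lower center index i0 with t in [i0, i0 + 1]; edges clamp (constant
  # extrapolation beyond the outermost voxel centers)
  i0 <- lapply(1:3, function(a) {
    as.integer(pmin(pmax(floor(src_index[[a]]), 1), max(src_shape[a] - 1L, 1)))
  })
  frac <- lapply(1:3, function(a) {
    pmin(pmax(src_index[[a]] - i0[[a]], 0), 1)
  })
  i1 <- lapply(1:3, function(a) pmin(i0[[a]] + 1L, src_shape[a]))
  nx <- reference_shape[1]
  ny <- reference_shape[2]
  nz <- reference_shape[3]
  gx0 <- rep(i0[[1]], times = ny * nz)
  gx1 <- rep(i1[[1]], times = ny * nz)
  fx <- rep(frac[[1]], times = ny * nz)
  gy0 <- rep(rep(i0[[2]], each = nx), times = nz)
  gy1 <- rep(rep(i1[[2]], each = nx), times = nz)
  fy <- rep(rep(frac[[2]], each = nx), times = nz)
  gz0 <- rep(i0[[3]], each = nx * ny)
  gz1 <- rep(i1[[3]], each = nx * ny)
  fz <- rep(frac[[3]], each = nx * ny)
  v <- as.numeric(x)
  at <- function(ix, iy, iz) {
    v[ix + src_shape[1] * ((iy - 1L) + src_shape[2] * (iz - 1L))]
  }
  out <-
    at(gx0, gy0, gz0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(gx1, gy0, gz0) * fx * (1 - fy) * (1 - fz) +
    at(gx0, gy1, gz0) * (1 - fx) * fy * (1 - fz) +
    at(gx1, gy1, gz0) * fx * fy * (1 - fz) +
    at(gx0, gy0, gz1) * (1 - fx) * (1 - fy) * fz +
    at(gx1, gy0, gz1) * fx * (1 - fy) * fz +
    at(gx0, gy1, gz1) * (1 - fx) * fy * fz +
    at(gx1, gy1, gz1) * fx * fy * fz
  set_spacing(array(out, dim = reference_shape), reference_spacing)
}

#' Representative tumor size from a mask
#'
#' The mean of the axis-aligned bounding-box extents (length, width,
#' height) of the nonzero voxels, in mm; each extent is the voxel count
#' along the axis times the spacing.
#'
#' @param mask Binary 3D array.
#' @param spacing Voxel spacing (mm); defaults to the `spacing` attribute.
#' @return Scalar size in mm.
#' @export
tumor_size_mm <- function(mask, spacing = NULL) {
  sp <- spacing_of(mask, spacing)
  idx <- which(as.logical(mask))
  if (!length(idx)) rlang::abort("mask is empty")
  dm <- dim(mask)
  coord <- arrayInd(idx, dm)
  extents <- vapply(1:3, function(a) {
    diff(range(coord[, a])) + 1L
  }, numeric(1))
  mean(extents * sp)
}

#' Apply cohort-level exclusion rules
#'
#' Drops tumors smaller than `min_size_mm` (strictly), tumors missing any
#' of the three contrast volumes, tumors flagged in a manual `exclude`
#' column (used for lesions whose roots spread through the entire gland,
#' which have no automatic criterion), and — when `size_window` is given —
#' tumors outside the inclusive `[low, high]` size window used for the
#' size-homogeneous analysis subset.
#'
#' @param cohort Cohort tibble with `size_mm` and `*_path` columns.
#' @param min_size_mm Minimum size (strict `<` is excluded); default 5.
#' @param size_window Optional `c(low, high)` inclusive window, e.g.
#'   `c(10, 30)` for a 20 +/- 10 mm subset.
#' @return The retained cohort tibble, with the per-tumor exclusion log
#'   attached as `attr(, "exclusions")` (columns `tumor_id`, `reason`).
#' @export
apply_exclusions <- function(cohort, min_size_mm = 5, size_window = NULL) {
  reasons <- rep(NA_character_, nrow(cohort))
  path_cols <- c("dce_path", "sub_path", "t2_path")
  missing_contrast <- rep(FALSE, nrow(cohort))
  for (pc in path_cols) {
    if (pc %in% names(cohort)) {
      missing_contrast <- missing_contrast | is.na(cohort[[pc]])
    } else {
      missing_contrast <- rep(TRUE, nrow(cohort))
    }
  }
  reasons[missing_contrast] <- "missing contrast"
  if ("exclude" %in% names(cohort)) {
    manual <- !is.na(cohort$exclude) & as.logical(cohort$exclude)
    reasons[is.na(reasons) & manual] <- "manual exclusion"
  }
  small <- cohort$size_mm < min_size_mm
  reasons[is.na(reasons) & small] <- sprintf("size < %g mm", min_size_mm)
  if (!is.null(size_window)) {
    outside <- cohort$size_mm < size_window[1] | cohort$size_mm > size_window[2]
    reasons[is.na(reasons) & outside] <- sprintf("size outside [%g, %g] mm",
      size_window[1], size_window[2])
  }
  log <- tibble::tibble(
    tumor_id = cohort$tumor_id[!is.na(reasons)],
    reason = reasons[!is.na(reasons)]
  )
  kept <- cohort[is.na(reasons), , drop = FALSE]
  if (!nrow(kept)) rlang::warn("all tumors excluded")
  attr(kept, "exclusions") <- log
  kept
}

#' @rdname apply_exclusions
#' @param cohort_or_result Output of [apply_exclusions()].
#' @export
exclusion_log <- function(cohort_or_result) {
  attr(cohort_or_result, "exclusions") %||%
    tibble::tibble(tumor_id = character(), reason = character())
}
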