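# Gray-level quantization of in-mask intensities.

#' Quantize in-mask intensities to L gray levels
#'
#' Equal-width binning of the in-mask intensity range into `L` bins:
#' `floor(L * (v - min) / (max - min)) + 1`, capped at `L`. Outside-mask
#' voxels are coded 0. A constant in-mask intensity maps every voxel to
#' level 1 and flags the result degenerate.
#'
#' @param volume Numeric 3D array.
#' @param mask Binary 3D array of the same shape.
#' @param L Number of gray levels (>= 2).
#' @return Integer array with levels `1..L` inside the mask, 0 outside;
#'   attribute `degenerate` is `TRUE` for constant regions.
#' @export
quantize <- function(volume, mask, L) {
  if (L < 2) rlang::abort("L must be >= 2")
  m <- as.logical(mask)
  if (!any(m)) rlang::abort("mask is empty")
  if (!all(dim(volume) == dim(mask))) rlang::abort("shape mismatch")
  v <- as.numeric(volume)[m]
  lo <- min(v)
  hi <- max(v)
  q <- array(0L, dim = dim(volume))
  if (hi - lo <= 0) {
    q[m] <- 1L
    attr(q, "degenerate") <- TRUE
  } else {
    q[m] <- pmin(as.integer(floor(L * (v - lo) / (hi - lo))) + 1L, as.integer(L))
    attr(q, "degenerate") <- FALSE
  }
  attr(q, "levels") <- as.integer(L)
  sp <- attr(mask, "spacing") %||% attr(volume, "spacing")
  if (!is.null(sp)) attr(q, "spacing") <- sp
  q
}

#' Texture matrices of a quantized volume
#'
#' Computes the full matrix set used by the texture features:
#' \itemize{
#'   \item GLCM: gray-level co-occurrence over the 13 unique 3D directions,
#'     at each requested voxel distance, counts summed over directions,
#'     symmetrized, and normalized to sum 1;
#'   \item GLRLM: run-length counts over the 13 directions (`"3d"`) and
#'     over the 4 in-plane directions (`"2d"`);
#'   \item GLSZM: size-zone counts from 26-connected (`"3d"`) or slice-wise
#'     8-connected (`"2d"`) equal-level zones;
#'   \item NGTDM: neighborhood gray-tone difference sums and level counts
#'     for each neighborhood half-width `d`.
#' }
#'
#' @param q Quantized volume from [quantize()].
#' @param glcm_distances Co-occurrence distances in voxels.
#' @param ngtdm_distances Neighborhood half-widths.
#' @param glrlm_modes,glszm_modes Aggregation modes (subset of "3d", "2d").
#' @return A list with elements `glcm` (named list of L x L probability
#'   matrices), `glrlm`, `glszm` (count matrices), `ngtdm` (L x 2 matrices
#'   of counts and difference sums), and `n_voxels`.
#' @export
compute_texture_matrices <- function(q, glcm_distances = c(1L, 2L, 3L),
                                     ngtdm_distances = c(1L, 2L, 3L),
                                     glrlm_modes = c("3d", "2d"),
                                     glszm_modes = c("3d", "2d")) {
  L <- attr(q, "levels")
  if (is.null(L)) L <- max(q)
  # texture matrices only involve in-mask voxels: crop to the bounding box
  idx <- arrayInd(which(q > 0L), dim(q))
  rng <- lapply(1:3, function(a) range(idx[, a]))
  q <- q[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
    rng[[3]][1]:rng[[3]][2], drop = FALSE]
  dm <- as.integer(dim(q))
  lab <- as.integer(q)
  off3 <- offsets_3d()
  off2 <- offsets_2d()
  n_vox <- sum(lab > 0L)

  glcm <- lapply(glcm_distances, function(d) {
    counts <- cpp_cooccurrence(lab, dm, L, off3 * as.integer(d))
    symm <- counts + t(counts)
    tot <- sum(symm)
    if (tot == 0) symm else symm / tot
  })
  names(glcm) <- paste0("d", glcm_distances)

  glrlm <- lapply(glrlm_modes, function(mode) {
    offs <- if (mode == "3d") off3 else off2
    cpp_runlength(lab, dm, L, offs)
  })
  names(glrlm) <- glrlm_modes

  glszm <- lapply(glszm_modes, function(mode) {
    zones <- cpp_zones(lab, dm, mode == "2d")
    max_sz <- if (nrow(zones)) max(zones[, 2]) else 1L
    mat <- matrix(0, nrow = L, ncol = max_sz)
    if (nrow(zones)) {
      for (k in seq_len(nrow(zones))) {
        mat[zones[k, 1], zones[k, 2]] <- mat[zones[k, 1], zones[k, 2]] + 1
      }
    }
    mat
  })
  names(glszm) <- glszm_modes

  ngtdm <- lapply(ngtdm_distances, function(d) {
    cpp_ngtdm(lab, dm, L, as.integer(d))
  })
  names(ngtdm) <- paste0("d", ngtdm_distances)

  list(glcm = glcm, glrlm = glrlm, glszm = glszm, ngtdm = ngtdm,
    n_voxels = n_vox, levels = L)
}
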