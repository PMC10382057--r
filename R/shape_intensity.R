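# Conventional size/shape and first-order intensity features, 3D geometric
# moments, and Haar wavelet-band summaries.

mask_coords_mm <- function(mask, sp) {
  idx <- which(as.logical(mask))
  coord <- arrayInd(idx, dim(mask))
  sweep(coord, 2, sp, `*`)
}

gaussian_smooth3d <- function(arr, spacing, sigma_mm) {
  shape <- dim(arr)
  axis_profile <- function(n, sp) {
    f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
    exp(-2 * pi^2 * (sigma_mm / sp)^2 * f^2)
  }
  H <- outer(outer(axis_profile(shape[1], spacing[1]),
    axis_profile(shape[2], spacing[2])), axis_profile(shape[3], spacing[3]))
  dim(H) <- shape
  Re(fft(fft(arr) * H, inverse = TRUE)) / prod(shape)
}

# Surface area via the coarea formula: the integral of the gradient
# magnitude of a slightly smoothed indicator equals the average area of its
# level sets, which converges to the true surface area.
surface_area_mm2 <- function(mask, sp) {
  m <- array(as.numeric(mask), dim = dim(mask))
  f <- gaussian_smooth3d(m, sp, sigma_mm = max(sp))
  grad2 <- 0
  for (a in 1:3) {
    n <- dim(f)[a]
    if (n < 3) next
    hi <- slice_shift(f, a, 1L)
    lo <- slice_shift(f, a, -1L)
    grad2 <- grad2 + ((hi - lo) / (2 * sp[a]))^2
  }
  sum(sqrt(grad2)) * prod(sp)
}

# Shift an array by k voxels along axis a, replicating the edge.
slice_shift <- function(x, a, k) {
  n <- dim(x)[a]
  idx <- pmin(pmax(seq_len(n) + k, 1L), n)
  args <- rep(list(quote(expr = )), 3)
  args[[a]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

boundary_voxels <- function(mask) {
  m <- as.logical(mask)
  dim(m) <- dim(mask)
  interior <- m
  for (a in 1:3) {
    interior <- interior & slice_shift(m, a, 1L) & slice_shift(m, a, -1L)
  }
  m & !interior
}

shape_features <- function(mask, sp) {
  n <- sum(mask)
  voxvol <- prod(sp)
  V <- n * voxvol
  A <- surface_area_mm2(mask, sp)
  r_eq <- (3 * V / (4 * pi))^(1 / 3)
  coord <- mask_coords_mm(mask, sp)
  extents <- vapply(1:3, function(a) diff(range(coord[, a])) + sp[a],
    numeric(1))
  if (n >= 2) {
    ev <- sort(eigen(stats::cov(coord), symmetric = TRUE,
      only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    ev <- c(1, 1, 1)
  }
  bnd <- mask_coords_mm(boundary_voxels(mask), sp)
  if (nrow(bnd) > 1500) {
    bnd <- bnd[seq(1, nrow(bnd), length.out = 1500), , drop = FALSE]
  }
  maxdiam <- if (nrow(bnd) >= 2) max(stats::dist(bnd)) else max(sp)
  c(
    volume_mm3 = V,
    surface_area_mm2 = A,
    surface_to_volume = A / V,
    sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    compactness1 = V / (sqrt(pi) * A^(3 / 2)),
    compactness2 = 36 * pi * V^2 / A^3,
    spherical_disproportion = A / (4 * pi * r_eq^2),
    bbox_extent_x = extents[1],
    bbox_extent_y = extents[2],
    bbox_extent_z = extents[3],
    bbox_volume_mm3 = prod(extents),
    elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1,
    max_diameter_mm = maxdiam
  )
}

firstorder_features <- function(v) {
  m <- mean(v)
  s <- sd(v)
  n <- length(v)
  cent <- v - m
  m2 <- mean(cent^2)
  qs <- quantile(v, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE, type = 7)
  hist_entropy <- if (max(v) > min(v)) {
    h <- tabulate(pmin(floor(32 * (v - min(v)) / (max(v) - min(v))) + 1, 32),
      nbins = 32)
    entropy_bits(h / n)
  } else 0
  c(
    mean = m,
    sd = s,
    skewness = if (m2 > 1e-24) mean(cent^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 1e-24) mean(cent^4) / m2^2 else 0,
    min = min(v),
    p10 = qs[1], p25 = qs[2], median = qs[3], p75 = qs[4], p90 = qs[5],
    max = max(v),
    iqr = qs[4] - qs[2],
    range = max(v) - min(v),
    energy = sum(v^2),
    entropy = hist_entropy,
    rms = sqrt(mean(v^2)),
    mad = mean(abs(cent))
  )
}

#' Conventional shape and first-order intensity features
#'
#' @param volume Numeric 3D array.
#' @param mask Binary 3D array on the same grid.
#' @param spacing Voxel spacing (mm).
#' @return Named vector `conv_*` matching the inventory's conventional
#'   category.
#' @export
shape_intensity_features <- function(volume, mask, spacing = NULL) {
  sp <- spacing_of(mask, spacing)
  if (!any(mask)) rlang::abort("mask is empty")
  v <- as.numeric(volume)[as.logical(mask)]
  out <- c(shape_features(mask, sp), firstorder_features(v))
  setNames(out, paste0("conv_", names(out)))
}

# Scale-normalized central geometric moments of the mask and rotation
# invariants of the second-order moment tensor.
moment_features <- function(mask, sp) {
  coord <- mask_coords_mm(mask, sp)
  voxvol <- prod(sp)
  ctr <- colMeans(coord)
  d <- sweep(coord, 2, ctr)
  mu000 <- nrow(d) * voxvol
  mu <- function(p, q, r) {
    voxvol * sum(d[, 1]^p * d[, 2]^q * d[, 3]^r)
  }
  eta <- function(p, q, r) {
    mu(p, q, r) / mu000^(1 + (p + q + r) / 3)
  }
  ords <- list(
    c(2, 0, 0), c(0, 2, 0), c(0, 0, 2), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
    c(3, 0, 0), c(0, 3, 0), c(0, 0, 3), c(2, 1, 0), c(2, 0, 1), c(1, 2, 0),
    c(0, 2, 1), c(1, 0, 2), c(0, 1, 2), c(1, 1, 1)
  )
  etas <- vapply(ords, function(o) eta(o[1], o[2], o[3]), numeric(1))
  names(etas) <- paste0("eta_", vapply(ords, function(o) {
    paste0(o, collapse = "")
  }, character(1)))
  M <- matrix(c(
    etas["eta_200"], etas["eta_110"], etas["eta_101"],
    etas["eta_110"], etas["eta_020"], etas["eta_011"],
    etas["eta_101"], etas["eta_011"], etas["eta_002"]
  ), 3, 3)
  ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
    decreasing = TRUE)
  minors <- M[1, 1] * M[2, 2] - M[1, 2]^2 +
    M[1, 1] * M[3, 3] - M[1, 3]^2 +
    M[2, 2] * M[3, 3] - M[2, 3]^2
  out <- c(
    etas,
    inv_j1 = sum(diag(M)),
    inv_j2 = minors,
    inv_j3 = det(M),
    anisotropy = if (ev[3] > 1e-12) sqrt(ev[1] / ev[3]) else 1
  )
  setNames(out, paste0("mom_", names(out)))
}

haar_axis <- function(x, a) {
  n <- dim(x)[a]
  odd <- seq(1, n, by = 2)
  even <- seq(2, n, by = 2)
  args_o <- rep(list(quote(expr = )), 3)
  args_o[[a]] <- odd
  args_e <- rep(list(quote(expr = )), 3)
  args_e[[a]] <- even
  xo <- do.call(`[`, c(list(x), args_o, list(drop = FALSE)))
  xe <- do.call(`[`, c(list(x), args_e, list(drop = FALSE)))
  list(lo = (xo + xe) / sqrt(2), hi = (xo - xe) / sqrt(2))
}

# One-level 3D Haar decomposition of the masked bounding-box crop
# (outside-mask voxels set to the in-mask mean), returning per-band
# summaries in inventory order (lll ... hhh).
wavelet_features <- function(volume, mask, stats_wanted) {
  idx <- arrayInd(which(as.logical(mask)), dim(mask))
  rng <- lapply(1:3, function(a) range(idx[, a]))
  crop <- volume[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
    rng[[3]][1]:rng[[3]][2], drop = FALSE]
  mcrop <- mask[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
    rng[[3]][1]:rng[[3]][2], drop = FALSE]
  fill <- mean(crop[as.logical(mcrop)])
  crop[!mcrop] <- fill
  # pad to even dimensions by edge replication
  for (a in 1:3) {
    if (dim(crop)[a] %% 2 == 1) {
      edge <- slice_take(crop, a, dim(crop)[a])
      crop <- abind3(crop, edge, a)
    }
  }
  x <- haar_axis(crop, 1)
  xy <- lapply(x, haar_axis, a = 2)
  bands <- list()
  for (nx in c("lo", "hi")) {
    for (ny in c("lo", "hi")) {
      z <- haar_axis(xy[[nx]][[ny]], 3)
      for (nz in c("lo", "hi")) {
        key <- paste0(
          if (nx == "lo") "l" else "h",
          if (ny == "lo") "l" else "h",
          if (nz == "lo") "l" else "h"
        )
        bands[[key]] <- as.numeric(z[[nz]])
      }
    }
  }
  # inventory band order: lll hll lhl hhl llh hlh lhh hhh
  order_keys <- wavelet_band_names()
  total_energy <- sum(vapply(bands, function(b) sum(b^2), numeric(1)))
  out <- numeric(0)
  for (key in order_keys) {
    b <- bands[[key]]
    ab <- abs(b)
    stats_all <- c(
      energy_frac = if (total_energy > 0) sum(b^2) / total_energy else 0,
      mean_abs = mean(ab),
      sd = sd(b),
      entropy = if (max(ab) > 0) {
        h <- tabulate(pmin(floor(16 * ab / max(ab)) + 1, 16), nbins = 16)
        entropy_bits(h / length(ab))
      } else 0
    )
    v <- stats_all[stats_wanted]
    names(v) <- paste0("wav_", key, "_", stats_wanted)
    out <- c(out, v)
  }
  out
}

slice_take <- function(x, a, i) {
  args <- rep(list(quote(expr = )), 3)
  args[[a]] <- i
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

abind3 <- function(x, y, a) {
  dms <- dim(x)
  dms[a] <- dms[a] + dim(y)[a]
  out <- array(0, dim = dms)
  args_x <- rep(list(quote(expr = )), 3)
  args_x[[a]] <- seq_len(dim(x)[a])
  args_y <- rep(list(quote(expr = )), 3)
  args_y[[a]] <- dim(x)[a] + seq_len(dim(y)[a])
  out <- do.call(`[<-`, c(list(out), args_x, list(x)))
  do.call(`[<-`, c(list(out), args_y, list(y)))
}
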