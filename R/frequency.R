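# Frequency-domain features: Gabor filter bank responses (slice-wise 2D),
# radial 3D FFT band energies, and local-binary-pattern descriptors.

# Complex Gabor transfer function on a P x P FFT grid: a Gaussian bump at
# (f, theta) in the frequency plane (analytic filter; magnitude of the
# spatial response is the local envelope). DC gain is forced to zero, so
# constant images give exactly zero response.
gabor_transfer <- function(P, f, theta_deg) {
  fr <- c(seq(0, floor(P / 2)), seq(-ceiling(P / 2) + 1, -1)) / P
  u <- matrix(fr, P, P)
  v <- t(u)
  th <- theta_deg * pi / 180
  up <- u * cos(th) + v * sin(th)
  vp <- -u * sin(th) + v * cos(th)
  sigma_f <- f / 3.52 # one-octave bandwidth (sigma_spatial = 0.56 / f)
  H <- exp(-((up - f)^2 + vp^2) / (2 * sigma_f^2))
  H[1, 1] <- 0
  H
}

gabor_cache <- new.env(parent = emptyenv())

gabor_bank <- function(P, frequencies, orientations) {
  key <- paste0(P, ":", paste(frequencies, collapse = ","), ":",
    paste(orientations, collapse = ","))
  bank <- gabor_cache[[key]]
  if (is.null(bank)) {
    bank <- list()
    for (f in frequencies) {
      for (o in orientations) {
        bank[[sprintf("f%02d_o%03d", round(f * 100), o)]] <-
          gabor_transfer(P, f, o)
      }
    }
    gabor_cache[[key]] <- bank
  }
  bank
}

next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

#' Gabor filter-bank texture features
#'
#' Applies a 2D Gabor bank (frequencies x orientations) slice-wise on the
#' axial plane of the masked bounding-box crop and summarizes the in-mask
#' response magnitude of each filter by its mean and standard deviation.
#'
#' @param volume Numeric 3D array.
#' @param mask Binary 3D array.
#' @param frequencies Cycles per pixel.
#' @param orientations_deg Orientations in degrees.
#' @return Named vector `gab_f*_o*_{mean,sd}` in inventory order.
#' @export
gabor_features <- function(volume, mask,
                           frequencies = c(0.05, 0.10, 0.20, 0.30, 0.40),
                           orientations_deg = c(0, 45, 90, 135)) {
  idx <- arrayInd(which(as.logical(mask)), dim(mask))
  rng <- lapply(1:2, function(a) range(idx[, a]))
  zs <- sort(unique(idx[, 3]))
  P <- next_pow2(max(rng[[1]][2] - rng[[1]][1], rng[[2]][2] - rng[[2]][1]) +
    1 + 16)
  bank <- gabor_bank(P, frequencies, orientations_deg)
  acc <- lapply(bank, function(h) numeric(0))
  for (z in zs) {
    sl <- volume[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2], z,
      drop = TRUE]
    msl <- mask[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2], z,
      drop = TRUE] > 0
    if (!any(msl)) next
    pad <- matrix(mean(sl), P, P)
    pad[seq_len(nrow(sl)), seq_len(ncol(sl))] <- sl
    Fs <- fft(pad)
    for (nm in names(bank)) {
      resp <- Mod(fft(Fs * bank[[nm]], inverse = TRUE)) / (P * P)
      acc[[nm]] <- c(acc[[nm]], resp[seq_len(nrow(sl)),
        seq_len(ncol(sl))][msl])
    }
  }
  out <- numeric(0)
  for (nm in names(bank)) {
    r <- acc[[nm]]
    mu <- if (length(r)) mean(r) else 0
    sdev <- if (length(r) > 1) sd(r) else 0
    v <- c(mu, sdev)
    names(v) <- paste0("gab_", nm, c("_mean", "_sd"))
    out <- c(out, v)
  }
  out
}

#' Radial FFT band energy features
#'
#' Takes the 3D FFT of the mean-subtracted masked crop (zero outside the
#' mask), bins the power spectrum into `n_bands` equal-width radial
#' frequency bands over (0, 1\] of the normalized Nyquist radius, and
#' reports each band's energy fraction and log mean power.
#'
#' @param volume Numeric 3D array.
#' @param mask Binary 3D array.
#' @param n_bands Number of radial bands.
#' @return Named vector `freq_band*_{frac,logpow}` in inventory order.
#' @export
frequency_features <- function(volume, mask, n_bands = 20) {
  idx <- arrayInd(which(as.logical(mask)), dim(mask))
  rng <- lapply(1:3, function(a) range(idx[, a]))
  crop <- volume[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
    rng[[3]][1]:rng[[3]][2], drop = FALSE]
  mcrop <- mask[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
    rng[[3]][1]:rng[[3]][2], drop = FALSE] > 0
  x <- array(0, dim = dim(crop))
  x[mcrop] <- crop[mcrop] - mean(crop[mcrop])
  Pw <- Mod(fft(x))^2
  shape <- dim(x)
  fr <- lapply(shape, function(n) {
    c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  })
  R2 <- outer(outer(fr[[1]]^2, fr[[2]]^2, `+`), fr[[3]]^2, `+`)
  rn <- sqrt(R2) / 0.5
  band <- pmin(ceiling(pmax(rn, 1e-12) * n_bands / sqrt(3)), n_bands)
  band[1] <- NA # exclude the DC cell
  total <- sum(Pw[-1])
  out <- numeric(0)
  for (b in seq_len(n_bands)) {
    inb <- which(band == b)
    e <- if (length(inb)) sum(Pw[inb]) else 0
    v <- c(
      frac = if (total > 0) e / total else 0,
      logpow = log1p(if (length(inb)) e / length(inb) else 0)
    )
    names(v) <- sprintf("freq_band%02d_%s", b, c("frac", "logpow"))
    out <- c(out, v)
  }
  out
}

# Rotation-invariant uniform local binary patterns (P = 8, R = 1),
# slice-wise on the axial plane; in-mask center pixels only.
lbp_features <- function(volume, mask) {
  codes <- integer(0)
  dm <- dim(volume)
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1), c(1, 1), c(1, 0),
    c(1, -1), c(0, -1))
  for (z in seq_len(dm[3])) {
    msl <- mask[, , z] > 0
    if (!any(msl)) next
    sl <- volume[, , z]
    nr <- nrow(sl)
    nc <- ncol(sl)
    if (nr < 3 || nc < 3) next
    core_r <- 2:(nr - 1)
    core_c <- 2:(nc - 1)
    ctr <- sl[core_r, core_c]
    inm <- msl[core_r, core_c]
    if (!any(inm)) next
    bits <- vapply(shifts, function(s) {
      as.integer(sl[core_r + s[1], core_c + s[2]] >= ctr)[inm]
    }, integer(sum(inm)))
    if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1)
    trans <- rowSums(abs(bits - bits[, c(2:8, 1), drop = FALSE]))
    ones <- rowSums(bits)
    code <- ifelse(trans <= 2, ones, 9L)
    codes <- c(codes, code)
  }
  p <- if (length(codes)) tabulate(codes + 1L, nbins = 10) / length(codes) else
    rep(0, 10)
  vals <- c(
    p,
    entropy_bits(p),
    sum(p^2),
    sum((0:9) * p),
    sum(((0:9) - sum((0:9) * p))^2 * p),
    1 - p[10],
    max(p)
  )
  setNames(vals, paste0("lbp_", lbp_feature_names()))
}
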