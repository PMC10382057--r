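# Scalar texture features from co-occurrence, run-length, size-zone and
# gray-tone difference matrices. Entropies use log base 2 with 0*log0 = 0;
# degenerate matrices take finite documented limits instead of NaN.

glcm_scalar_features <- function(P) {
  L <- nrow(P)
  vec <- as.vector(P)
  iv <- rep(seq_len(L), times = L)
  jv <- rep(seq_len(L), each = L)
  i <- matrix(iv, L, L)
  j <- matrix(jv, L, L)
  px <- rowSums(P)
  mu <- sum(seq_len(L) * px)
  sigma2 <- sum((seq_len(L) - mu)^2 * px)
  ks <- 2:(2 * L)
  p_sum <- numeric(2 * L - 1)
  tmp <- rowsum(vec, iv + jv)
  p_sum[as.integer(rownames(tmp)) - 1L] <- tmp
  kd <- 0:(L - 1)
  p_diff <- numeric(L)
  tmp <- rowsum(vec, abs(iv - jv))
  p_diff[as.integer(rownames(tmp)) + 1L] <- tmp
  da <- sum(kd * p_diff)
  sa <- sum(ks * p_sum)
  se <- entropy_bits(p_sum)
  hxy <- entropy_bits(as.vector(P))
  hx <- entropy_bits(px)
  pxy <- outer(px, px)
  pos <- P > 0 & pxy > 0
  hxy1 <- -sum(P[pos] * log2(pxy[pos]))
  hxy2 <- entropy_bits(as.vector(pxy))
  autoc <- sum(i * j * P)
  c(
    autocorrelation = autoc,
    joint_average = mu,
    joint_energy = sum(P^2),
    joint_entropy = hxy,
    joint_variance = sigma2,
    contrast = sum((i - j)^2 * P),
    correlation = if (sigma2 > 1e-12) (autoc - mu^2) / sigma2 else 0,
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    difference_average = da,
    difference_entropy = entropy_bits(p_diff),
    difference_variance = sum((kd - da)^2 * p_diff),
    difference_energy = sum(p_diff^2),
    sum_average = sa,
    sum_entropy = se,
    sum_variance = sum((ks - se)^2 * p_sum),
    sum_energy = sum(p_sum^2),
    inverse_difference = sum(p_diff / (1 + kd)),
    inverse_difference_moment = sum(p_diff / (1 + kd^2)),
    inverse_difference_norm = sum(p_diff / (1 + kd / L)),
    inverse_difference_moment_norm = sum(p_diff / (1 + kd^2 / L^2)),
    inverse_variance = sum(p_diff[-1] / kd[-1]^2),
    maximum_probability = max(P),
    imc1 = if (hx > 1e-12) (hxy - hxy1) / hx else 0,
    imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    marginal_entropy = hx,
    same_level_probability = sum(diag(P))
  )
}

# Shared distribution features for run-length (runs) and size-zone (zones)
# matrices: counts indexed by gray level (rows) and run length / zone size
# (columns). n_voxels gives the run/zone-percentage denominator.
rl_scalar_features <- function(M, n_voxels, prefix) {
  L <- nrow(M)
  J <- ncol(M)
  Nr <- sum(M)
  nm <- if (prefix == "glrlm") {
    c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv", "rlv",
      "run_entropy", "lglre", "hglre", "srlgle", "srhgle", "lrlgle", "lrhgle")
  } else {
    c("sae", "lae", "gln", "glnn", "szn", "sznn", "zp", "glv", "zv",
      "zone_entropy", "lglze", "hglze", "salgle", "sahgle", "lalgle", "lahgle")
  }
  if (Nr == 0) {
    return(setNames(rep(0, 16), nm))
  }
  ivec <- seq_len(L)
  jvec <- seq_len(J)
  gi <- rowSums(M)
  rj <- colSums(M)
  mu_i <- sum(ivec * gi) / Nr
  mu_j <- sum(jvec * rj) / Nr
  i2 <- ivec^2
  j2 <- jvec^2
  vals <- c(
    sum(rj / j2) / Nr,
    sum(rj * j2) / Nr,
    sum(gi^2) / Nr,
    sum(gi^2) / Nr^2,
    sum(rj^2) / Nr,
    sum(rj^2) / Nr^2,
    Nr / n_voxels,
    sum((ivec - mu_i)^2 * gi) / Nr,
    sum((jvec - mu_j)^2 * rj) / Nr,
    entropy_bits(as.vector(M) / Nr),
    sum(gi / i2) / Nr,
    sum(gi * i2) / Nr,
    sum(M * outer(1 / i2, 1 / j2)) / Nr,
    sum(M * outer(i2, 1 / j2)) / Nr,
    sum(M * outer(1 / i2, j2)) / Nr,
    sum(M * outer(i2, j2)) / Nr
  )
  setNames(vals, nm)
}

ngtdm_scalar_features <- function(mat, n_voxels) {
  ni <- mat[, 1]
  si <- mat[, 2]
  N <- sum(ni)
  out <- c(coarseness = 0, contrast = 0, busyness = 0, complexity = 0,
    strength = 0)
  if (N == 0) return(out)
  pi_ <- ni / N
  present <- which(pi_ > 0)
  iv <- seq_along(pi_)
  denom_c <- sum(pi_ * si)
  out["coarseness"] <- if (denom_c > 1e-12) min(1 / denom_c, 1e6) else 1e6
  ngp <- length(present)
  if (ngp >= 2) {
    pp <- outer(pi_[present], pi_[present])
    dd <- outer(iv[present], iv[present], "-")
    out["contrast"] <- sum(pp * dd^2) / (ngp * (ngp - 1)) * sum(si) / N
    ipi <- iv[present] * pi_[present]
    denom_b <- sum(abs(outer(ipi, ipi, "-")))
    out["busyness"] <- if (denom_b > 1e-12) denom_c / denom_b else 0
    psi <- pi_[present] * si[present]
    out["complexity"] <- sum(abs(dd) * (outer(psi, psi, "+")) /
      outer(pi_[present], pi_[present], "+")) / N
    denom_s <- sum(si)
    out["strength"] <- if (denom_s > 1e-12) {
      sum(outer(pi_[present], pi_[present], "+") * dd^2) / denom_s
    } else 0
  }
  out
}

#' Scalar texture features from a texture-matrix set
#'
#' Evaluates the full matrix-based feature block (co-occurrence, run
#' length, size zone, gray-tone difference) of the inventory on one
#' matrix set from [compute_texture_matrices()].
#'
#' @param mats Output of [compute_texture_matrices()].
#' @return Named numeric vector (`glcm_*`, `glrlm_*`, `glszm_*`,
#'   `ngtdm_*`), all finite.
#' @export
texture_features <- function(mats) {
  out <- numeric(0)
  for (d in names(mats$glcm)) {
    v <- glcm_scalar_features(mats$glcm[[d]])
    names(v) <- paste0("glcm_", d, "_", names(v))
    out <- c(out, v)
  }
  for (mode in names(mats$glrlm)) {
    v <- rl_scalar_features(mats$glrlm[[mode]], mats$n_voxels, "glrlm")
    names(v) <- paste0("glrlm_", mode, "_", names(v))
    out <- c(out, v)
  }
  for (mode in names(mats$glszm)) {
    v <- rl_scalar_features(mats$glszm[[mode]], mats$n_voxels, "glszm")
    names(v) <- paste0("glszm_", mode, "_", names(v))
    out <- c(out, v)
  }
  for (d in names(mats$ngtdm)) {
    v <- ngtdm_scalar_features(mats$ngtdm[[d]], mats$n_voxels)
    names(v) <- paste0("ngtdm_", d, "_", names(v))
    out <- c(out, v)
  }
  out
}
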