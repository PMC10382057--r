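# Independent brute-force oracles for the texture-matrix kernels and AUC.
# These enumerate voxel pairs / runs / zones / neighborhoods directly and
# stay independent of the compiled implementations they check.

oracle_offsets_3d <- function() {
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dz > 0 || (dz == 0 && (dy > 0 || (dy == 0 && dx > 0)))) {
      out[[length(out) + 1]] <- c(dx, dy, dz)
    }
  }
  do.call(rbind, out)
}

# GLCM by explicit enumeration over all voxel pairs.
oracle_glcm <- function(q, L, distance, offsets = oracle_offsets_3d()) {
  dm <- dim(q)
  counts <- matrix(0, L, L)
  for (o in seq_len(nrow(offsets))) {
    off <- offsets[o, ] * distance
    for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
      a <- q[x, y, z]
      if (a <= 0) next
      x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
      if (x2 < 1 || x2 > dm[1] || y2 < 1 || y2 > dm[2] ||
          z2 < 1 || z2 > dm[3]) next
      b <- q[x2, y2, z2]
      if (b <= 0) next
      counts[a, b] <- counts[a, b] + 1
    }
  }
  symm <- counts + t(counts)
  if (sum(symm) > 0) symm / sum(symm) else symm
}

# Run lengths by walking each line voxel by voxel.
oracle_glrlm <- function(q, L, offsets) {
  dm <- dim(q)
  maxlen <- max(dm)
  counts <- matrix(0, L, maxlen)
  inside <- function(p) all(p >= 1) && all(p <= dm)
  for (o in seq_len(nrow(offsets))) {
    off <- offsets[o, ]
    for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
      a <- q[x, y, z]
      if (a <= 0) next
      prev <- c(x, y, z) - off
      if (inside(prev) && q[prev[1], prev[2], prev[3]] == a) next
      len <- 1
      cur <- c(x, y, z) + off
      while (inside(cur) && q[cur[1], cur[2], cur[3]] == a) {
        len <- len + 1
        cur <- cur + off
      }
      counts[a, len] <- counts[a, len] + 1
    }
  }
  counts
}

# Size zones by repeated flood fill over an explicit neighbor list.
oracle_glszm <- function(q, L, planar = FALSE) {
  dm <- dim(q)
  seen <- array(FALSE, dm)
  zones <- list()
  neigh <- as.matrix(expand.grid(dx = -1:1, dy = -1:1,
    dz = if (planar) 0 else -1:1))
  neigh <- neigh[rowSums(abs(neigh)) > 0, , drop = FALSE]
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    if (seen[x, y, z] || q[x, y, z] <= 0) next
    lev <- q[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (k in seq_len(nrow(neigh))) {
        np <- p + as.numeric(neigh[k, 1:3])
        if (any(np < 1) || any(np > dm)) next
        if (!seen[np[1], np[2], np[3]] && q[np[1], np[2], np[3]] == lev) {
          seen[np[1], np[2], np[3]] <- TRUE
          stack[[length(stack) + 1]] <- np
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  max_sz <- max(vapply(zones, `[`, numeric(1), 2))
  mat <- matrix(0, L, max_sz)
  for (zn in zones) mat[zn[1], zn[2]] <- mat[zn[1], zn[2]] + 1
  mat
}

# NGTDM by direct per-voxel neighborhood averaging.
oracle_ngtdm <- function(q, L, d) {
  dm <- dim(q)
  out <- matrix(0, L, 2)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    a <- q[x, y, z]
    if (a <= 0) next
    vals <- c()
    for (dx in -d:d) for (dy in -d:d) for (dz in -d:d) {
      if (dx == 0 && dy == 0 && dz == 0) next
      p <- c(x + dx, y + dy, z + dz)
      if (any(p < 1) || any(p > dm)) next
      b <- q[p[1], p[2], p[3]]
      if (b > 0) vals <- c(vals, b)
    }
    if (length(vals)) {
      out[a, 1] <- out[a, 1] + 1
      out[a, 2] <- out[a, 2] + abs(a - mean(vals))
    }
  }
  out
}

# Direct transcription of the ReliefF update rule with explicit neighbor
# lists (the oracle deliberately mirrors the definition, not the code).
oracle_relieff <- function(X, y, k) {
  n <- nrow(X)
  w <- numeric(ncol(X))
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(X) - X[i, ])^2))
    hits <- setdiff(order(d), i)
    hits <- hits[y[hits] == y[i]][seq_len(k)]
    miss <- order(d)
    miss <- miss[y[miss] != y[i]][seq_len(k)]
    for (f in seq_len(ncol(X))) {
      w[f] <- w[f] +
        sum(abs(X[i, f] - X[miss, f])) / (n * k) -
        sum(abs(X[i, f] - X[hits, f])) / (n * k)
    }
  }
  w
}

# AUC by explicit pairwise positive-negative comparison.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Random quantized test volume: levels 1..L with a fraction of outside-mask
# zeros, spacing attached.
random_quantized <- function(dims, L, seed, p_mask = 0.8) {
  withr::with_seed(seed, {
    q <- array(sample(1:L, prod(dims), replace = TRUE), dim = dims)
    q[runif(prod(dims)) > p_mask] <- 0L
    storage.mode(q) <- "integer"
    attr(q, "levels") <- as.integer(L)
    q
  })
}
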