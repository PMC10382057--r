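# Internal helpers shared across modules.

# Derive a reproducible child seed from a base seed and a stream index.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 2654435761) %%
    2147483629L)
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a finite numeric scalar.", name))
  }
  invisible(x)
}

# 3D arrays carry voxel spacing in mm as an attribute.
spacing_of <- function(x, spacing = NULL) {
  sp <- spacing %||% attr(x, "spacing")
  if (is.null(sp)) rlang::abort("voxel spacing (mm) is required")
  if (length(sp) == 1L) sp <- rep(sp, 3L)
  as.numeric(sp)
}

set_spacing <- function(x, spacing) {
  attr(x, "spacing") <- as.numeric(spacing)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The 13 unique direction offsets of the 26-neighborhood (one per
# antipodal pair), and the 4 unique in-plane (axial) directions.
offsets_3d <- function() {
  all <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  all <- all[!(all[, 1] == 0 & all[, 2] == 0 & all[, 3] == 0), , drop = FALSE]
  keep <- all[, 3] > 0 |
    (all[, 3] == 0 & (all[, 2] > 0 | (all[, 2] == 0 & all[, 1] > 0)))
  out <- all[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  unname(out)
}

offsets_2d <- function() {
  out <- offsets_3d()
  out[out[, 3] == 0L, , drop = FALSE]
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

assert_binary_mask <- function(mask) {
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1, TRUE, FALSE))) {
    rlang::abort("mask must be binary (0/1)")
  }
  invisible(mask)
}
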