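# Synthetic phantom cohorts: seeded NIfTI tumor volumes (DCE / Sub / T2),
# masks, and a label table with the statistical structure the downstream
# radiomic analysis assumes.

contrast_names <- function() c("dce", "t1", "t2")

as_contrast_vec <- function(x, name) {
  if (length(x) == 1L) x <- setNames(rep(x, 3L), contrast_names())
  if (is.null(names(x))) names(x) <- contrast_names()
  missing <- setdiff(contrast_names(), names(x))
  if (length(missing)) {
    rlang::abort(sprintf("`%s` must name contrasts %s", name,
      toString(missing)))
  }
  x[contrast_names()]
}

#' Specify a tumor phantom
#'
#' Geometric and intensity parameters of one synthetic tumor: a perturbed
#' superellipsoid embedded in a noisy background, with a spatially
#' correlated interior texture field. The DCE tumor level must exceed the
#' background (lesions enhance), and the tumor must fit inside the grid
#' with at least a two-voxel margin.
#'
#' @param grid_shape Voxels per axis for the DCE/Sub (reference) grid.
#' @param spacing_mm Voxel size per axis, mm.
#' @param tumor_size_mm Target mean of the bounding-box extents, mm.
#' @param shape_irregularity Scalar in \[0,1\] scaling low-order harmonic
#'   perturbation of the ellipsoid boundary.
#' @param background_level,tumor_level Mean intensities per contrast
#'   (named `dce`, `t1`, `t2`; arbitrary units). The subtraction channel is
#'   derived as `pmax(DCE - T1, 0)`.
#' @param noise_sd Gaussian noise standard deviation per contrast.
#' @param texture_sd Standard deviation of the tumor-interior correlated
#'   texture field per contrast.
#' @param texture_granularity_mm Correlation length (mm) of the texture
#'   field, scalar or per contrast.
#' @param t2_grid Optional list with `shape` and `spacing_mm` for a coarser
#'   native T2 grid (emulating the lower T2 resolution); `NULL` keeps T2 on
#'   the reference grid.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(36L, 36L, 36L),
                         spacing_mm = c(2, 2, 2),
                         tumor_size_mm = 20,
                         shape_irregularity = 0.3,
                         background_level = c(dce = 100, t1 = 90, t2 = 120),
                         tumor_level = c(dce = 180, t1 = 100, t2 = 160),
                         noise_sd = c(dce = 8, t1 = 8, t2 = 10),
                         texture_sd = c(dce = 25, t1 = 10, t2 = 25),
                         texture_granularity_mm = 4,
                         t2_grid = list(shape = c(24L, 24L, 24L),
                                        spacing_mm = c(3, 3, 3))) {
  spec <- list(
    grid_shape = as.integer(grid_shape),
    spacing_mm = as.numeric(spacing_mm),
    tumor_size_mm = tumor_size_mm,
    shape_irregularity = shape_irregularity,
    background_level = as_contrast_vec(background_level, "background_level"),
    tumor_level = as_contrast_vec(tumor_level, "tumor_level"),
    noise_sd = as_contrast_vec(noise_sd, "noise_sd"),
    texture_sd = as_contrast_vec(texture_sd, "texture_sd"),
    texture_granularity_mm = as_contrast_vec(texture_granularity_mm,
      "texture_granularity_mm"),
    t2_grid = t2_grid
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  stopifnot_scalar(spec$tumor_size_mm, "tumor_size_mm")
  stopifnot_scalar(spec$shape_irregularity, "shape_irregularity")
  if (spec$shape_irregularity < 0 || spec$shape_irregularity > 1) {
    rlang::abort("shape_irregularity must lie in [0, 1]")
  }
  if (any(spec$noise_sd < 0) || any(spec$texture_sd < 0)) {
    rlang::abort("noise and texture standard deviations must be >= 0")
  }
  if (spec$tumor_level[["dce"]] <= spec$background_level[["dce"]]) {
    rlang::abort("tumor_level must exceed background_level on DCE")
  }
  if (any(spec$texture_granularity_mm <= 0)) {
    rlang::abort("texture_granularity_mm must be positive")
  }
  invisible(spec)
}

# Largest tumor_size_mm (mean bbox extent) that fits with margin, allowing
# for boundary perturbation and radius anisotropy.
max_tumor_size <- function(spec) {
  extent <- min(spec$grid_shape * spec$spacing_mm)
  margin <- 2 * max(spec$spacing_mm)
  (extent - 2 * margin) / 1.45
}

# Enlarge the reference (and native T2) grid so an oversized tumor still
# fits with margin; spacing is preserved.
adapt_grid_to_size <- function(spec) {
  if (spec$tumor_size_mm <= max_tumor_size(spec)) {
    return(spec)
  }
  sp <- spec$spacing_mm
  need_mm <- spec$tumor_size_mm * 1.5 + 6 * max(sp)
  spec$grid_shape <- pmax(spec$grid_shape,
    as.integer(ceiling(need_mm / sp)))
  if (!is.null(spec$t2_grid)) {
    spec$t2_grid$shape <- pmax(as.integer(spec$t2_grid$shape),
      as.integer(ceiling(need_mm / spec$t2_grid$spacing_mm)))
  }
  spec
}

#' Class-linked effect profile for cohort generation
#'
#' Describes how phantom parameters shift for positive-class tumors
#' (ER+/PR+/HER2+/ILC), scaled by a single standardized `effect_size`.
#' `effect_size = 0` yields class-exchangeable cohorts by construction.
#'
#' @param prevalence Named positive-class prevalences in (0,1):
#'   `er`, `pr`, `her2` (probability of "+") and `idc` (probability the
#'   histotype is IDC; ILC is the positive class downstream).
#' @param effect_size Standardized magnitude multiplying every `delta`.
#' @param effects A tibble with columns `label` (er/pr/her2/histotype),
#'   `param` (a `phantom_spec` parameter), `contrast` (`NA` for all), and
#'   `delta` (shift in native units at `effect_size = 1`).
#' @return A `class_effect_profile` list.
#' @export
class_effect_profile <- function(prevalence = c(er = 0.75, pr = 0.65,
                                                her2 = 0.20, idc = 0.85),
                                 effect_size = 1,
                                 effects = default_class_effects()) {
  if (any(prevalence <= 0) || any(prevalence >= 1)) {
    rlang::abort("prevalences must lie strictly in (0, 1)")
  }
  stopifnot_scalar(effect_size, "effect_size")
  out <- list(
    prevalence = prevalence[c("er", "pr", "her2", "idc")],
    effect_size = effect_size,
    effects = effects
  )
  class(out) <- "class_effect_profile"
  out
}

#' @rdname class_effect_profile
#' @export
default_class_effects <- function() {
  tibble::tribble(
    ~label,      ~param,                   ~contrast, ~delta,
    "er",        "texture_granularity_mm", NA,        1.5,
    "histotype", "shape_irregularity",     NA,        0.15,
    "histotype", "texture_sd",             NA,        8,
    "pr",        "tumor_level",            "dce",     6,
    "her2",      "texture_granularity_mm", NA,        -0.8
  )
}

#' @rdname class_effect_profile
#' @export
null_profile <- function() class_effect_profile(effect_size = 0)

#' ER-linked texture effect profile
#'
#' A profile whose only effect is a strong ER-linked shift of the tumor
#' texture (longer correlation length and larger amplitude), optionally
#' restricted to a subset of contrast channels.
#'
#' @param granularity_delta Shift of the texture correlation length (mm).
#' @param texture_sd_delta Shift of the texture amplitude.
#' @param contrasts Contrast channels carrying the effect (`NULL` = all).
#' @param prevalence See [class_effect_profile()].
#' @return A `class_effect_profile`.
#' @export
er_texture_profile <- function(granularity_delta = 3,
                               texture_sd_delta = 10,
                               contrasts = NULL,
                               prevalence = c(er = 0.5, pr = 0.65,
                                              her2 = 0.20, idc = 0.85)) {
  cs <- contrasts %||% NA
  effects <- dplyr::bind_rows(lapply(cs, function(ct) {
    tibble::tibble(
      label = "er",
      param = c("texture_granularity_mm", "texture_sd"),
      contrast = ct,
      delta = c(granularity_delta, texture_sd_delta)
    )
  }))
  class_effect_profile(prevalence = prevalence, effect_size = 1,
    effects = effects)
}

# Shift spec parameters for one tumor given its (true) class labels.
apply_class_effects <- function(spec, profile, labels) {
  if (is.null(profile) || is.null(labels) || profile$effect_size == 0 ||
      !nrow(profile$effects)) {
    return(spec)
  }
  positive <- c(
    er = identical(labels$er, "+"),
    pr = identical(labels$pr, "+"),
    her2 = identical(labels$her2, "+"),
    histotype = identical(labels$histotype, "ILC")
  )
  for (i in seq_len(nrow(profile$effects))) {
    e <- profile$effects[i, ]
    if (!isTRUE(positive[[e$label]])) next
    shift <- profile$effect_size * e$delta
    if (is.na(e$contrast)) {
      spec[[e$param]] <- spec[[e$param]] + shift
    } else {
      spec[[e$param]][[e$contrast]] <- spec[[e$param]][[e$contrast]] + shift
    }
  }
  # keep parameters in their valid ranges after shifting
  spec$shape_irregularity <- min(max(spec$shape_irregularity, 0), 1)
  spec$texture_granularity_mm <- pmax(spec$texture_granularity_mm, 0.5)
  spec$texture_sd <- pmax(spec$texture_sd, 0)
  spec
}

# Low-order real spherical-harmonic basis evaluated at unit directions.
harmonic_basis <- function(dx, dy, dz) {
  cbind(
    dx, dy, dz,
    sqrt(3) * dx * dy, sqrt(3) * dx * dz, sqrt(3) * dy * dz,
    sqrt(3 / 4) * (dx^2 - dy^2), (3 * dz^2 - 1) / 2
  )
}

#' Generate a tumor segmentation mask
#'
#' Voxelizes a randomly perturbed superellipsoid whose mean bounding-box
#' extent is calibrated to `spec$tumor_size_mm`. The boundary perturbation
#' is a low-order spherical-harmonic field scaled by
#' `spec$shape_irregularity`; the region is star-shaped and therefore
#' connected.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; the mask is a pure function of `(spec, seed)`.
#' @return A logical 3D array with a `spacing` attribute.
#' @export
generate_tumor_mask <- function(spec, seed) {
  validate_phantom_spec(spec)
  if (spec$tumor_size_mm > max_tumor_size(spec)) {
    rlang::abort(sprintf(
      "tumor of size %.1f mm cannot fit in a %s grid with a 2-voxel margin",
      spec$tumor_size_mm,
      paste(round(spec$grid_shape * spec$spacing_mm), collapse = "x")
    ))
  }
  shape <- spec$grid_shape
  sp <- spec$spacing_mm
  with_seed(seed, {
    aniso <- exp(rnorm(3, 0, 0.12))
    aniso <- aniso / mean(aniso)
    expo <- runif(1, 1.8, 2.6)
    w <- rnorm(8)
  })
  radii <- spec$tumor_size_mm / 2 * aniso

  ax <- lapply(1:3, function(a) (seq_len(shape[a]) - (shape[a] + 1) / 2) * sp[a])
  X <- array(rep(ax[[1]], times = shape[2] * shape[3]), dim = shape)
  Y <- array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), dim = shape)
  Z <- array(rep(ax[[3]], each = shape[1] * shape[2]), dim = shape)
  rr <- sqrt(X^2 + Y^2 + Z^2)
  rr[rr == 0] <- 1e-9
  B <- harmonic_basis(as.vector(X / rr), as.vector(Y / rr), as.vector(Z / rr))
  s <- as.vector(B %*% w)
  s <- s / max(sqrt(mean(s^2)), 1e-9)
  boundary <- 1 + 0.25 * spec$shape_irregularity * s

  voxelize <- function(radii) {
    u <- (abs(as.vector(X)) / radii[1])^expo +
      (abs(as.vector(Y)) / radii[2])^expo +
      (abs(as.vector(Z)) / radii[3])^expo
    array(u^(1 / expo) <= boundary, dim = shape)
  }
  mask <- voxelize(radii)
  # one-step size calibration against the realized bounding box
  for (it in 1:3) {
    if (!any(mask)) break
    measured <- tumor_size_mm(mask, sp)
    if (abs(measured - spec$tumor_size_mm) / spec$tumor_size_mm < 0.02) break
    radii <- radii * spec$tumor_size_mm / measured
    mask <- voxelize(radii)
  }
  if (!any(mask)) {
    # sub-voxel tumor: occupy the center voxel (excluded downstream as <5 mm)
    ctr <- ceiling(shape / 2)
    mask[ctr[1], ctr[2], ctr[3]] <- TRUE
  }
  set_spacing(mask, sp)
}

# Stationary Gaussian random field: white noise smoothed in the frequency
# domain by a Gaussian transfer function with correlation length sigma_mm,
# then normalized to unit variance.
gaussian_random_field <- function(shape, spacing, sigma_mm) {
  w <- array(rnorm(prod(shape)), dim = shape)
  if (!is.finite(sigma_mm) || sigma_mm > 1e3) {
    return(array(0, dim = shape))
  }
  # separable Gaussian transfer function (outer product of axis profiles)
  axis_profile <- function(n, sp) {
    f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
    exp(-2 * pi^2 * (sigma_mm / sp)^2 * f^2)
  }
  H <- outer(
    outer(axis_profile(shape[1], spacing[1]), axis_profile(shape[2],
      spacing[2])),
    axis_profile(shape[3], spacing[3])
  )
  dim(H) <- shape
  sm <- Re(fft(fft(w) * H, inverse = TRUE)) / prod(shape)
  sdv <- sd(as.vector(sm))
  if (sdv < 1e-12) array(0, dim = shape) else sm / sdv
}

synth_channel <- function(mask, shape, spacing, bg, tum, noise, tex_sd,
                          gran) {
  field <- gaussian_random_field(shape, spacing, gran)
  vol <- array(bg, dim = shape)
  if (noise > 0) vol <- vol + array(rnorm(prod(shape), 0, noise), dim = shape)
  vol[mask] <- vol[mask] + (tum - bg) + tex_sd * field[mask]
  vol
}

#' Generate the three contrast volumes for one tumor
#'
#' Synthesizes DCE, T1 and T2 channels (background plus noise, tumor-level
#' elevation, and a correlated interior texture field) and derives the
#' subtraction channel `Sub = pmax(DCE - T1, 0)`. If the spec defines a
#' native T2 grid, T2 is synthesized there (with the mask transferred by
#' nearest neighbor), emulating the coarser T2 resolution.
#'
#' @param mask Logical mask from [generate_tumor_mask()] on the spec grid.
#' @param spec A [phantom_spec()].
#' @param profile Optional [class_effect_profile()] shifting parameters by
#'   class; ignored when `labels` is `NULL`.
#' @param labels Optional list with `er`, `pr`, `her2` (`"+"/"-"`) and
#'   `histotype` (`"IDC"/"ILC"`).
#' @param seed Integer seed; output is a pure function of the arguments.
#' @return Named list of spacing-tagged arrays `dce`, `sub`, `t2`.
#' @export
generate_volume_set <- function(mask, spec, profile = NULL, labels = NULL,
                                seed = 1L) {
  spec <- apply_class_effects(spec, profile, labels)
  validate_phantom_spec(spec)
  shape <- spec$grid_shape
  sp <- spec$spacing_mm
  if (!all(dim(mask) == shape)) rlang::abort("mask is not on the spec grid")
  out <- with_seed(seed, {
    dce <- synth_channel(mask, shape, sp, spec$background_level[["dce"]],
      spec$tumor_level[["dce"]], spec$noise_sd[["dce"]],
      spec$texture_sd[["dce"]], spec$texture_granularity_mm[["dce"]])
    t1 <- synth_channel(mask, shape, sp, spec$background_level[["t1"]],
      spec$tumor_level[["t1"]], spec$noise_sd[["t1"]],
      spec$texture_sd[["t1"]], spec$texture_granularity_mm[["t1"]])
    if (is.null(spec$t2_grid)) {
      t2_shape <- shape
      t2_sp <- sp
      t2_mask <- mask
    } else {
      t2_shape <- as.integer(spec$t2_grid$shape)
      t2_sp <- as.numeric(spec$t2_grid$spacing_mm)
      t2_mask <- resample_to_reference(set_spacing(mask, sp),
        reference_shape = t2_shape, reference_spacing = t2_sp,
        kind = "mask")
    }
    t2 <- synth_channel(t2_mask, t2_shape, t2_sp,
      spec$background_level[["t2"]], spec$tumor_level[["t2"]],
      spec$noise_sd[["t2"]], spec$texture_sd[["t2"]],
      spec$texture_granularity_mm[["t2"]])
    list(
      dce = set_spacing(dce, sp),
      sub = set_spacing(pmax(dce - t1, 0), sp),
      t2 = set_spacing(t2, t2_sp)
    )
  })
  out
}

sample_labels <- function(prevalence) {
  list(
    er = if (runif(1) < prevalence[["er"]]) "+" else "-",
    pr = if (runif(1) < prevalence[["pr"]]) "+" else "-",
    her2 = if (runif(1) < prevalence[["her2"]]) "+" else "-",
    histotype = if (runif(1) < prevalence[["idc"]]) "IDC" else "ILC"
  )
}

#' Generate a phantom cohort on disk
#'
#' Samples patients (a configurable fraction carrying two tumors, all of a
#' patient's tumors sharing labels), draws tumor sizes from a log-normal
#' law calibrated to a right-skewed clinical size distribution
#' (mean 24.6 mm, median 20.3 mm), synthesizes volumes and masks, writes
#' NIfTI files plus a `cohort.csv` label table and a YAML generation
#' config, and returns the cohort tibble.
#'
#' @param n_patients Number of patients (>= 10).
#' @param out_dir Output directory (created if needed).
#' @param spec Base [phantom_spec()]; per-tumor size and mild shape jitter
#'   are applied on top.
#' @param profile [class_effect_profile()] linking labels to parameters.
#' @param seed Integer master seed.
#' @param p_second_tumor Probability a patient carries a second tumor
#'   (0.33 yields roughly 429 tumors per 323 patients).
#' @param missing_frac Per-cell probability that a label is missing.
#' @param size_meanlog,size_sdlog Log-normal size-law parameters (mm); the
#'   defaults solve mean = 24.6 and median = 20.3.
#' @return A tibble with columns `tumor_id`, `patient_id`, `er`, `pr`,
#'   `her2`, `histotype`, `size_mm` (measured from the realized mask), and
#'   the four file paths.
#' @export
generate_cohort <- function(n_patients, out_dir,
                            spec = phantom_spec(),
                            profile = class_effect_profile(),
                            seed = 1L,
                            p_second_tumor = 0.33,
                            missing_frac = 0.08,
                            size_meanlog = log(20.3),
                            size_sdlog = sqrt(2 * log(24.6 / 20.3))) {
  if (n_patients < 10) rlang::abort("n_patients must be >= 10")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) {
    rlang::abort(paste0("out_dir not writable: ", out_dir))
  }
  # the grid adapts to large tumors (below), so the size law is truncated
  # only at a hard 80 mm ceiling where its mass is negligible
  size_cap <- 80

  rows <- list()
  tumor_k <- 0L
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%04d", i)
    pseed <- child_seed(seed, i)
    patient <- with_seed(pseed, {
      labels <- sample_labels(profile$prevalence)
      n_tum <- 1L + rbinom(1L, 1L, p_second_tumor)
      sizes <- numeric(n_tum)
      for (t in seq_len(n_tum)) {
        repeat {
          s <- rlnorm(1, size_meanlog, size_sdlog)
          if (s >= 3 && s <= size_cap) break
        }
        sizes[t] <- s
      }
      irr <- pmin(pmax(spec$shape_irregularity + rnorm(n_tum, 0, 0.05), 0), 1)
      miss <- matrix(runif(4 * n_tum) < missing_frac, nrow = n_tum)
      list(labels = labels, sizes = sizes, irr = irr, miss = miss)
    })
    for (t in seq_along(patient$sizes)) {
      tumor_k <- tumor_k + 1L
      tid <- sprintf("T%04d", tumor_k)
      tspec <- spec
      tspec$tumor_size_mm <- patient$sizes[t]
      tspec$shape_irregularity <- patient$irr[t]
      tspec <- adapt_grid_to_size(tspec)
      tspec <- apply_class_effects(tspec, profile, patient$labels)
      mseed <- child_seed(pseed, 1000L + t)
      mask <- generate_tumor_mask(tspec, mseed)
      vols <- generate_volume_set(mask, tspec, seed = child_seed(pseed,
        2000L + t))
      paths <- setNames(
        file.path(out_dir, paste0(tid, "_", c("dce", "sub", "t2", "mask"),
          ".nii.gz")),
        c("dce", "sub", "t2", "mask")
      )
      write_volume(vols$dce, paths[["dce"]])
      write_volume(vols$sub, paths[["sub"]])
      write_volume(vols$t2, paths[["t2"]])
      write_volume(mask * 1, paths[["mask"]], spacing = spacing_of(mask))
      lab <- patient$labels
      m <- patient$miss[t, ]
      rows[[tumor_k]] <- tibble::tibble(
        tumor_id = tid, patient_id = pid,
        er = if (m[1]) NA_character_ else lab$er,
        pr = if (m[2]) NA_character_ else lab$pr,
        her2 = if (m[3]) NA_character_ else lab$her2,
        histotype = if (m[4]) NA_character_ else lab$histotype,
        size_mm = tumor_size_mm(mask),
        dce_path = basename(paths[["dce"]]),
        sub_path = basename(paths[["sub"]]),
        t2_path = basename(paths[["t2"]]),
        mask_path = basename(paths[["mask"]])
      )
    }
  }
  cohort <- dplyr::bind_rows(rows)
  readr::write_csv(cohort, file.path(out_dir, "cohort.csv"))
  yaml::write_yaml(
    list(
      seed = as.integer(seed), n_patients = as.integer(n_patients),
      p_second_tumor = p_second_tumor, missing_frac = missing_frac,
      size_meanlog = size_meanlog, size_sdlog = size_sdlog,
      grid_shape = spec$grid_shape, spacing_mm = spec$spacing_mm,
      effect_size = profile$effect_size
    ),
    file.path(out_dir, "cohort_config.yaml")
  )
  cohort %>%
    dplyr::mutate(dplyr::across(dplyr::ends_with("_path"),
      ~ file.path(out_dir, .x)))
}

#' Read a cohort table written by [generate_cohort()]
#'
#' @param path Path to a `cohort.csv`; relative file paths are resolved
#'   against its directory.
#' @return The cohort tibble with absolute paths.
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(
      tumor_id = "c", patient_id = "c", er = "c", pr = "c", her2 = "c",
      histotype = "c", size_mm = "d", .default = "c"
    ))
  base <- dirname(path)
  cohort %>%
    dplyr::mutate(dplyr::across(dplyr::ends_with("_path"),
      ~ ifelse(is.na(.x) | grepl("^/", .x), .x, file.path(base, .x))))
}
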