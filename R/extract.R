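# Per-tumor feature extraction: 342 features per contrast, quantization-
# dependent features averaged over the six gray-level quantizations.

#' Extract the full radiomic feature vector for one tumor
#'
#' Quantization-dependent texture-matrix features are computed at each of
#' the six gray-level quantizations (8, 16, 24, 32, 48, 64 by default) and
#' arithmetically averaged; every other feature is computed once per
#' contrast. The output is aligned to the inventory order and always has
#' exactly `nrow(inventory)` values per contrast.
#'
#' @param volumes Named list of contrast arrays (`dce`, `sub`, `t2`), all
#'   co-registered on the same grid as `mask`.
#' @param mask Binary 3D array with a `spacing` attribute.
#' @param inventory Feature inventory tibble from [feature_inventory()].
#' @param manifest Manifest list from [feature_manifest()].
#' @param spacing Spacing override (mm).
#' @param contrasts Contrast channels to extract.
#' @return A tibble with one row per contrast: `contrast` plus one column
#'   per inventory feature.
#' @export
extract_features <- function(volumes, mask, inventory = feature_inventory(),
                             manifest = feature_manifest(), spacing = NULL,
                             contrasts = c("dce", "sub", "t2")) {
  needed <- contrasts
  missing <- setdiff(needed, names(volumes))
  if (length(missing)) {
    rlang::abort(paste0("missing contrast volume(s): ", toString(missing)))
  }
  sp <- spacing_of(mask, spacing)
  if (!any(mask)) rlang::abort("mask is empty")
  for (ct in needed) {
    if (!all(dim(volumes[[ct]]) == dim(mask))) {
      rlang::abort(paste0("contrast ", ct, " is not on the mask grid"))
    }
  }
  levels <- manifest$levels
  shape_block <- shape_features(mask, sp)
  mom_block <- moment_features(mask, sp)

  rows <- lapply(needed, function(ct) {
    vol <- volumes[[ct]]
    v_in <- as.numeric(vol)[as.logical(mask)]
    fo <- firstorder_features(v_in)
    conv <- setNames(c(shape_block, fo),
      paste0("conv_", c(names(shape_block), names(fo))))
    wav <- wavelet_features(vol, mask, manifest$transforms$stats)
    lbp <- lbp_features(vol, mask)
    gab <- gabor_features(vol, mask, manifest$gabor$frequencies,
      manifest$gabor$orientations_deg)
    frq <- frequency_features(vol, mask, manifest$frequency$n_bands)

    tex_acc <- NULL
    for (L in levels) {
      q <- quantize(vol, mask, L)
      mats <- compute_texture_matrices(
        q,
        glcm_distances = manifest$glcm$distances,
        ngtdm_distances = manifest$ngtdm$distances,
        glrlm_modes = manifest$glrlm$modes,
        glszm_modes = manifest$glszm$modes
      )
      tf <- texture_features(mats)
      tex_acc <- if (is.null(tex_acc)) tf else tex_acc + tf
    }
    tex <- tex_acc / length(levels)
    all_vals <- c(conv, mom_block, wav, lbp, gab, frq, tex)
    missing_f <- setdiff(inventory$name, names(all_vals))
    if (length(missing_f)) {
      rlang::abort(paste0("extractor did not produce: ",
        toString(head(missing_f, 5))))
    }
    vals <- all_vals[inventory$name]
    vals[!is.finite(vals)] <- 0
    tibble::as_tibble(c(list(contrast = ct), as.list(vals)))
  })
  dplyr::bind_rows(rows)
}

# Read, smooth, and co-register one tumor's volumes onto the DCE grid.
load_volume_set <- function(row, contrasts = c("dce", "sub", "t2")) {
  dce <- read_volume(row$dce_path)
  ref_shape <- dim(dce)
  ref_sp <- spacing_of(dce)
  mask <- read_volume(row$mask_path)
  mask <- resample_to_reference(mask > 0.5, ref_shape, ref_sp, kind = "mask",
    spacing = spacing_of(mask))
  vols <- list(dce = dce)
  if ("sub" %in% contrasts) {
    vols$sub <- resample_to_reference(read_volume(row$sub_path), ref_shape,
      ref_sp, kind = "volume")
  }
  if ("t2" %in% contrasts) {
    vols$t2 <- resample_to_reference(read_volume(row$t2_path), ref_shape,
      ref_sp, kind = "volume")
  }
  mask <- smooth_mask(set_spacing(mask, ref_sp))
  list(volumes = vols[contrasts], mask = mask)
}

#' Extract features for every tumor in a cohort
#'
#' For each retained tumor: reads the NIfTI volumes and mask, smooths the
#' mask morphologically, resamples everything onto the DCE (reference)
#' grid, and extracts the full per-contrast feature vectors. Tumors whose
#' mask degenerates under smoothing are dropped and reported in the
#' exclusion log attribute.
#'
#' @param cohort Cohort tibble (after [apply_exclusions()]).
#' @param inventory,manifest See [extract_features()].
#' @param contrasts Contrast channels to extract (all three by default;
#'   restricting saves I/O and compute for mono-contrast studies).
#' @param progress Print a dot per tumor.
#' @return A tibble with columns `tumor_id`, `contrast`, and one column
#'   per feature; attribute `exclusions` lists dropped tumors.
#' @export
extract_cohort_features <- function(cohort, inventory = feature_inventory(),
                                    manifest = feature_manifest(),
                                    contrasts = c("dce", "sub", "t2"),
                                    progress = FALSE) {
  dropped <- list()
  rows <- vector("list", nrow(cohort))
  for (k in seq_len(nrow(cohort))) {
    row <- cohort[k, ]
    res <- tryCatch({
      vs <- load_volume_set(row, contrasts)
      extract_features(vs$volumes, vs$mask, inventory, manifest,
        contrasts = contrasts)
    }, phantomics_degenerate_mask = function(e) NULL)
    if (is.null(res)) {
      dropped[[length(dropped) + 1]] <- tibble::tibble(
        tumor_id = row$tumor_id, reason = "degenerate mask"
      )
    } else {
      rows[[k]] <- dplyr::mutate(res, tumor_id = row$tumor_id,
        .before = 1)
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  out <- dplyr::bind_rows(rows)
  attr(out, "exclusions") <- dplyr::bind_rows(dropped)
  out
}
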