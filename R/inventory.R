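# Feature inventory: the ordered list of 342 named radiomic features.

glcm_feature_names <- function() {
  c(
    "autocorrelation", "joint_average", "joint_energy", "joint_entropy",
    "joint_variance", "contrast", "correlation", "cluster_shade",
    "cluster_prominence", "cluster_tendency", "difference_average",
    "difference_entropy", "difference_variance", "difference_energy",
    "sum_average", "sum_entropy", "sum_variance", "sum_energy",
    "inverse_difference", "inverse_difference_moment",
    "inverse_difference_norm", "inverse_difference_moment_norm",
    "inverse_variance", "maximum_probability", "imc1", "imc2",
    "marginal_entropy", "same_level_probability"
  )
}

glrlm_feature_names <- function() {
  c(
    "sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv", "rlv",
    "run_entropy", "lglre", "hglre", "srlgle", "srhgle", "lrlgle", "lrhgle"
  )
}

glszm_feature_names <- function() {
  c(
    "sae", "lae", "gln", "glnn", "szn", "sznn", "zp", "glv", "zv",
    "zone_entropy", "lglze", "hglze", "salgle", "sahgle", "lalgle", "lahgle"
  )
}

ngtdm_feature_names <- function() {
  c("coarseness", "contrast", "busyness", "complexity", "strength")
}

conventional_feature_names <- function() {
  c(
    # shape
    "volume_mm3", "surface_area_mm2", "surface_to_volume", "sphericity",
    "compactness1", "compactness2", "spherical_disproportion",
    "bbox_extent_x", "bbox_extent_y", "bbox_extent_z", "bbox_volume_mm3",
    "elongation", "flatness", "max_diameter_mm",
    # first-order intensity
    "mean", "sd", "skewness", "kurtosis", "min", "p10", "p25", "median",
    "p75", "p90", "max", "iqr", "range", "energy", "entropy", "rms", "mad"
  )
}

moment_feature_names <- function() {
  ords <- c(
    "200", "020", "002", "110", "101", "011",
    "300", "030", "003", "210", "201", "120", "021", "102", "012", "111"
  )
  c(paste0("eta_", ords), "inv_j1", "inv_j2", "inv_j3", "anisotropy")
}

wavelet_band_names <- function() {
  c("lll", "hll", "lhl", "hhl", "llh", "hlh", "lhh", "hhh")
}

lbp_feature_names <- function(points = 8) {
  c(
    paste0("code_", 0:points), "code_nonuniform",
    "entropy", "energy", "mean", "var", "uniform_frac", "max_frac"
  )
}

default_manifest_path <- function() {
  system.file("extdata", "feature_manifest.yaml", package = "phantomics")
}

#' Load the structural configuration of the radiomic feature set
#'
#' The manifest controls quantization levels, the gray-level co-occurrence
#' distances, the run-length/size-zone aggregation modes, the Gabor bank and
#' the number of radial frequency bands, from which the full feature
#' inventory is derived.
#'
#' @param path Path to a YAML manifest; default ships with the package.
#' @return A named list of manifest entries.
#' @export
feature_manifest <- function(path = NULL) {
  path <- path %||% default_manifest_path()
  m <- yaml::read_yaml(path)
  required <- c(
    "levels", "glcm", "glrlm", "glszm", "ngtdm", "gabor", "frequency",
    "transforms", "descriptor"
  )
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    rlang::abort(paste0("manifest missing entries: ", toString(missing)))
  }
  m
}

#' The ordered radiomic feature inventory
#'
#' Enumerates every feature the extractor computes, in extraction order,
#' with its category, its Table-style size/shape-vs-texture group, and
#' whether it depends on gray-level quantization (and is therefore averaged
#' over the six quantization levels).
#'
#' @param manifest A manifest list from [feature_manifest()], or `NULL` for
#'   the shipped default (342 features).
#' @return A tibble with columns `name`, `category`, `group`, `quantized`.
#' @examples
#' inv <- feature_inventory()
#' nrow(inv) # 342
#' dplyr::count(inv, category)
#' @export
feature_inventory <- function(manifest = NULL) {
  m <- manifest %||% feature_manifest()
  conv <- tibble::tibble(
    name = paste0("conv_", conventional_feature_names()),
    category = "conventional", quantized = FALSE
  )
  mom <- tibble::tibble(
    name = paste0("mom_", moment_feature_names()),
    category = "moments", quantized = FALSE
  )
  wav <- tidyr::expand_grid(
    band = wavelet_band_names(), stat = m$transforms$stats
  ) %>%
    dplyr::mutate(name = paste0("wav_", .data$band, "_", .data$stat)) %>%
    dplyr::transmute(.data$name, category = "transforms", quantized = FALSE)
  lbp <- tibble::tibble(
    name = paste0("lbp_", lbp_feature_names(m$descriptor$lbp_points)),
    category = "descriptor", quantized = FALSE
  )
  gab <- tidyr::expand_grid(
    f = m$gabor$frequencies, o = m$gabor$orientations_deg,
    stat = c("mean", "sd")
  ) %>%
    dplyr::mutate(
      name = sprintf("gab_f%02d_o%03d_%s", round(.data$f * 100), .data$o,
        .data$stat)
    ) %>%
    dplyr::transmute(.data$name, category = "gabor", quantized = FALSE)
  frq <- tidyr::expand_grid(
    band = seq_len(m$frequency$n_bands), stat = c("frac", "logpow")
  ) %>%
    dplyr::mutate(name = sprintf("freq_band%02d_%s", .data$band, .data$stat)) %>%
    dplyr::transmute(.data$name, category = "frequency", quantized = FALSE)
  glcm <- tidyr::expand_grid(d = m$glcm$distances, f = glcm_feature_names()) %>%
    dplyr::mutate(name = sprintf("glcm_d%d_%s", .data$d, .data$f)) %>%
    dplyr::transmute(.data$name, category = "glcm", quantized = TRUE)
  glrlm <- tidyr::expand_grid(mode = m$glrlm$modes, f = glrlm_feature_names()) %>%
    dplyr::mutate(name = sprintf("glrlm_%s_%s", .data$mode, .data$f)) %>%
    dplyr::transmute(.data$name, category = "glrlm", quantized = TRUE)
  glszm <- tidyr::expand_grid(mode = m$glszm$modes, f = glszm_feature_names()) %>%
    dplyr::mutate(name = sprintf("glszm_%s_%s", .data$mode, .data$f)) %>%
    dplyr::transmute(.data$name, category = "glszm", quantized = TRUE)
  ngtdm <- tidyr::expand_grid(d = m$ngtdm$distances, f = ngtdm_feature_names()) %>%
    dplyr::mutate(name = sprintf("ngtdm_d%d_%s", .data$d, .data$f)) %>%
    dplyr::transmute(.data$name, category = "ngtdm", quantized = TRUE)

  inv <- dplyr::bind_rows(
    conv, mom, wav, lbp, gab, frq, glcm, glrlm, glszm, ngtdm
  ) %>%
    dplyr::mutate(
      group = dplyr::if_else(
        .data$category %in% c("conventional", "moments", "transforms"),
        "size_shape", "texture"
      ),
      .after = "category"
    )
  if (anyDuplicated(inv$name)) rlang::abort("duplicate feature names")
  inv
}

# Map possibly contrast-prefixed feature names (e.g. "dce_glcm_d1_contrast")
# back to inventory rows.
strip_contrast_prefix <- function(names) {
  sub("^(dce|sub|t2)_", "", names)
}
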