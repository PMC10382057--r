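# NIfTI I/O: thin wrappers around RNifti keeping voxel spacing attached.

#' Read a NIfTI volume as a spacing-tagged array
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A 3D numeric array with a `spacing` attribute (mm per voxel).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  set_spacing(arr, sp)
}

#' Write a spacing-tagged array as NIfTI
#'
#' @param x 3D array with a `spacing` attribute, or `spacing` given.
#' @param path Output path (`.nii.gz`).
#' @param spacing Voxel spacing in mm (length 3); defaults to the attribute.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, spacing = NULL) {
  sp <- spacing_of(x, spacing)
  img <- RNifti::asNifti(array(as.numeric(x), dim = dim(x)))
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}
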