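#' Read a neuroimaging volume
#'
#' Reads a 3D NIfTI-1 volume (`.nii` / `.nii.gz`) and returns the voxel data
#' together with its geometry. Binary masks are stored as 0/1 integers and
#' density fields as floats in `[0, 1]`; both come back as plain arrays.
#'
#' @param path Path to a NIfTI file.
#' @return A list with `values` (3D array), `spacing` (mm, length 3) and
#'   `affine` (4x4 voxel-to-world matrix).
#' @export
read_volume <- function(path) {
  if (length(path) != 1 || !is.character(path) || !file.exists(path)) {
    stop_format(sprintf("Volume file not found: '%s'.", path))
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_format(sprintf(
                    "Could not read '%s' as a NIfTI volume: %s", path,
                    conditionMessage(e))))
  arr <- as.array(img)
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3) {
    stop_format(sprintf("'%s' is not a 3D volume (dims: %s).", path,
                        paste(dim(arr), collapse = "x")))
  }
  list(values = array(as.vector(arr), dim = dim(arr)),
       spacing = as.numeric(RNifti::pixdim(img))[1:3],
       affine = matrix(as.numeric(RNifti::xform(img)), 4, 4))
}

#' Write a neuroimaging volume
#'
#' Writes a 3D array as NIfTI-1. Logical arrays are stored as 8-bit 0/1;
#' numeric arrays as 32-bit floats.
#'
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param values 3D array (logical mask or numeric field).
#' @param spacing Voxel size in mm.
#' @param affine Optional 4x4 voxel-to-world matrix.
#' @return `path`, invisibly.
#' @export
write_volume <- function(path, values, spacing = c(1, 1, 1), affine = NULL) {
  if (is.null(dim(values)) || length(dim(values)) != 3) {
    stop_dimension("`values` must be a 3D array.")
  }
  if (is.logical(values)) {
    storage.mode(values) <- "integer"
    datatype <- "uint8"
  } else {
    storage.mode(values) <- "double"
    datatype <- "float"
  }
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- as.numeric(spacing)
  if (!is.null(affine)) {
    RNifti::qform(img) <- structure(affine, code = 2L)
  }
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
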