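## NIfTI I/O. Masks and dose grids travel as .nii/.nii.gz volumes whose
## sform/qform is a pure scaling + translation (axis-aligned). Rotated or
## flipped orientations are rejected rather than silently resampled, because
## resampling a binary mask would perturb the very geometric metrics under
## study.

grid_from_affine <- function(affine, dims, path) {
  rot <- affine[1:3, 1:3]
  diag_part <- diag(rot)
  off <- rot - diag(diag_part, 3, 3)
  if (any(abs(off) > 1e-6 * max(abs(diag_part), 1)))
    stop(sprintf(
      "'%s': affine encodes a rotation or shear; only axis-aligned volumes are supported",
      path))
  if (any(diag_part <= 0))
    stop(sprintf(
      "'%s': affine has non-positive scale (flipped orientation); re-export the volume axis-aligned with positive spacing",
      path))
  image_grid(dims, diag_part, affine[1:3, 4])
}

affine_from_grid <- function(grid) {
  aff <- diag(c(grid$spacing, 1))
  aff[1:3, 4] <- grid$origin
  aff
}

read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1L, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop(sprintf("'%s': expected a 3-D volume, got %s dims",
                 path, length(dim(arr))))
  affine <- RNifti::xform(img)
  list(array = arr, grid = grid_from_affine(unclass(affine), dim(arr), path))
}

write_nifti_volume <- function(arr, grid, path, datatype) {
  img <- RNifti::asNifti(arr)
  # sform only: assigning the qform as well routes the matrix through the
  # quaternion representation, which rescales the stored spacing
  RNifti::sform(img) <- structure(affine_from_grid(grid), code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a binary structure mask from a NIfTI file
#'
#' Voxels with value > 0.5 are occupied. The grid (spacing, origin) is taken
#' from the NIfTI affine, which must be axis-aligned; volumes with a rotation
#' or shear in their affine are rejected. An all-zero volume is a valid
#' (empty) mask.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param name structure label to attach; defaults to the file stem.
#' @return a [structure_mask()].
#' @export
read_mask <- function(path, name = NULL) {
  v <- read_nifti_volume(path)
  if (is.null(name))
    name <- sub("\\.nii(\\.gz)?$", "", basename(path))
  structure_mask(name, v$grid, v$array > 0.5)
}

#' Write a structure mask to a NIfTI file
#'
#' @param mask a [structure_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  write_nifti_volume(array(as.integer(mask$occupancy), dim = mask$grid$dims),
                     mask$grid, path, datatype = "uint8")
}

#' Read a dose grid (cGy) from a NIfTI file
#'
#' @param path path to a `.nii` or `.nii.gz` file of per-voxel dose in cGy.
#' @return a [dose_grid()].
#' @export
read_dose <- function(path) {
  v <- read_nifti_volume(path)
  dose_grid(v$grid, v$array)
}

#' Write a dose grid to a NIfTI file
#'
#' @param dose a [dose_grid()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dose <- function(dose, path) {
  stopifnot(inherits(dose, "dose_grid"))
  write_nifti_volume(dose$dose, dose$grid, path, datatype = "double")
}
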