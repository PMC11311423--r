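#' Voxel lattice geometry shared by masks and dose grids
#'
#' An `image_grid` describes an axis-aligned voxel lattice: the number of
#' voxels per axis, the voxel edge lengths in mm, and the world coordinate
#' (mm) of the *center* of voxel (0,0,0). Voxel indices are 0-based in world
#' arithmetic, so the center of voxel (i,j,k) sits at
#' `origin + c(i,j,k) * spacing`. No rotation is supported: all distances in
#' the package are measured in this world frame, which handles anisotropic
#' spacing uniformly.
#'
#' @param dims integer vector of length 3, voxel counts per axis (all >= 1).
#' @param spacing numeric vector of length 3, voxel edge lengths in mm
#'   (all > 0).
#' @param origin numeric vector of length 3, world position (mm) of the
#'   center of voxel (0,0,0). Defaults to the zero vector.
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(c(10, 10, 10), c(1, 1, 2))
#' voxel_volume_cc(g) # 0.002
#' @export
image_grid <- function(dims, spacing, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("`dims` must be 3 positive integers")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel edge lengths in mm")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite world coordinates in mm")
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d x %d voxels, spacing %g x %g x %g mm, origin (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Volume of one voxel in cc
#'
#' @param grid an [image_grid()].
#' @return Voxel volume in cubic centimeters (`prod(spacing)/1000`).
#' @export
voxel_volume_cc <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  prod(grid$spacing) / 1000
}

#' Do two grids describe the same lattice?
#'
#' @param a,b [image_grid()] objects.
#' @param tol absolute tolerance on spacing and origin in mm.
#' @return logical.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

## World coordinates (mm) of all voxel centers, as an n x 3 matrix in
## column-major (linear index) order.
voxel_centers <- function(grid) {
  d <- grid$dims
  cx <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  cy <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  cz <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  cbind(rep(cx, times = d[2] * d[3]),
        rep(rep(cy, each = d[1]), times = d[3]),
        rep(cz, each = d[1] * d[2]))
}

#' Named binary occupancy volume on a grid
#'
#' @param name organ or PTV label (character scalar).
#' @param grid an [image_grid()].
#' @param occupancy logical (or coercible) array whose dimensions equal
#'   `grid$dims`.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(name, grid, occupancy) {
  stopifnot(inherits(grid, "image_grid"))
  if (!is.character(name) || length(name) != 1L || is.na(name))
    stop("`name` must be a single string")
  occ <- array(as.logical(occupancy), dim = dim(occupancy))
  if (is.null(dim(occ)) || length(dim(occ)) != 3L ||
      !all(dim(occ) == grid$dims))
    stop(sprintf("occupancy shape (%s) does not match grid dims (%s) for '%s'",
                 paste(dim(occupancy), collapse = "x"),
                 paste(grid$dims, collapse = "x"), name))
  if (anyNA(occ)) stop("occupancy contains NA")
  structure(list(name = name, grid = grid, occupancy = occ),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d voxels (%.4g cc) on %dx%dx%d grid\n",
              x$name, sum(x$occupancy), mask_volume_cc(x),
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]))
  invisible(x)
}

#' Structure volume in cc
#'
#' @param mask a [structure_mask()].
#' @return occupied voxel count times voxel volume, in cc.
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$occupancy) * voxel_volume_cc(mask$grid)
}

#' Per-voxel dose in cGy on a grid
#'
#' @param grid an [image_grid()].
#' @param dose numeric array of non-negative, finite doses in cGy with
#'   dimensions equal to `grid$dims`.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(grid, dose) {
  stopifnot(inherits(grid, "image_grid"))
  dose <- array(as.numeric(dose), dim = dim(dose))
  if (is.null(dim(dose)) || length(dim(dose)) != 3L ||
      !all(dim(dose) == grid$dims))
    stop("dose shape does not match grid dims")
  if (any(!is.finite(dose))) stop("dose contains non-finite values")
  if (any(dose < 0)) stop("dose contains negative values (cGy expected)")
  structure(list(grid = grid, dose = dose), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %dx%dx%d, dose range [%.1f, %.1f] cGy\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              min(x$dose), max(x$dose)))
  invisible(x)
}
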