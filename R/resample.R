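#' Resample a dose grid onto a target lattice by trilinear interpolation
#'
#' Clinical dose grids rarely share the contour lattice, so dose (never the
#' binary masks) is resampled: the dose field is evaluated at every target
#' voxel center by trilinear interpolation between the 8 surrounding source
#' voxel centers. Target voxel centers outside the source center extent
#' receive 0 cGy and are counted in a warning; if the two extents are
#' disjoint the call errors instead.
#'
#' @param dose a [dose_grid()] on its native lattice.
#' @param target an [image_grid()] to sample onto.
#' @return a [dose_grid()] on `target`. If the grids are identical the dose
#'   values are returned unchanged.
#' @export
interpolate_dose_to_grid <- function(dose, target) {
  stopifnot(inherits(dose, "dose_grid"), inherits(target, "image_grid"))
  src <- dose$grid
  if (same_grid(src, target))
    return(dose_grid(target, dose$dose))

  # continuous 0-based source index per target axis
  tidx <- lapply(1:3, function(ax) {
    world <- target$origin[ax] + (seq_len(target$dims[ax]) - 1) * target$spacing[ax]
    (world - src$origin[ax]) / src$spacing[ax]
  })
  inside_ax <- lapply(1:3, function(ax)
    tidx[[ax]] >= 0 & tidx[[ax]] <= src$dims[ax] - 1)

  d <- target$dims
  ix <- rep(tidx[[1]], times = d[2] * d[3])
  iy <- rep(rep(tidx[[2]], each = d[1]), times = d[3])
  iz <- rep(tidx[[3]], each = d[1] * d[2])
  inside <- rep(inside_ax[[1]], times = d[2] * d[3]) &
    rep(rep(inside_ax[[2]], each = d[1]), times = d[3]) &
    rep(inside_ax[[3]], each = d[1] * d[2])

  if (!any(inside))
    stop("dose and target grid extents are disjoint; cannot interpolate")

  out <- numeric(prod(d))
  n_out <- sum(!inside)
  if (n_out > 0L)
    warning(sprintf("%d target voxel(s) outside the dose extent set to 0 cGy",
                    n_out))
  if (any(inside)) {
    ix <- ix[inside]; iy <- iy[inside]; iz <- iz[inside]
    # lower corner, clamped so the upper corner stays on the lattice
    x0 <- pmin(floor(ix), src$dims[1] - 2L); x0 <- pmax(x0, 0)
    y0 <- pmin(floor(iy), src$dims[2] - 2L); y0 <- pmax(y0, 0)
    z0 <- pmin(floor(iz), src$dims[3] - 2L); z0 <- pmax(z0, 0)
    # degenerate single-slab axes: keep corner at 0 with zero fraction
    if (src$dims[1] == 1L) x0 <- rep(0, length(ix))
    if (src$dims[2] == 1L) y0 <- rep(0, length(iy))
    if (src$dims[3] == 1L) z0 <- rep(0, length(iz))
    fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
    nx <- src$dims[1]; nxy <- src$dims[1] * src$dims[2]
    dx1 <- if (src$dims[1] > 1L) 1L else 0L
    dy1 <- if (src$dims[2] > 1L) nx else 0L
    dz1 <- if (src$dims[3] > 1L) nxy else 0L
    base <- x0 + y0 * nx + z0 * nxy + 1
    v <- as.vector(dose$dose)
    val <-
      v[base]                   * (1 - fx) * (1 - fy) * (1 - fz) +
      v[base + dx1]             * fx       * (1 - fy) * (1 - fz) +
      v[base + dy1]             * (1 - fx) * fy       * (1 - fz) +
      v[base + dx1 + dy1]       * fx       * fy       * (1 - fz) +
      v[base + dz1]             * (1 - fx) * (1 - fy) * fz +
      v[base + dx1 + dz1]       * fx       * (1 - fy) * fz +
      v[base + dy1 + dz1]       * (1 - fx) * fy       * fz +
      v[base + dx1 + dy1 + dz1] * fx       * fy       * fz
    out[inside] <- val
  }
  # interpolation of non-negative corners can only produce tiny negative
  # round-off; clamp to keep the dose-grid invariant
  out[out < 0 & out > -1e-9] <- 0
  dose_grid(target, array(out, dim = d))
}
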