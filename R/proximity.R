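## Distance from each OAR to the closest planning target volume, and
## classification against a proximity cutoff. Distances are
## surface-to-surface (minimum Euclidean distance between exposed-face
## surfel sets), clamped to 0 when the OAR overlaps a PTV voxel-wise, so
## organs abutting or inside a target are correctly reported as distance 0.

#' Distance from an OAR to the closest PTV
#'
#' @param oar a non-empty [structure_mask()].
#' @param ptvs a list of [structure_mask()] PTVs on the same grid, at least
#'   one non-empty.
#' @return list of class `proximity_result`: `distance_mm` (>= 0; 0 on
#'   voxel-wise overlap), `nearest_ptv` (label of the argmin PTV).
#' @export
distance_to_ptv <- function(oar, ptvs) {
  stopifnot(inherits(oar, "structure_mask"))
  if (inherits(ptvs, "structure_mask")) ptvs <- list(ptvs)
  ptvs <- Filter(function(p) sum(p$occupancy) > 0L, ptvs)
  if (length(ptvs) == 0L) stop("no non-empty PTV masks supplied")
  if (sum(oar$occupancy) == 0L)
    stop(sprintf("OAR '%s' is empty; distance undefined", oar$name))
  for (p in ptvs) check_same_grid(oar, p)

  # voxel-wise overlap wins immediately
  for (p in ptvs) {
    if (any(oar$occupancy & p$occupancy))
      return(structure(list(distance_mm = 0, nearest_ptv = p$name),
                       class = "proximity_result"))
  }
  so <- extract_surface(oar)
  d <- vapply(ptvs, function(p)
    cpp_min_dist_between(so$points, extract_surface(p)$points), numeric(1))
  i <- which.min(d)
  structure(list(distance_mm = d[i], nearest_ptv = ptvs[[i]]$name),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("<proximity_result> %.3f mm to '%s'\n", x$distance_mm,
              x$nearest_ptv))
  invisible(x)
}

#' Classify records against a proximity cutoff
#'
#' Sets `within_cutoff = distance_to_ptv_mm <= cutoff_mm` (inclusive: a
#' structure exactly at the cutoff counts as within). 25 mm reflects the
#' 2.5 cm review criterion; 30 mm is the tabulation cutoff.
#'
#' @param records data.frame with a `distance_to_ptv_mm` column.
#' @param cutoff_mm proximity cutoff in mm (default 25).
#' @return `records` with `within_cutoff` set.
#' @export
classify_proximity <- function(records, cutoff_mm = 25) {
  stopifnot(is.data.frame(records), "distance_to_ptv_mm" %in% names(records))
  records$within_cutoff <- records$distance_to_ptv_mm <= cutoff_mm
  records
}
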