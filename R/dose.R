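## Dosimetric indices extracted from one planned dose grid transposed over
## both contours of a pair: the near-maximum D0.01cc, the volume-weighted
## mean dose, and the organ-specific clinical-objective difference.

mask_doses <- function(dose, mask) {
  if (!same_grid(dose$grid, mask$grid))
    stop(sprintf("dose grid does not match mask grid for '%s'; resample the dose first",
                 mask$name))
  dose$dose[mask$occupancy]
}

#' Near-maximum dose D0.01cc (cGy)
#'
#' The maximum dose received by at least `volume_cc` (default 0.01 cc) of
#' the structure: voxel doses are sorted descending and whole-voxel volumes
#' accumulated until the running total first reaches `volume_cc`; the dose of
#' the last voxel included — the minimum dose within the hottest 0.01 cc —
#' is returned. Ties are broken by descending dose then ascending linear
#' voxel index, so the statistic is deterministic. Structures smaller than
#' `volume_cc` (e.g. lenses on coarse grids) fall back to the in-structure
#' minimum with a warning rather than erroring.
#'
#' @param dose a [dose_grid()] on the mask's grid.
#' @param mask a non-empty [structure_mask()].
#' @param volume_cc the hot-volume criterion in cc (default 0.01).
#' @return dose in cGy.
#' @export
dmax_d001cc <- function(dose, mask, volume_cc = 0.01) {
  dv <- mask_doses(dose, mask)
  if (length(dv) == 0L)
    stop(sprintf("D0.01cc undefined: mask '%s' is empty", mask$name))
  vv <- voxel_volume_cc(mask$grid)
  total <- length(dv) * vv
  # descending dose, ascending linear index on ties
  dv <- dv[order(-dv, seq_along(dv))]
  # tiny slack so accumulated voxel volumes that should exactly reach the
  # criterion are not defeated by floating-point rounding
  eps <- 1e-9
  if (total < volume_cc - eps) {
    warning(sprintf("structure '%s' (%.4g cc) smaller than the %.3g cc criterion; returning its minimum dose",
                    mask$name, total, volume_cc))
    return(dv[length(dv)])
  }
  n_needed <- which(cumsum(rep(vv, length(dv))) >= volume_cc - eps)[1]
  dv[n_needed]
}

#' Mean structure dose (cGy)
#'
#' Volume-weighted mean of in-structure voxel doses; with equal-volume voxels
#' this is the arithmetic mean.
#'
#' @inheritParams dmax_d001cc
#' @return dose in cGy.
#' @export
dmean <- function(dose, mask) {
  dv <- mask_doses(dose, mask)
  if (length(dv) == 0L)
    stop(sprintf("mean dose undefined: mask '%s' is empty", mask$name))
  mean(dv)
}

#' Dose statistics for one structure
#'
#' @inheritParams dmax_d001cc
#' @return list with `dmax_cgy` (D0.01cc), `dmean_cgy`, `volume_cc`.
#' @export
dose_stats <- function(dose, mask, volume_cc = 0.01) {
  list(dmax_cgy = dmax_d001cc(dose, mask, volume_cc),
       dmean_cgy = dmean(dose, mask),
       volume_cc = mask_volume_cc(mask))
}

#' Dosimetric comparison of one auto/clinical contour pair
#'
#' Applies the same dose grid over both contours and differences the
#' statistics. Signed deltas follow the auto-minus-clinical convention; all
#' cohort summaries use the absolute values, which are convention-free. The
#' clinical-objective delta is `|delta Dmax|` for organs constrained by
#' D0.01cc and `|delta Dmean|` for those constrained by mean dose.
#'
#' @param dose a [dose_grid()] on the masks' grid.
#' @param auto,clinical [structure_mask()] objects on one grid.
#' @param policy organ-to-kind mapping, see [organ_policy()].
#' @param volume_cc hot-volume criterion for D0.01cc.
#' @return list with `auto`, `clinical` ([dose_stats()] each), signed
#'   `delta_dmax_cgy`/`delta_dmean_cgy`, their absolutes, `dco_kind`, and
#'   `delta_dco_cgy` (absolute). If either mask is empty, a list with
#'   `evaluable = FALSE` and a `reason` instead.
#' @export
evaluate_pair <- function(dose, auto, clinical, policy = organ_policy(),
                          volume_cc = 0.01) {
  check_same_grid(auto, clinical)
  organ <- clinical$name
  if (sum(auto$occupancy) == 0L || sum(clinical$occupancy) == 0L) {
    which_empty <- c("auto", "clinical")[c(sum(auto$occupancy) == 0L,
                                           sum(clinical$occupancy) == 0L)]
    return(list(evaluable = FALSE,
                reason = sprintf("empty %s mask for organ '%s'",
                                 paste(which_empty, collapse = " and "), organ)))
  }
  sa <- dose_stats(dose, auto, volume_cc)
  sc <- dose_stats(dose, clinical, volume_cc)
  kind <- dco_kind_for(organ, policy)
  ddmax <- sa$dmax_cgy - sc$dmax_cgy
  ddmean <- sa$dmean_cgy - sc$dmean_cgy
  list(evaluable = TRUE, reason = NA_character_,
       auto = sa, clinical = sc,
       delta_dmax_cgy = ddmax, delta_dmean_cgy = ddmean,
       abs_delta_dmax_cgy = abs(ddmax), abs_delta_dmean_cgy = abs(ddmean),
       dco_kind = kind,
       delta_dco_cgy = if (kind == "max") abs(ddmax) else abs(ddmean))
}
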