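## Synthetic phantom cohorts: geometric organ templates, a PTV, an
## exponential dose fall-off field, and seeded auto-vs-clinical perturbations
## with ground-truth labels, so every pipeline stage is testable without
## patient data.

#' Rasterize an ellipsoid on a grid
#'
#' @param grid an [image_grid()].
#' @param center_mm world center (mm).
#' @param radii_mm semi-axes (mm), scalar or length 3.
#' @param name structure label.
#' @return a [structure_mask()]; voxel centers with normalized radius <= 1
#'   are occupied.
#' @export
ellipsoid_mask <- function(grid, center_mm, radii_mm, name = "ellipsoid") {
  radii_mm <- rep(radii_mm, length.out = 3)
  q <- lapply(1:3, function(ax) {
    x <- grid$origin[ax] + (seq_len(grid$dims[ax]) - 1) * grid$spacing[ax]
    ((x - center_mm[ax]) / radii_mm[ax])^2
  })
  occ <- outer(outer(q[[1]], q[[2]], "+"), q[[3]], "+") <= 1
  structure_mask(name, grid, occ)
}

#' Rasterize an axis-aligned tube (finite cylinder) on a grid
#'
#' Tubular organs (esophagus, spinal cord, larynx) are modeled as cylinders
#' along one axis; clinical cropping is emulated by the `truncate`
#' perturbation.
#'
#' @param grid an [image_grid()].
#' @param center_mm world center (mm).
#' @param radius_mm tube radius (mm).
#' @param half_length_mm half-length along `axis` (mm).
#' @param axis tube axis (1, 2 or 3; default 3 = axial).
#' @param name structure label.
#' @return a [structure_mask()].
#' @export
tube_mask <- function(grid, center_mm, radius_mm, half_length_mm, axis = 3,
                      name = "tube") {
  radial_axes <- setdiff(1:3, axis)
  coords <- lapply(1:3, function(ax)
    grid$origin[ax] + (seq_len(grid$dims[ax]) - 1) * grid$spacing[ax])
  q <- lapply(1:3, function(ax) {
    if (ax == axis) {
      # large value outside the length extent, 0 inside
      ifelse(abs(coords[[ax]] - center_mm[ax]) <= half_length_mm, 0, Inf)
    } else {
      ((coords[[ax]] - center_mm[ax]) / radius_mm)^2
    }
  })
  occ <- outer(outer(q[[1]], q[[2]], "+"), q[[3]], "+") <= 1
  structure_mask(name, grid, occ)
}

shift_occ <- function(occ, axis, by) {
  # shift occupancy by `by` voxels along `axis`; vacated voxels become FALSE
  if (by == 0L) return(occ)
  d <- dim(occ)
  out <- array(FALSE, dim = d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0L) 1:(n - by) else (1 - by):n
  dst <- if (by > 0L) (1 + by):n else 1:(n + by)
  if (axis == 1L) out[dst, , ] <- occ[src, , ]
  else if (axis == 2L) out[, dst, ] <- occ[, src, ]
  else out[, , dst] <- occ[, , src]
  out
}

dilate_occ <- function(occ) {
  out <- occ
  for (ax in 1:3) {
    out <- out | shift_occ(occ, ax, 1L) | shift_occ(occ, ax, -1L)
  }
  out
}

erode_occ <- function(occ) {
  out <- occ
  for (ax in 1:3) {
    out <- out & shift_occ(occ, ax, 1L) & shift_occ(occ, ax, -1L)
  }
  out
}

#' Apply a controlled perturbation to a mask
#'
#' The perturbation taxonomy mirrors how auto-contours differ from their
#' clinically edited versions: used as-is (`identity`), systematic over- or
#' under-segmentation (`dilate`/`erode`, face-connected morphology),
#' misregistration (`translate`, whole-voxel shift nearest to the requested
#' mm), cropping of slices distant from the treatment volume (`truncate`),
#' and forgotten interpolation of manual contours (`delete_slices`).
#'
#' @param mask a [structure_mask()].
#' @param kind one of `"identity"`, `"dilate"`, `"erode"`, `"translate"`,
#'   `"truncate"`, `"delete_slices"`.
#' @param magnitude iterations for dilate/erode; signed mm for translate;
#'   slice count for truncate/delete_slices. Ignored for identity.
#' @param axis translation axis (1-3), default 1.
#' @param seed optional seed for the random slice choice of
#'   `delete_slices`; other kinds are deterministic.
#' @return a [structure_mask()]; never empty (error if the perturbation
#'   would empty the mask).
#' @export
perturb <- function(mask, kind, magnitude = NULL, axis = 1L, seed = NULL) {
  stopifnot(inherits(mask, "structure_mask"))
  occ <- mask$occupancy
  out <- switch(
    kind,
    identity = occ,
    dilate = {
      k <- as.integer(magnitude)
      stopifnot(k >= 1L)
      for (i in seq_len(k)) occ <- dilate_occ(occ)
      occ
    },
    erode = {
      k <- as.integer(magnitude)
      stopifnot(k >= 1L)
      for (i in seq_len(k)) occ <- erode_occ(occ)
      occ
    },
    translate = {
      by <- as.integer(round(magnitude / mask$grid$spacing[axis]))
      shift_occ(occ, axis, by)
    },
    truncate = {
      n_clear <- as.integer(magnitude)
      stopifnot(n_clear >= 1L)
      zs <- which(apply(occ, 3L, any))
      if (n_clear >= length(zs))
        stop(sprintf("truncating %d slice(s) would empty '%s'", n_clear, mask$name))
      clear <- utils::tail(zs, n_clear)
      occ[, , clear] <- FALSE
      occ
    },
    delete_slices = {
      r <- as.integer(magnitude)
      stopifnot(r >= 1L)
      zs <- which(apply(occ, 3L, any))
      interior <- zs[zs > min(zs) & zs < max(zs)]
      if (length(interior) == 0L)
        stop(sprintf("'%s' has no interior axial slices to delete", mask$name))
      r <- min(r, length(interior))
      if (!is.null(seed)) {
        clear <- withr_seed(seed, sample(interior, r))
      } else {
        clear <- sample(interior, r)
      }
      occ[, , clear] <- FALSE
      occ
    },
    stop(sprintf("unknown perturbation kind '%s'", kind))
  )
  if (!any(out))
    stop(sprintf("perturbation '%s' emptied mask '%s'", kind, mask$name))
  structure_mask(mask$name, mask$grid, out)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic dose field with exponential fall-off from the PTV
#'
#' Prescription dose inside the PTV; outside, the dose decays as
#' `prescription * exp(-d / lambda)` with `d` the Euclidean distance (mm)
#' from the voxel center to the PTV surface, clamped below at a background
#' floor. This is the simplest monotone model of the steep gradients around
#' a target and the near-homogeneous low-dose far field. Optional Gaussian
#' noise (clamped at 0) roughens the field.
#'
#' @param grid an [image_grid()].
#' @param ptv non-empty PTV [structure_mask()] on `grid`.
#' @param prescription_cgy dose inside the PTV (cGy).
#' @param lambda_mm fall-off length (mm, > 0); 5 mm is a steep clinical
#'   gradient.
#' @param floor_cgy background floor (cGy).
#' @param noise_sd_cgy additive Gaussian noise SD (cGy, default 0 =
#'   deterministic).
#' @return a [dose_grid()].
#' @export
make_dose_field <- function(grid, ptv, prescription_cgy = 6996,
                            lambda_mm = 5, floor_cgy = 30,
                            noise_sd_cgy = 0) {
  stopifnot(inherits(grid, "image_grid"), inherits(ptv, "structure_mask"))
  if (!is.finite(lambda_mm) || lambda_mm <= 0)
    stop("`lambda_mm` must be > 0")
  if (sum(ptv$occupancy) == 0L) stop("PTV is empty")
  dose <- array(floor_cgy, dim = grid$dims)
  surf <- extract_surface(ptv)$points
  # beyond this distance the exponential is below the floor anyway
  reach_mm <- lambda_mm * log(prescription_cgy / floor_cgy)
  occ_idx <- which(ptv$occupancy, arr.ind = TRUE)
  pad <- ceiling(reach_mm / grid$spacing) + 1L
  lo <- pmax(apply(occ_idx, 2, min) - pad, 1L)
  hi <- pmin(apply(occ_idx, 2, max) + pad, grid$dims)
  sub <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                               z = lo[3]:hi[3]))
  centers <- sweep((sub - 1) * rep(grid$spacing, each = nrow(sub)), 2L,
                   grid$origin, "+")
  d <- cpp_min_dists(centers, surf)
  lin <- sub[, 1] + (sub[, 2] - 1L) * grid$dims[1] +
    (sub[, 3] - 1L) * grid$dims[1] * grid$dims[2]
  dose[lin] <- pmax(floor_cgy, prescription_cgy * exp(-d / lambda_mm))
  dose[ptv$occupancy] <- prescription_cgy
  if (noise_sd_cgy > 0)
    dose <- pmax(0, dose + stats::rnorm(length(dose), 0, noise_sd_cgy))
  dose_grid(grid, dose)
}

## Organ templates mirror head-and-neck anatomy around a mid-neck target:
## most OARs lie within 2.5 cm of the PTV, and several of those are small
## (cochlea, submandibular gland, optic nerve, spinal cord), so sizeable
## contouring errors on them produce low DSC *and* large dose differences in
## the steep gradient; the orbital structures sit in the flat far field.
default_organ_templates <- function() {
  list(
    list(name = "brainstem", shape = "ellipsoid", center = c(64, 82, 64),
         radii = c(8, 9, 10), distance_class = "overlap"),
    list(name = "brain", shape = "ellipsoid", center = c(64, 64, 100),
         radii = c(24, 22, 20), distance_class = "near"),
    list(name = "larynx", shape = "tube", center = c(64, 34, 64),
         radius = 7, half_length = 16, axis = 3, distance_class = "near"),
    list(name = "parotid_l", shape = "ellipsoid", center = c(92, 64, 64),
         radii = c(9, 7, 11), distance_class = "near"),
    list(name = "parotid_r", shape = "ellipsoid", center = c(36, 64, 64),
         radii = c(9, 7, 11), distance_class = "near"),
    list(name = "spinal_cord", shape = "tube", center = c(64, 92, 64),
         radius = 4, half_length = 30, axis = 3, distance_class = "near"),
    list(name = "cochlea_l", shape = "ellipsoid", center = c(64, 44, 64),
         radii = c(4, 4, 4), distance_class = "near"),
    list(name = "glnd_submand_l", shape = "ellipsoid", center = c(64, 64, 42),
         radii = c(6, 5, 7), distance_class = "near"),
    list(name = "optic_nerve_l", shape = "tube", center = c(40, 64, 64),
         radius = 2.5, half_length = 10, axis = 1, distance_class = "near"),
    list(name = "eye_l", shape = "ellipsoid", center = c(12, 12, 64),
         radii = c(5, 5, 5), distance_class = "far"),
    list(name = "eye_r", shape = "ellipsoid", center = c(116, 116, 64),
         radii = c(5, 5, 5), distance_class = "far"),
    list(name = "lens_l", shape = "ellipsoid", center = c(12, 12, 78),
         radii = c(3.5, 3.5, 3.5), distance_class = "far")
  )
}

#' Simulation configuration for synthetic phantom cohorts
#'
#' Defaults define the reference study conditions: a 64^3 lattice of 2 mm
#' voxels; a 12 mm spherical PTV prescribed 6996 cGy; twelve organ templates
#' spanning lens-scale (~0.2 cc) to brain-scale (~45 cc) volumes placed in
#' three distance classes (overlapping/abutting the PTV, within 25 mm, and
#' beyond 50 mm), with small structures among the near class as in
#' head-and-neck anatomy; a steep exponential fall-off (lambda = 5 mm) over
#' a 30 cGy floor; and a perturbation mix whose identity mass of 0.57
#' reproduces the typical fraction of auto-contours used clinically as-is.
#'
#' @param seed integer RNG seed.
#' @param dims,spacing,origin grid specification (see [image_grid()]).
#' @param n_patients number of phantom patients.
#' @param prescription_cgy plan prescription (cGy).
#' @param ptv_center,ptv_radius PTV sphere specification (mm).
#' @param organ_templates list of organ template specs (see
#'   `default_organ_templates`); each needs `name`, `shape`
#'   (`"ellipsoid"`/`"tube"`), `center`, size fields, and `distance_class`.
#' @param lambda_mm,floor_cgy,noise_sd_cgy dose-model parameters.
#' @param perturbation_probs named probabilities over
#'   identity/dilate/erode/translate/truncate/delete_slices; must sum to 1.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       dims = c(64, 64, 64),
                       spacing = c(2, 2, 2),
                       origin = c(0, 0, 0),
                       n_patients = 18,
                       prescription_cgy = 6996,
                       ptv_center = c(64, 64, 64),
                       ptv_radius = 12,
                       organ_templates = default_organ_templates(),
                       lambda_mm = 5,
                       floor_cgy = 30,
                       noise_sd_cgy = 0,
                       perturbation_probs = c(identity = 0.57,
                                              dilate = 0.11,
                                              erode = 0.11,
                                              translate = 0.11,
                                              truncate = 0.05,
                                              delete_slices = 0.05)) {
  if (abs(sum(perturbation_probs) - 1) > 1e-9)
    stop("perturbation probabilities must sum to 1")
  if (lambda_mm <= 0) stop("lambda_mm must be > 0")
  grid <- image_grid(dims, spacing, origin)
  extent_lo <- grid$origin
  extent_hi <- grid$origin + (grid$dims - 1) * grid$spacing
  check_fit <- function(center, reach, what) {
    if (any(center - reach < extent_lo) || any(center + reach > extent_hi))
      stop(sprintf("%s does not fit inside the grid", what))
  }
  check_fit(ptv_center, ptv_radius, "PTV")
  for (tpl in organ_templates) {
    reach <- if (tpl$shape == "ellipsoid") rep(tpl$radii, length.out = 3)
    else {
      r <- rep(tpl$radius, 3); r[tpl$axis] <- tpl$half_length; r
    }
    check_fit(tpl$center, reach, sprintf("organ '%s'", tpl$name))
  }
  structure(list(seed = as.integer(seed), grid = grid,
                 n_patients = n_patients,
                 prescription_cgy = prescription_cgy,
                 ptv_center = ptv_center, ptv_radius = ptv_radius,
                 organ_templates = organ_templates,
                 lambda_mm = lambda_mm, floor_cgy = floor_cgy,
                 noise_sd_cgy = noise_sd_cgy,
                 perturbation_probs = perturbation_probs),
            class = "sim_config")
}

rasterize_template <- function(tpl, grid) {
  if (tpl$shape == "ellipsoid")
    ellipsoid_mask(grid, tpl$center, tpl$radii, tpl$name)
  else if (tpl$shape == "tube")
    tube_mask(grid, tpl$center, tpl$radius, tpl$half_length,
              axis = tpl$axis, name = tpl$name)
  else stop(sprintf("unknown shape '%s'", tpl$shape))
}

draw_perturbation <- function(probs) {
  kind <- sample(names(probs), 1L, prob = probs)
  mag <- switch(kind,
                identity = NA_real_,
                dilate = sample(1:2, 1L),
                erode = 1,
                translate = sample(c(-1, 1), 1L) * stats::runif(1, 2, 8),
                truncate = sample(2:4, 1L),
                delete_slices = sample(1:2, 1L))
  axis <- if (kind == "translate") sample(1:3, 1L) else NA_integer_
  list(kind = kind, magnitude = mag, axis = axis)
}

#' Generate a seeded synthetic phantom cohort on disk
#'
#' Writes, per phantom patient, a dose grid, the PTV, and per-organ
#' clinical/auto mask pairs as NIfTI volumes, plus a cohort manifest JSON
#' and a ground-truth CSV of the applied perturbations and intended distance
#' classes. The clinical masks and the (noise-free) dose field come straight
#' from the templates, so changing only the seed changes the perturbation
#' draws but not the geometry. Perturbations whose drawn magnitude would
#' empty a small structure are downgraded to a 1-step dilation, recorded as
#' such in the ground truth.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created; must be empty of colliding
#'   files).
#' @return list with `manifest_path`, `ground_truth` (data.frame, also
#'   written as `ground_truth.csv`), and `out_dir`.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- config$grid

  ptv <- ellipsoid_mask(grid, config$ptv_center, rep(config$ptv_radius, 3),
                        "ptv")
  clinical_masks <- lapply(config$organ_templates, rasterize_template,
                           grid = grid)
  names(clinical_masks) <- vapply(config$organ_templates, `[[`, "", "name")
  base_dose <- make_dose_field(grid, ptv, config$prescription_cgy,
                               config$lambda_mm, config$floor_cgy,
                               noise_sd_cgy = 0)

  gt_rows <- list()
  patients <- vector("list", config$n_patients)
  withr_seed(config$seed, {
    for (i in seq_len(config$n_patients)) {
      pid <- sprintf("P%03d", i)
      dose_path <- sprintf("%s_dose.nii.gz", pid)
      ptv_path <- sprintf("%s_ptv.nii.gz", pid)
      pdose <- base_dose
      if (config$noise_sd_cgy > 0)
        pdose <- dose_grid(grid, pmax(0, base_dose$dose +
                                        stats::rnorm(length(base_dose$dose),
                                                     0, config$noise_sd_cgy)))
      write_dose(pdose, file.path(out_dir, dose_path))
      write_mask(ptv, file.path(out_dir, ptv_path))
      oars <- list()
      for (tpl in config$organ_templates) {
        clinical <- clinical_masks[[tpl$name]]
        pert <- draw_perturbation(config$perturbation_probs)
        auto <- tryCatch(
          perturb(clinical, pert$kind, pert$magnitude,
                  axis = if (is.na(pert$axis)) 1L else pert$axis),
          error = function(e) NULL)
        if (is.null(auto)) {
          pert <- list(kind = "dilate", magnitude = 1, axis = NA_integer_)
          auto <- perturb(clinical, "dilate", 1)
        }
        a_path <- sprintf("%s_%s_auto.nii.gz", pid, tpl$name)
        c_path <- sprintf("%s_%s_clinical.nii.gz", pid, tpl$name)
        write_mask(auto, file.path(out_dir, a_path))
        write_mask(clinical, file.path(out_dir, c_path))
        oars[[tpl$name]] <- list(auto = a_path, clinical = c_path)
        gt_rows[[length(gt_rows) + 1L]] <- data.frame(
          patient = pid, organ = tpl$name,
          perturbation = pert$kind,
          magnitude = if (is.na(pert$magnitude)) NA_real_ else pert$magnitude,
          axis = pert$axis,
          distance_class = tpl$distance_class,
          identical_pair = pert$kind == "identity",
          stringsAsFactors = FALSE)
      }
      patients[[i]] <- list(id = pid,
                            prescription_cgy = config$prescription_cgy,
                            dose = dose_path,
                            ptvs = list(ptv = ptv_path),
                            oars = oars)
    }
  })
  manifest <- structure(list(patients = patients), class = "cohort_manifest")
  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest(manifest, manifest_path)
  ground_truth <- do.call(rbind, gt_rows)
  utils::write.csv(ground_truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  list(manifest_path = manifest_path, ground_truth = ground_truth,
       out_dir = out_dir)
}

#' Two illustrative fixtures where geometry and dose disagree
#'
#' Fixture A: a large organ whose auto version extends a small protrusion
#' from near the PTV into the steep-gradient region — geometric agreement is
#' excellent (DSC > 0.95) yet the near-maximum dose differs by hundreds of
#' cGy, so the pair flags. Fixture B: a small organ about 2 cm from the PTV
#' in the flat far field whose auto version is substantially shrunk — poor
#' geometric agreement (DSC < 0.7) with a negligible dose difference.
#'
#' @param prescription_cgy prescription (cGy).
#' @param lambda_mm dose fall-off length (mm).
#' @param floor_cgy background floor (cGy).
#' @return named list of two fixtures, each with `patient`, `organ`, `dose`
#'   ([dose_grid()]), `ptvs`, `auto`, `clinical`, `prescription_cgy`.
#' @export
make_scenario_cases <- function(prescription_cgy = 6996, lambda_mm = 5,
                                floor_cgy = 30) {
  grid <- image_grid(c(64, 64, 64), c(2, 2, 2))
  ptv <- ellipsoid_mask(grid, c(64, 64, 64), c(12, 12, 12), "ptv")
  dose <- make_dose_field(grid, ptv, prescription_cgy, lambda_mm, floor_cgy)

  # A: brain-scale organ just outside the PTV; auto adds a small protrusion
  # reaching into the steep gradient between organ and target
  clinical_a <- ellipsoid_mask(grid, c(96, 64, 64), c(16, 14, 12), "brain")
  bump <- array(FALSE, dim = grid$dims)
  cx <- voxel_centers(grid)
  in_bump <- abs(cx[, 1] - 78) <= 1 & abs(cx[, 2] - 64) <= 3 &
    abs(cx[, 3] - 64) <= 3
  bump[in_bump] <- TRUE
  auto_a <- structure_mask("brain", grid, clinical_a$occupancy | bump)

  # B: small organ ~2 cm from the PTV in the flat far field; auto is a
  # one-step erosion (substantially smaller)
  clinical_b <- ellipsoid_mask(grid, c(64, 28, 64), c(4, 4, 4), "cochlea_l")
  auto_b <- perturb(clinical_b, "erode", 1)

  list(
    A = list(patient = "fixtureA", organ = "brain", dose = dose,
             ptvs = list(ptv), auto = auto_a, clinical = clinical_a,
             prescription_cgy = prescription_cgy),
    B = list(patient = "fixtureB", organ = "cochlea_l", dose = dose,
             ptvs = list(ptv), auto = auto_b, clinical = clinical_b,
             prescription_cgy = prescription_cgy)
  )
}

#' Evaluate a scenario fixture through the pipeline
#'
#' @param fixture one element of [make_scenario_cases()].
#' @param config an [analysis_config()].
#' @return a flagged one-row record data.frame.
#' @export
evaluate_fixture <- function(fixture, config = analysis_config()) {
  row <- evaluate_oar_pair(fixture$patient, fixture$organ, fixture$auto,
                           fixture$clinical, fixture$dose, fixture$ptvs,
                           fixture$prescription_cgy, config)
  flag_records(row, config)
}
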