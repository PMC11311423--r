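# Shared fixtures and independent brute-force oracles. The oracles here
# re-derive surfaces and distances from first principles (triple loops,
# all-pairs scans) so they share no code with the production path.

iso_grid <- function(dims = c(12, 12, 12), spacing = c(1, 1, 1),
                     origin = c(0, 0, 0)) {
  image_grid(dims, spacing, origin)
}

cube_mask <- function(grid, lo, hi, name = "cube") {
  occ <- array(FALSE, dim = grid$dims)
  occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  structure_mask(name, grid, occ)
}

random_mask <- function(grid, p = 0.15, name = "rand") {
  occ <- array(stats::runif(prod(grid$dims)) < p, dim = grid$dims)
  if (!any(occ)) occ[sample(length(occ), 1)] <- TRUE
  structure_mask(name, grid, occ)
}

random_grid <- function(dims = c(12, 12, 12)) {
  image_grid(dims,
             spacing = stats::runif(3, 0.8, 2.5),
             origin = stats::runif(3, -10, 10))
}

# Independent surfel enumeration: walk every voxel and its 6 faces.
oracle_surfels <- function(mask) {
  g <- mask$grid
  occ <- mask$occupancy
  d <- g$dims
  nbs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
               c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  pts <- list()
  wts <- numeric(0)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!occ[i, j, k]) next
    ctr <- g$origin + (c(i, j, k) - 1) * g$spacing
    for (r in seq_len(6)) {
      v <- nbs[r, ]
      q <- c(i, j, k) + v
      inside <- all(q >= 1) && all(q <= d)
      if (inside && occ[q[1], q[2], q[3]]) next
      ax <- which(v != 0)
      pts[[length(pts) + 1L]] <- ctr + v * g$spacing / 2
      wts <- c(wts, prod(g$spacing[-ax]))
    }
  }
  if (length(pts) == 0L)
    return(list(points = matrix(numeric(0), ncol = 3), weights = numeric(0)))
  list(points = do.call(rbind, pts), weights = wts)
}

# All-pairs minimum distances from rows of P to rows of Q.
oracle_min_dists <- function(P, Q) {
  apply(P, 1, function(p) sqrt(min(colSums((t(Q) - p)^2))))
}

oracle_surface_dice <- function(a, b, tau) {
  sa <- oracle_surfels(a)
  sb <- oracle_surfels(b)
  da <- oracle_min_dists(sa$points, sb$points)
  db <- oracle_min_dists(sb$points, sa$points)
  (sum(sa$weights[da <= tau]) + sum(sb$weights[db <= tau])) /
    (sum(sa$weights) + sum(sb$weights))
}

oracle_hausdorff <- function(a, b) {
  sa <- oracle_surfels(a)
  sb <- oracle_surfels(b)
  max(max(oracle_min_dists(sa$points, sb$points)),
      max(oracle_min_dists(sb$points, sa$points)))
}

oracle_distance_to_ptv <- function(oar, ptv) {
  if (any(oar$occupancy & ptv$occupancy)) return(0)
  so <- oracle_surfels(oar)
  sp <- oracle_surfels(ptv)
  min(oracle_min_dists(so$points, sp$points))
}

# Independent D0.01cc: plain sort-and-accumulate (same 1e-9 volume slack as
# the production definition).
oracle_dmax <- function(doses, voxel_cc, volume_cc) {
  s <- sort(doses, decreasing = TRUE)
  if (length(s) * voxel_cc < volume_cc - 1e-9) return(min(s))
  n <- ceiling((volume_cc - 1e-9) / voxel_cc)
  s[n]
}

# Exhaustive Wilcoxon signed-rank p (Pratt zeros): enumerate every sign
# assignment of the nonzero differences.
oracle_wilcoxon_p <- function(d) {
  r <- rank(abs(d))
  nz <- d != 0
  rnz <- r[nz]
  m <- length(rnz)
  if (m == 0L) return(1)
  w_obs <- sum(rnz[d[nz] > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  ws <- as.vector(signs %*% rnz)
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Minimal record rows for cohort-analysis unit tests.
make_records <- function(n, delta_dco = 0, dsc = 0.95, sdsc = 0.95, hd = 1,
                         dist = 10, organ = "brainstem", patient = "P001",
                         dco_kind = "max", prescription = 6996,
                         identical_pair = FALSE) {
  data.frame(patient = rep(patient, length.out = n),
             organ = rep(organ, length.out = n),
             dsc = rep(dsc, length.out = n),
             sdsc = rep(sdsc, length.out = n),
             hd_mm = rep(hd, length.out = n),
             tolerance_mm = 2,
             identical_pair = rep(identical_pair, length.out = n),
             auto_dmax_cgy = 1000, auto_dmean_cgy = 500, auto_volume_cc = 1,
             clinical_dmax_cgy = 1000 - rep(delta_dco, length.out = n),
             clinical_dmean_cgy = 500, clinical_volume_cc = 1,
             delta_dmax_cgy = rep(delta_dco, length.out = n),
             delta_dmean_cgy = 0,
             abs_delta_dmax_cgy = abs(rep(delta_dco, length.out = n)),
             abs_delta_dmean_cgy = 0,
             dco_kind = rep(dco_kind, length.out = n),
             delta_dco_cgy = abs(rep(delta_dco, length.out = n)),
             distance_to_ptv_mm = rep(dist, length.out = n),
             nearest_ptv = "ptv", within_cutoff = NA,
             flagged = NA, prescription_cgy = prescription,
             evaluable = TRUE, reason = NA_character_,
             stringsAsFactors = FALSE)
}

# Compact simulation setup for tests that only exercise plumbing.
small_sim_config <- function(seed = 1L, n_patients = 4,
                             identity_prob = 0.57) {
  probs <- c(identity = identity_prob,
             dilate = (1 - identity_prob) * 0.4,
             erode = (1 - identity_prob) * 0.2,
             translate = (1 - identity_prob) * 0.4)
  sim_config(seed = seed,
             dims = c(32, 32, 32), spacing = c(2, 2, 2),
             n_patients = n_patients,
             ptv_center = c(32, 32, 32), ptv_radius = 8,
             organ_templates = list(
               list(name = "brainstem", shape = "ellipsoid",
                    center = c(32, 48, 32), radii = c(5, 6, 7),
                    distance_class = "near"),
               list(name = "cochlea_l", shape = "ellipsoid",
                    center = c(14, 32, 32), radii = c(4, 4, 4),
                    distance_class = "near"),
               list(name = "spinal_cord", shape = "tube",
                    center = c(32, 14, 32), radius = 3, half_length = 12,
                    axis = 3, distance_class = "near")),
             perturbation_probs = probs)
}
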