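make_dose_on <- function(g, values) dose_grid(g, array(values, dim = g$dims))

test_that("D0.01cc matches hand-worked examples", {
  # uniform field: any hot volume sees the same dose
  g <- iso_grid(c(10, 10, 10))  # 1 mm voxels, 0.001 cc each
  m <- cube_mask(g, c(1, 1, 1), c(10, 10, 10), "brain")
  d <- make_dose_on(g, 5000)
  expect_equal(dmax_d001cc(d, m), 5000)

  # 100 voxels with distinct doses 1..100: hottest 10 voxels (0.01 cc) are
  # 91..100, so the statistic is 91
  g2 <- image_grid(c(100, 1, 1), c(1, 1, 1))
  m2 <- structure_mask("brainstem", g2, array(TRUE, dim = c(100, 1, 1)))
  d2 <- dose_grid(g2, array(1:100, dim = c(100, 1, 1)))
  expect_equal(dmax_d001cc(d2, m2), 91)

  # sub-criterion structure falls back to its minimum, with a warning
  g3 <- image_grid(c(5, 1, 1), c(1, 1, 1))  # 0.005 cc total
  m3 <- structure_mask("lens_l", g3, array(TRUE, dim = c(5, 1, 1)))
  d3 <- dose_grid(g3, array(c(10, 20, 30, 40, 50), dim = c(5, 1, 1)))
  expect_warning(v <- dmax_d001cc(d3, m3), "smaller")
  expect_equal(v, 10)

  empty <- structure_mask("e", g, array(FALSE, dim = g$dims))
  expect_error(dmax_d001cc(d, empty), "empty")
})

test_that("D0.01cc limits: volume -> 0 gives the max, volume = structure gives the min", {
  g <- image_grid(c(50, 1, 1), c(1, 1, 1))
  m <- structure_mask("x", g, array(TRUE, dim = c(50, 1, 1)))
  set.seed(41)
  doses <- sample(1000, 50)
  d <- dose_grid(g, array(doses, dim = c(50, 1, 1)))
  expect_equal(dmax_d001cc(d, m, volume_cc = 1e-9), max(doses))
  expect_equal(dmax_d001cc(d, m, volume_cc = 0.05), min(doses))
})

test_that("D0.01cc matches the brute-force oracle on random draws", {
  set.seed(42)
  for (i in 1:60) {
    nvox <- sample(3:200, 1)
    g <- image_grid(c(nvox, 1, 1), runif(3, 0.5, 3))
    m <- structure_mask("x", g, array(TRUE, dim = c(nvox, 1, 1)))
    doses <- round(runif(nvox) * 7000, 1)
    d <- dose_grid(g, array(doses, dim = c(nvox, 1, 1)))
    vv <- voxel_volume_cc(g)
    expected <- oracle_dmax(doses, vv, 0.01)
    got <- if (nvox * vv < 0.01 - 1e-9)
      suppressWarnings(dmax_d001cc(d, m)) else dmax_d001cc(d, m)
    expect_equal(got, expected)
  }
})

test_that("superset monotonicity: growing a structure cannot lower D0.01cc", {
  set.seed(43)
  g <- iso_grid(c(12, 12, 12))
  d <- make_dose_on(g, runif(12^3) * 7000)
  for (i in 1:5) {
    b <- random_mask(g, 0.1, "b")
    a <- perturb(b, "dilate", 1)  # a strictly contains b
    expect_gte(dmax_d001cc(d, a), dmax_d001cc(d, b))
  }
})

test_that("dmean matches arithmetic means and scales linearly with dose", {
  g <- iso_grid(c(10, 10, 10))
  m <- cube_mask(g, c(1, 1, 1), c(10, 10, 10), "larynx")
  expect_equal(dmean(make_dose_on(g, 5000), m), 5000)

  half <- array(0, dim = g$dims); half[1:5, , ] <- 100
  expect_equal(dmean(dose_grid(g, half), m), 50)

  g2 <- image_grid(c(100, 1, 1), c(1, 1, 1))
  m2 <- structure_mask("x", g2, array(TRUE, dim = c(100, 1, 1)))
  d2 <- dose_grid(g2, array(1:100, dim = c(100, 1, 1)))
  expect_equal(dmean(d2, m2), 50.5)
  d2a <- dose_grid(g2, array(3 * (1:100), dim = c(100, 1, 1)))
  expect_equal(dmean(d2a, m2), 3 * 50.5)
})

test_that("evaluate_pair differences the two contour sets under one dose grid", {
  g <- image_grid(c(4, 1, 1), c(3, 2, 2))  # 0.012 cc voxels (>= 0.01)
  d <- dose_grid(g, array(c(100, 200, 500, 50), dim = c(4, 1, 1)))
  clinical <- structure_mask("brainstem", g,
                             array(c(TRUE, TRUE, FALSE, FALSE), dim = c(4, 1, 1)))
  auto <- structure_mask("brainstem", g,
                         array(c(TRUE, TRUE, TRUE, FALSE), dim = c(4, 1, 1)))
  res <- evaluate_pair(d, auto, clinical)
  expect_true(res$evaluable)
  expect_equal(res$delta_dmax_cgy, 300)   # 500 vs 200
  expect_equal(res$dco_kind, "max")
  expect_equal(res$delta_dco_cgy, 300)
  expect_gt(res$delta_dmean_cgy, 0)       # superset reached higher dose

  same <- evaluate_pair(d, clinical, clinical)
  expect_equal(same$delta_dmax_cgy, 0)
  expect_equal(same$delta_dco_cgy, 0)
})

test_that("the clinical-objective kind follows the organ policy", {
  g <- image_grid(c(4, 1, 1), c(3, 2, 2))
  d <- dose_grid(g, array(c(100, 200, 500, 50), dim = c(4, 1, 1)))
  clinical <- structure_mask("larynx", g,
                             array(c(TRUE, TRUE, FALSE, FALSE), dim = c(4, 1, 1)))
  auto <- structure_mask("larynx", g,
                         array(c(TRUE, TRUE, TRUE, FALSE), dim = c(4, 1, 1)))
  res <- evaluate_pair(d, auto, clinical)
  expect_equal(res$dco_kind, "mean")
  expect_equal(res$delta_dco_cgy, abs(res$delta_dmean_cgy))

  pol <- organ_policy()
  expect_setequal(names(pol)[pol == "mean"],
                  c("larynx", "glnd_submand_l", "glnd_submand_r",
                    "parotid_l", "parotid_r"))
  expect_equal(sum(pol == "max"), 14)
})

test_that("empty masks yield an unevaluable record instead of an error", {
  g <- iso_grid(c(4, 4, 4))
  d <- make_dose_on(g, 100)
  full <- cube_mask(g, c(1, 1, 1), c(3, 3, 3), "eye_l")
  empty <- structure_mask("eye_l", g, array(FALSE, dim = g$dims))
  res <- evaluate_pair(d, empty, full)
  expect_false(res$evaluable)
  expect_match(res$reason, "auto")
  expect_match(res$reason, "eye_l")
})
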