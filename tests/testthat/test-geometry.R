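test_that("surfel extraction enumerates exposed faces with area weights", {
  g <- iso_grid(c(12, 12, 12))
  single <- cube_mask(g, c(5, 5, 5), c(5, 5, 5))
  s <- extract_surface(single)
  expect_equal(nrow(s$points), 6)
  expect_equal(s$weights, rep(1, 6))
  expect_equal(s$total_area, 6)

  block <- cube_mask(g, c(5, 5, 5), c(6, 6, 6))
  s2 <- extract_surface(block)
  expect_equal(nrow(s2$points), 24)
  expect_equal(s2$total_area, 24)

  empty <- structure_mask("none", g, array(FALSE, dim = g$dims))
  s3 <- extract_surface(empty)
  expect_equal(nrow(s3$points), 0)
  expect_equal(s3$total_area, 0)
})

test_that("surfel weights honor anisotropic spacing and grid-edge faces count", {
  g <- image_grid(c(3, 3, 3), c(1, 2, 4))
  m <- cube_mask(g, c(1, 1, 1), c(1, 1, 1))  # voxel at the grid corner
  s <- extract_surface(m)
  expect_equal(nrow(s$points), 6)  # corner voxel still closed
  # face areas: x-faces 2*4, y-faces 1*4, z-faces 1*2
  expect_setequal(s$weights, c(8, 8, 4, 4, 2, 2))
  expect_equal(s$total_area, 28)
})

test_that("dice matches hand-computed overlaps and rejects degenerate input", {
  g <- image_grid(c(20, 12, 12), c(1, 1, 1))
  a <- cube_mask(g, c(1, 1, 1), c(10, 10, 10), "a")
  b <- cube_mask(g, c(6, 1, 1), c(15, 10, 10), "b")
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0.5)  # 500 shared of 1000 + 1000
  expect_equal(dice(b, a), 0.5)

  disjoint <- cube_mask(g, c(15, 1, 1), c(20, 10, 10), "d")
  expect_equal(dice(a, disjoint), 0)

  empty <- structure_mask("e", g, array(FALSE, dim = g$dims))
  expect_error(dice(empty, empty), "empty")
  g2 <- image_grid(c(20, 12, 12), c(2, 1, 1))
  expect_error(dice(a, cube_mask(g2, c(1, 1, 1), c(2, 2, 2))), "same grid")
})

test_that("surface dice is 1 for identical, 0 for far-apart, 1 for 1-voxel dilation at 2 mm", {
  g <- iso_grid(c(16, 16, 16))
  a <- cube_mask(g, c(3, 3, 3), c(7, 7, 7), "a")
  expect_equal(surface_dice(a, a, 0), 1)
  far <- cube_mask(g, c(13, 13, 13), c(15, 15, 15), "far")
  expect_equal(surface_dice(a, far, 2), 0)

  dil <- perturb(a, "dilate", 1)
  # every surfel of the dilation is within 2 mm of the original surface and
  # vice versa (verified by the brute-force oracle)
  expect_equal(surface_dice(a, dil, 2), 1)
  expect_equal(oracle_surface_dice(a, dil, 2), 1)

  empty <- structure_mask("e", g, array(FALSE, dim = g$dims))
  expect_error(surface_dice(a, empty, 2), "empty")
})

test_that("surface dice is non-decreasing in the tolerance", {
  set.seed(31)
  g <- iso_grid(c(10, 10, 10))
  for (i in 1:5) {
    a <- random_mask(g, 0.2, "a")
    b <- random_mask(g, 0.2, "b")
    taus <- c(0, 0.5, 1, 2, 4, 8)
    vals <- vapply(taus, function(t) surface_dice(a, b, t), numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("hausdorff matches analytic values on cubes and single voxels", {
  g <- image_grid(c(20, 12, 12), c(1, 1, 1))
  a <- cube_mask(g, c(1, 1, 1), c(10, 10, 10), "a")
  b <- cube_mask(g, c(6, 1, 1), c(15, 10, 10), "b")
  expect_equal(hausdorff(a, a), 0)
  expect_equal(hausdorff(a, b), 5)

  # single voxels with centers 10 mm apart: the directed max-of-min runs
  # from each voxel's far face to the other's near face, 10 mm (the *minimum*
  # surface gap, 9 mm, is what distance_to_ptv reports instead)
  v1 <- cube_mask(g, c(3, 6, 6), c(3, 6, 6), "v1")
  v2 <- cube_mask(g, c(13, 6, 6), c(13, 6, 6), "v2")
  expect_equal(oracle_hausdorff(v1, v2), 10)
  expect_equal(hausdorff(v1, v2), 10)
  expect_equal(distance_to_ptv(v1, list(v2))$distance_mm, 9)
})

test_that("a 1-voxel offset at 2.5 mm spacing measures 2.5 mm, not 1", {
  g <- image_grid(c(12, 8, 8), c(2.5, 1, 1))
  a <- cube_mask(g, c(3, 3, 3), c(5, 5, 5), "a")
  b <- cube_mask(g, c(4, 3, 3), c(6, 5, 5), "b")
  expect_equal(hausdorff(a, b), 2.5)
})

test_that("translating an interior convex shape by t mm gives HD exactly t", {
  g <- iso_grid(c(24, 24, 24))
  a <- cube_mask(g, c(5, 5, 5), c(10, 10, 10), "a")
  for (t in c(3, 5, 8)) {
    b <- perturb(a, "translate", t, axis = 2)
    expect_equal(hausdorff(a, b), t)
  }
})

test_that("dice, surface dice and hausdorff are symmetric on random masks", {
  set.seed(32)
  g <- random_grid(c(10, 10, 10))
  for (i in 1:8) {
    a <- random_mask(g, 0.2, "a")
    b <- random_mask(g, 0.2, "b")
    expect_identical(dice(a, b), dice(b, a))
    expect_equal(surface_dice(a, b, 2), surface_dice(b, a, 2),
                 tolerance = 1e-15)
    expect_equal(hausdorff(a, b), hausdorff(b, a), tolerance = 1e-15)
  }
})

test_that("production metrics match the exhaustive surfel oracle on random masks", {
  set.seed(33)
  for (i in 1:12) {
    g <- random_grid(c(10, 10, 10))
    a <- random_mask(g, 0.18, "a")
    b <- random_mask(g, 0.18, "b")
    tau <- runif(1, 0.5, 4)
    expect_equal(surface_dice(a, b, tau), oracle_surface_dice(a, b, tau),
                 tolerance = 1e-9)
    expect_equal(hausdorff(a, b), oracle_hausdorff(a, b), tolerance = 1e-9)
  }
})

test_that("compare_pair bundles the metrics and short-circuits identical pairs", {
  g <- image_grid(c(20, 12, 12), c(1, 1, 1))
  a <- cube_mask(g, c(1, 1, 1), c(10, 10, 10), "brain")
  res <- compare_pair(a, a, 2)
  expect_identical(c(res$dsc, res$sdsc, res$hd_mm), c(1, 1, 0))
  expect_true(res$identical)

  b <- cube_mask(g, c(6, 1, 1), c(15, 10, 10), "brain")
  res2 <- compare_pair(a, b, 2)
  expect_false(res2$identical)
  expect_equal(res2$dsc, 0.5)
  expect_equal(res2$hd_mm, 5)
  expect_equal(res2$sdsc, oracle_surface_dice(a, b, 2), tolerance = 1e-9)

  empty <- structure_mask("brainstem", g, array(FALSE, dim = g$dims))
  expect_error(compare_pair(empty, a, 2), "brainstem|brain")
})
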