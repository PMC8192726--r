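test_that("seed scaling halves coordinates and drops conflicted coarse voxels", {
  s <- seed_set(fg = rbind(c(10, 10, 10)), bg = rbind(c(40, 0, 0)))
  s1 <- scale_seeds_to_level(s, 1)
  expect_equal(s1$fg, matrix(c(5L, 5L, 5L), 1))
  expect_equal(s1$bg, matrix(c(20L, 0L, 0L), 1))
  expect_identical(scale_seeds_to_level(s, 0)$fg, s$fg)

  clash <- seed_set(fg = rbind(c(2, 0, 0)), bg = rbind(c(3, 0, 0)))
  c1 <- scale_seeds_to_level(clash, 1)
  expect_equal(nrow(c1$fg), 0)
  expect_equal(nrow(c1$bg), 0)
  expect_equal(attr(c1, "conflicts"), matrix(c(1L, 0L, 0L), 1))
})

test_that("homogeneity classification respects both probabilities and seeds", {
  cfg <- hierarchy_config()
  expect_equal(classify_homogeneous(rep(1, 8), FALSE, FALSE, cfg), "foreground")
  expect_equal(classify_homogeneous(rep(0.999, 8), FALSE, TRUE, cfg), "mixed")
  expect_equal(classify_homogeneous(c(0, 1), FALSE, FALSE, cfg), "mixed")
  expect_equal(classify_homogeneous(rep(0.005, 8), FALSE, FALSE, cfg), "background")
  expect_equal(classify_homogeneous(rep(0.005, 8), TRUE, FALSE, cfg), "mixed")
})

test_that("coarse boundary sampling honors constants, sides, and interpolation", {
  g <- voxel_grid(array(runif(64^3), c(64, 64, 64)))
  pyr <- build_octree(g, 32)
  seeds <- seed_set(fg = rbind(c(5, 32, 32)), bg = rbind(c(60, 32, 32)))
  prob <- run_hierarchical_rw(pyr, seeds)

  expect_error(boundary_from_coarse(prob, prob$n_levels - 1, c(0, 0, 0)),
               "no parent")

  # overwrite the coarse level with synthetic maps to probe the sampling
  const <- array(1, c(32, 32, 32))
  hiervess:::put_region_brick(prob$store, 1L, c(0L, 0L, 0L), const)
  b <- boundary_from_coarse(prob, 0, c(0, 0, 0), mode = "nearest")
  expect_true(all(b$values == 1))

  halves <- array(rep(c(0, 1), each = 16), c(32, 32, 32))
  hiervess:::put_region_brick(prob$store, 1L, c(0L, 0L, 0L), halves)
  bn <- boundary_from_coarse(prob, 0, c(0, 0, 0), mode = "nearest")
  expect_true(all(bn$values %in% c(0, 1)))
  # halo voxels (0-based x = 32, the ring outside brick 0) map to parent
  # x >= 16 -> value 1
  expect_true(all(bn$values[bn$coords[, 1] == 32] == 1))
  expect_true(all(bn$values[bn$coords[, 1] < 30] == 0))

  bt <- boundary_from_coarse(prob, 0, c(0, 0, 0), mode = "trilinear")
  ring <- bt$coords[, 2] == 0 & bt$coords[, 3] == 10
  xs <- bt$coords[ring, 1]
  vals <- bt$values[ring][order(xs)]
  expect_true(all(diff(vals) >= -1e-12))        # monotone across the interface
  expect_true(any(vals > 0 & vals < 1))         # genuinely interpolated
})

test_that("single-brick volumes reproduce the flat solver bit for bit", {
  set.seed(21)
  a <- array(runif(16^3, 0, 255), c(16, 16, 16))
  g <- voxel_grid(a)
  seeds <- seed_set(fg = rbind(c(2, 8, 8)), bg = rbind(c(13, 8, 8)))
  pyr <- build_octree(g, 32)
  expect_equal(pyr$n_levels, 1L)
  prob <- run_hierarchical_rw(pyr, seeds)
  oracle <- flat_rw_oracle(g, seeds,
                           rw_config(intensity_scale = diff(range(a))))
  expect_identical(prob_level_array(prob, 0), oracle)
})

test_that("hierarchical and flat masks agree on a multi-brick phantom", {
  gt <- generate_tree(small_phantom(3))
  grid <- rasterize_phantom(gt)
  seeds <- make_seed_file(gt, 3, 4)
  pyr <- build_octree(grid, 32)
  prob <- run_hierarchical_rw(pyr, seeds)
  oracle <- flat_rw_oracle(grid, seeds,
                           rw_config(intensity_scale = diff(range(grid$intensities))))
  mh <- prob_level_array(prob, 0) >= 0.5
  mo <- oracle >= 0.5
  expect_lt(mean(mh != mo), 0.01)
  dice <- 2 * sum(mh & gt$mask) / (sum(mh) + sum(gt$mask))
  expect_gt(dice, 0.95)
})

test_that("homogeneous octants are pruned at the coarsest possible level", {
  # tube confined to one octant of a 64^3 volume
  m <- array(FALSE, c(64, 64, 64))
  m <- paint_tube(m, c(6, 16, 16), c(28, 16, 16), 5)
  grid <- mask_to_grid(m)
  seeds <- seed_set(fg = rbind(c(15, 15, 15)),
                    bg = rbind(c(50, 50, 50), c(40, 16, 16), c(16, 48, 16)))
  pyr <- build_octree(grid, 32)
  prob <- run_hierarchical_rw(pyr, seeds)
  st <- segmentation_stats(prob)
  l0 <- st[st$level == 0, ]
  expect_gt(l0$determined, 0)
  expect_lt(l0$solved / (l0$solved + l0$determined), 0.4)
  # pruned bricks agree with the thresholded flat result
  oracle <- flat_rw_oracle(grid, seeds,
                           rw_config(intensity_scale = diff(range(grid$intensities))))
  mh <- threshold_segmentation(prob)
  expect_lt(mean(mh != (oracle >= 0.5)), 0.001)
})

test_that("threshold uses >= with ties going to foreground", {
  # constant 1 x 1 x 9 chain seeded at both ends: p is linear in x and the
  # center voxel sits exactly at 0.5
  g <- voxel_grid(array(150, c(9, 8, 8)))
  pyr <- build_octree(g, 8)
  yz <- as.matrix(expand.grid(y = 0:7, z = 0:7))
  seeds <- seed_set(fg = cbind(0, yz), bg = cbind(8, yz))
  prob <- run_hierarchical_rw(pyr, seeds)
  p <- prob_level_array(prob, 0)
  expect_equal(p[5, 4, 4], 0.5, tolerance = 1e-6)
  m <- threshold_segmentation(prob)
  expect_identical(m, p >= 0.5)
  expect_true(all(m[abs(p - 0.5) < 1e-9]))      # tie -> foreground
  # thresholding the complement gives the complement up to the tie set
  ties <- abs(p - 0.5) < 1e-9
  expect_identical((1 - p >= 0.5)[!ties], (!m)[!ties])
})

test_that("brick processing order does not change the result", {
  gt <- generate_tree(small_phantom(5))
  grid <- rasterize_phantom(gt)
  seeds <- make_seed_file(gt, 2, 3)
  pyr <- build_octree(grid, 32)
  p1 <- run_hierarchical_rw(pyr, seeds)
  p2 <- run_hierarchical_rw(pyr, seeds, order_seed = 99)
  p3 <- run_hierarchical_rw(pyr, seeds)   # determinism of repeated runs
  expect_identical(prob_level_array(p1, 0), prob_level_array(p2, 0))
  expect_identical(prob_level_array(p1, 0), prob_level_array(p3, 0))
})

test_that("segmentation refuses to start without both seed classes", {
  g <- voxel_grid(array(runif(16^3), c(16, 16, 16)))
  pyr <- build_octree(g, 32)
  expect_error(run_hierarchical_rw(pyr, seed_set(fg = rbind(c(1, 1, 1)))),
               "background")
})
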