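test_that("phantoms are deterministic per seed", {
  spec <- small_phantom(9, noise = 12)
  g1 <- generate_tree(spec); g2 <- generate_tree(spec)
  expect_identical(g1$segments, g2$segments)
  expect_identical(g1$mask, g2$mask)
  v1 <- rasterize_phantom(g1); v2 <- rasterize_phantom(g2)
  expect_identical(v1$intensities, v2$intensities)
  s1 <- make_seed_file(g1, 2, 3); s2 <- make_seed_file(g2, 2, 3)
  expect_identical(s1$fg, s2$fg)
  expect_identical(s1$bg, s2$bg)
})

test_that("sequential bifurcation insertion gives n+1 leaves", {
  gt0 <- generate_tree(small_phantom(1, nb = 0))
  expect_equal(nrow(gt0$segments), 1)
  expect_equal(gt0$totals$n_leaves, 1)

  gt5 <- generate_tree(topology_spec(5, seed = 3))
  expect_equal(gt5$totals$n_bifurcations, 5)
  expect_equal(gt5$totals$n_leaves, 6)
  real <- gt5$segments[!gt5$segments$stub, ]
  expect_equal(nrow(real), 2 * 5 + 1)
  # leaves = segments that are nobody's parent
  leaves <- setdiff(real$id, real$parent)
  expect_equal(length(leaves), 6)
  # child/parent radius ratio is the configured decay
  kids <- real[real$parent > 0, ]
  expect_equal(kids$radius_um / real$radius_um[match(kids$parent, real$id)],
               rep(0.8, nrow(kids)))
})

test_that("solid rasterization matches the analytic tube volume", {
  spec <- small_phantom(4, nb = 0)
  gt <- generate_tree(spec)
  grid <- rasterize_phantom(gt)
  bright <- sum(grid$intensities > 100)
  # tubes are rendered as capsules: cylinder plus two hemispherical caps
  r <- gt$segments$radius_um
  capsule <- pi * r^2 * gt$segments$length_um + 4 / 3 * pi * r^3
  expect_lt(abs(bright - capsule / prod(spec$spacing)) * prod(spec$spacing) / capsule,
            0.1)
})

test_that("hollow mode shows the double-line profile of a lumenized vessel", {
  spec <- phantom_spec(rng_seed = 2, dims = c(64, 64, 64), spacing = c(2, 2, 2),
                       n_bifurcations = 0, radius_root_um = 14,
                       wall_mode = "hollow", wall_thickness_frac = 0.35)
  gt <- generate_tree(spec)
  grid <- rasterize_phantom(gt)
  # profile across the tube at the root midpoint
  sf <- gt$segments
  mid <- (c(sf$ax, sf$ay, sf$az) + c(sf$bx, sf$by, sf$bz)) / 2
  vx <- pmax(1, round(mid / spec$spacing))
  profile <- grid$intensities[vx[1], , vx[3]]
  bright <- which(profile > 100)
  expect_gt(length(bright), 1)
  inner <- profile[(min(bright) + 2):(max(bright) - 2)]
  expect_true(any(inner < 100))          # dark lumen between two bright walls
  runs <- rle(profile > 100)
  expect_equal(sum(runs$values), 2)      # exactly two bright bands

  # the true mask still covers the lumen (outer tube)
  expect_true(all(grid$intensities[!gt$mask] < 100 + 3 * spec$noise_sigma))
})

test_that("derived seeds are inside the vessel and clear of its surface", {
  gt <- generate_tree(small_phantom(6))
  seeds <- make_seed_file(gt, 3, 5)
  expect_true(all(gt$mask[seeds$fg + 1L]))
  d_out <- distance_transform(!gt$mask, gt$spec$spacing)
  expect_true(all(d_out[seeds$bg + 1L] > 3 * max(gt$spec$spacing)))
  expect_warning(make_seed_file(gt, 0, 0), "empty seed set")
})

test_that("the full pipeline recovers mask and length from a noisy phantom", {
  spec <- phantom_spec(rng_seed = 8, dims = c(96, 96, 96), spacing = c(2, 2, 2),
                       n_bifurcations = 2, radius_root_um = 12,
                       radius_decay = 0.8,
                       noise_sigma = 0.2 * 190)   # sigma = 0.2 x contrast
  gt <- generate_tree(spec)
  grid <- rasterize_phantom(gt)
  seeds <- make_seed_file(gt, 3, 6)
  pyr <- build_octree(grid, 32)
  prob <- run_hierarchical_rw(pyr, seeds)
  mask <- remove_spurious_and_fill(median_smooth(threshold_segmentation(prob), 1))
  dice <- 2 * sum(mask & gt$mask) / (sum(mask) + sum(gt$mask))
  expect_gt(dice, 0.9)

  # noise-free counterpart: total centerline length within 10% of truth
  spec0 <- phantom_spec(rng_seed = 8, dims = c(96, 96, 96), spacing = c(2, 2, 2),
                        n_bifurcations = 2, radius_root_um = 12,
                        radius_decay = 0.8, noise_sigma = 0)
  gt0 <- generate_tree(spec0)
  gp <- mask_to_pruned_graph(gt0$mask, spec0$spacing)
  got <- sum(segment_table(gp)$length_um)
  expect_lt(abs(got - gt0$totals$total_length_um) / gt0$totals$total_length_um, 0.1)
})
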