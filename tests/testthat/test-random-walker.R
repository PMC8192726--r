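test_that("edge weights are Gaussian in the normalized difference, symmetric", {
  cfg <- rw_config(beta = 90, intensity_scale = 1)
  expect_equal(edge_weight(0.3, 0.3, cfg), 1 + cfg$w_min)
  set.seed(2)
  a <- runif(50); b <- runif(50)
  expect_equal(edge_weight(a, b, cfg), edge_weight(b, a, cfg))
  cfg2 <- rw_config(beta = 90, intensity_scale = 100)
  expect_equal(edge_weight(0, 100, cfg2), exp(-90) + cfg2$w_min)
  expect_true(all(edge_weight(a, b, cfg) > 0))
  expect_true(all(edge_weight(a, b, cfg) <= 1 + cfg$w_min))
})

test_that("uniform chains give the harmonic interpolant between seeds", {
  p3 <- solve_random_walker(array(5, c(1, 1, 3)),
                            seed_set(fg = rbind(c(0, 0, 0)),
                                     bg = rbind(c(0, 0, 2))))
  expect_equal(as.vector(p3), c(1, 0.5, 0), tolerance = 1e-6)

  p4 <- solve_random_walker(array(5, c(1, 1, 4)),
                            seed_set(fg = rbind(c(0, 0, 0)),
                                     bg = rbind(c(0, 0, 3))))
  expect_equal(as.vector(p4), c(1, 2 / 3, 1 / 3, 0), tolerance = 1e-6)
})

test_that("constant boundary values extend harmonically as a constant", {
  d <- c(4, 4, 4)
  sh <- which(array(TRUE, d), arr.ind = TRUE)
  on_shell <- apply(sh, 1, function(v) any(v == 1 | v == 4))
  bnd <- list(coords = sh[on_shell, ] - 1L,
              values = rep(0.8, sum(on_shell)))
  p <- solve_random_walker(array(1, d), seed_set(), boundary = bnd)
  expect_equal(range(p), c(0.8, 0.8), tolerance = 1e-6)
})

test_that("a sharp intensity step blocks the walker", {
  a <- array(c(200, 200, 10, 10), c(1, 1, 4))
  p <- solve_random_walker(a, seed_set(fg = rbind(c(0, 0, 0)),
                                       bg = rbind(c(0, 0, 3))),
                           cfg = rw_config(beta = 90))
  expect_equal(as.vector(p), c(1, 1, 0, 0), tolerance = 1e-2)
})

test_that("iterative solution matches a dense direct solve on small grids", {
  set.seed(7)
  for (d in list(c(5, 4, 3), c(8, 8, 8), c(12, 12, 12))) {
    intens <- array(runif(prod(d), 0, 255), d)
    fg <- rbind(c(0, 0, 0))
    bg <- rbind(d - 1L, c(0, d[2] - 1L, 0))
    cfg <- rw_config()
    p_it <- flat_rw_oracle(voxel_grid(intens), seed_set(fg, bg), cfg)
    p_dn <- dense_rw_solve(intens, c(1, 1, 1), fg, bg, cfg)
    expect_lt(max(abs(p_it - p_dn)), 1e-6)
  }
})

test_that("probabilities satisfy range, clamping, harmonicity and maximum principle", {
  set.seed(9)
  d <- c(16, 16, 16)
  intens <- array(runif(prod(d), 0, 255), d)
  fg <- rbind(c(3, 3, 3))
  bg <- rbind(c(12, 12, 12))
  cfg <- rw_config()
  p <- flat_rw_oracle(voxel_grid(intens), seed_set(fg, bg), cfg)

  expect_true(all(p >= 0 & p <= 1))
  expect_equal(p[4, 4, 4], 1)
  expect_equal(p[13, 13, 13], 0)

  # harmonicity: every unconstrained voxel is the weighted mean of its
  # neighbors, computed here independently
  scale <- diff(range(intens))
  cfg$intensity_scale <- scale
  worst <- 0
  for (x in 1:16) for (y in 1:16) for (z in 1:16) {
    if ((x == 4 && y == 4 && z == 4) || (x == 13 && y == 13 && z == 13)) next
    ws <- 0; acc <- 0
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      q <- c(x, y, z) + o
      if (any(q < 1 | q > 16)) next
      w <- edge_weight(intens[x, y, z], intens[q[1], q[2], q[3]], cfg)
      ws <- ws + w
      acc <- acc + w * p[q[1], q[2], q[3]]
    }
    worst <- max(worst, abs(p[x, y, z] - acc / ws))
  }
  expect_lt(worst, 10 * cfg$solver_tol)

  # maximum principle on the interior
  expect_true(all(p <= 1 & p >= 0))

  # complement symmetry under seed swap
  p_swap <- flat_rw_oracle(voxel_grid(intens), seed_set(bg, fg), cfg)
  expect_lt(max(abs(p_swap - (1 - p))), 1e-4)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(solve_random_walker(array(1, c(3, 3, 3)), seed_set()),
               "under-determined")
  expect_error(
    solve_random_walker(array(runif(1000), c(10, 10, 10)),
                        seed_set(fg = rbind(c(0, 0, 0)),
                                 bg = rbind(c(9, 9, 9))),
                        cfg = rw_config(max_iter = 1, solver_tol = 1e-12)),
    "residual")
  expect_error(
    solve_random_walker(array(1, c(3, 3, 3)),
                        seed_set(fg = rbind(c(5, 0, 0)))),
    "outside")
})
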