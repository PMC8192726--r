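test_that("caliber classes use the printed millimeter boundaries", {
  expect_equal(as.character(classify_by_diameter(0.015)), "small")
  expect_equal(as.character(classify_by_diameter(0.02)), "medium")
  expect_equal(as.character(classify_by_diameter(0.0199)), "small")
  expect_equal(as.character(classify_by_diameter(0.099)), "medium")
  expect_equal(as.character(classify_by_diameter(0.1)), "large")
  expect_error(classify_by_diameter(-0.1), "non-negative")
})

test_that("diameter histogram bins are left-closed with conserved counts", {
  h <- diameter_histogram(c(1, 1, 3))
  expect_equal(h$counts, c(2, 1))
  expect_equal(h$breaks_um, c(0, 2, 4))

  expect_equal(length(diameter_histogram(numeric(0))$counts), 0)

  set.seed(19)
  d <- runif(137, 0, 40)
  expect_equal(sum(diameter_histogram(d)$counts), 137)
  expect_equal(sum(diameter_histogram(d, 3.5)$counts), 137)
  expect_error(diameter_histogram(d, 0), "positive")
  # boundary value falls into the right-hand bin
  expect_equal(diameter_histogram(c(2))$counts, c(0, 1))
})

test_that("frustum quadrature reproduces analytic cylinders, cones and tubes", {
  # cylinder: exact at any sampling
  pts <- cbind(seq(0, 50, by = 5), 0, 0)
  expect_equal(centerline_volume(pts, rep(4, nrow(pts))), pi * 16 * 50,
               tolerance = 1e-12)
  # cone: the frustum rule is exact as well
  r <- seq(6, 0, length.out = nrow(pts))
  expect_equal(centerline_volume(pts, r), pi / 3 * 36 * 50, tolerance = 1e-12)
  # curved tapering tube: first-order convergence in the step size
  vol_at <- function(n) {
    th <- seq(0, pi, length.out = n)
    p <- cbind(30 * cos(th), 30 * sin(th), 0)
    centerline_volume(p, seq(5, 2, length.out = n))
  }
  exact <- vol_at(20001)
  e1 <- abs(vol_at(51) - exact)
  e2 <- abs(vol_at(201) - exact)
  expect_lt(e2, e1 / 2)
  expect_lt(e1 / exact, 0.05)

  # end-to-end on a rasterized tube: radius estimation from the distance
  # transform carries sub-voxel uncertainty, so the tolerance is wider
  m <- straight_tube_mask(c(72, 20, 20), r = 4, x0 = 5, x1 = 68)
  g <- extract_graph(skeletonize(m), m, c(1, 1, 1))
  st <- segment_table(g)
  analytic <- pi * 4^2 * st$length_um
  expect_lt(abs(st$volume_um3 - analytic) / analytic, 0.2)
})

test_that("summaries carry totals, classes, and organ volume arithmetic", {
  m <- y_junction_mask()
  g <- extract_graph(skeletonize(m), m, c(2, 2, 2))
  organ <- array(FALSE, c(12, 12, 12)); organ[2:11, 2:11, 2:11] <- TRUE
  rep <- summarize_graph(g, organ_mask = organ, spacing = c(10, 10, 10))
  expect_equal(rep$totals$n_segments, length(g$segments))
  expect_equal(rep$totals$organ_volume_mm3, 1000 * 1000 / 1e9)
  expect_equal(sum(rep$histogram$counts), rep$totals$n_segments)
  expect_equal(sum(table(rep$segments$class)), rep$totals$n_segments)
  expect_equal(rep$totals$total_length_mm,
               sum(segment_table(g)$length_um) / 1e3)

  f <- tempfile(fileext = ".json")
  write_report(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$totals$total_length_mm, rep$totals$total_length_mm)
})

test_that("straightness is 1 for straight and 2/pi for semicircular segments", {
  m <- straight_tube_mask(c(72, 16, 16), r = 3)
  st <- segment_table(extract_graph(skeletonize(m), m, c(1, 1, 1)))
  expect_equal(st$straightness, 1, tolerance = 1e-6)

  # semicircular tube of arc radius 22 in a thin slab
  arc <- array(FALSE, c(64, 40, 16))
  theta <- seq(0, pi, length.out = 60)
  ctr <- c(32, 6)
  pts <- cbind(ctr[1] + 22 * cos(theta), ctr[2] + 22 * sin(theta), 8)
  for (i in seq_len(nrow(pts) - 1))
    arc <- paint_tube(arc, pts[i, ], pts[i + 1, ], 2.6)
  g <- extract_graph(skeletonize(arc), arc, c(1, 1, 1))
  st <- segment_table(g)
  main <- st[which.max(st$length_um), ]
  expect_equal(main$straightness, 2 / pi, tolerance = 0.02)
})

test_that("longer vessels are the thicker ones in generator-built trees", {
  spec <- phantom_spec(rng_seed = 2, dims = c(144, 144, 144), spacing = c(2, 2, 2),
                       n_bifurcations = 2, radius_root_um = 10,
                       radius_decay = 0.55, noise_sigma = 0)
  gt <- generate_tree(spec)
  mask <- remove_spurious_and_fill(gt$mask)
  gp <- prune_graph(extract_graph(skeletonize(mask), mask, spec$spacing), 3)
  rep <- summarize_graph(gp)
  med <- tapply(rep$segments$length_um, rep$segments$class, stats::median)
  med <- med[!is.na(med)]
  expect_gte(length(med), 2)       # calibers straddle the small/medium cutoff
  expect_true(all(diff(med) > 0))  # median length grows with the class
})
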