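test_that("a straight tube thins to a single path with two endpoints", {
  m <- straight_tube_mask(c(72, 16, 16), r = 3, x0 = 5, x1 = 68)
  sk <- skeletonize(m)
  g <- extract_graph(sk, m, c(1, 1, 1))
  expect_equal(length(g$segments), 1)
  expect_equal(sum(g$nodes$kind == "endpoint"), 2)
  expect_equal(sum(g$nodes$kind == "branch"), 0)
  st <- segment_table(g)
  expect_lt(abs(st$length_um - 63) / 63, 0.05)        # axis length 63 voxels
  expect_lt(abs(st$avg_diameter_um / 2 - 3), 1)       # radius within 1 spacing
})

test_that("a solid sphere thins to a tiny single component", {
  m <- array(FALSE, c(20, 20, 20))
  ctr <- 10.5
  xx <- rep(1:20, times = 400); yy <- rep(rep(1:20, each = 20), 20)
  zz <- rep(1:20, each = 400)
  m[(xx - ctr)^2 + (yy - ctr)^2 + (zz - ctr)^2 <= 49] <- TRUE
  sk <- skeletonize(m)
  expect_lte(sum(sk), 10)
  expect_equal(length(connected_components(sk, 26, method = "inmemory")$sizes), 1)
})

test_that("a Y junction yields three endpoints, one branch node, three segments", {
  m <- y_junction_mask()
  g <- extract_graph(skeletonize(m), m, c(1, 1, 1))
  expect_equal(sum(g$nodes$kind == "endpoint"), 3)
  expect_equal(sum(g$nodes$kind == "branch"), 1)
  expect_equal(length(g$segments), 3)
})

test_that("disjoint tubes give disjoint graph components", {
  m <- array(FALSE, c(64, 32, 16))
  m <- paint_tube(m, c(5, 8, 8), c(59, 8, 8), 3)
  m <- paint_tube(m, c(5, 24, 8), c(59, 24, 8), 3)
  g <- extract_graph(skeletonize(m), m, c(1, 1, 1))
  expect_equal(length(g$segments), 2)
  expect_equal(nrow(g$nodes), 4)
  # the two segments share no nodes
  ends <- lapply(g$segments, function(s) c(s$node_a, s$node_b))
  expect_equal(length(intersect(ends[[1]], ends[[2]])), 0)
})

test_that("extract_graph rejects non-thin input", {
  slab <- array(TRUE, c(8, 8, 8))
  expect_error(extract_graph(slab, slab, c(1, 1, 1)), "not thin")
})

test_that("thinning preserves 26-connectivity of components", {
  set.seed(31)
  m <- array(FALSE, c(32, 32, 32))
  m <- paint_tube(m, c(5, 10, 10), c(28, 12, 14), 2.5)
  m <- paint_tube(m, c(5, 24, 20), c(26, 22, 24), 2.2)
  sk <- skeletonize(m)
  expect_equal(length(connected_components(sk, 26, method = "inmemory")$sizes),
               length(connected_components(m, 26, method = "inmemory")$sizes))
  expect_true(all(m[sk]))     # skeleton is a subset of the mask
})

test_that("bulge size follows the proper-length over diameter formula", {
  expect_equal(bulge_size(50, 10, 8), 5.0)
  expect_equal(bulge_size(5, 10, 4), 0.0)           # clamped at zero
  k <- 7.3
  expect_equal(bulge_size(50 * k, 10 * k, 8 * k), bulge_size(50, 10, 8))
  expect_error(bulge_size(50, 10, 0), "diameter")
})

test_that("pruning removes stubs, merges the junction away, keeps the trunk", {
  m <- array(FALSE, c(64, 24, 24))
  m <- paint_tube(m, c(5, 12, 12), c(59, 12, 12), 4)   # thick trunk
  m <- paint_tube(m, c(32, 12, 12), c(32, 21, 12), 2)  # short stub
  g <- extract_graph(skeletonize(m), m, c(1, 1, 1))
  expect_gte(length(g$segments), 3)
  gp <- prune_graph(g, 3.0)
  expect_equal(length(gp$segments), 1)
  expect_equal(sum(gp$nodes$kind == "endpoint"), 2)
  # total length conserved through the degree-2 merge of the trunk halves
  trunk_parts <- Filter(function(s) s$avg_diameter_um > 7, g$segments)
  expect_equal(gp$segments[[1]]$length_um,
               sum(vapply(trunk_parts, `[[`, numeric(1), "length_um")),
               tolerance = 1e-9)
})

test_that("a zero threshold never prunes and pruning is monotone in the threshold", {
  gt <- generate_tree(topology_spec(3, seed = 5))
  mask <- remove_spurious_and_fill(gt$mask)
  g <- extract_graph(skeletonize(mask), mask, gt$spec$spacing)
  g0 <- prune_graph(g, 0)
  expect_equal(length(g0$segments), length(g$segments))

  lens <- function(gg) sum(vapply(gg$segments, `[[`, numeric(1), "length_um"))
  prev_n <- Inf; prev_len <- Inf
  for (t in c(1, 3, 5)) {
    gp <- prune_graph(g, t)
    expect_lte(length(gp$segments), prev_n)
    expect_lte(lens(gp), prev_len + 1e-9)
    prev_n <- length(gp$segments); prev_len <- lens(gp)
  }
})

test_that("uniform scaling of the voxel spacing changes no pruning decision", {
  gt <- generate_tree(topology_spec(2, seed = 4))
  mask <- remove_spurious_and_fill(gt$mask)
  g1 <- prune_graph(extract_graph(skeletonize(mask), mask, gt$spec$spacing), 3.0)
  g2 <- prune_graph(extract_graph(skeletonize(mask), mask, gt$spec$spacing * 2), 3.0)
  expect_equal(length(g1$segments), length(g2$segments))
  expect_equal(nrow(g1$nodes), nrow(g2$nodes))
  expect_equal(sort(g1$nodes$degree), sort(g2$nodes$degree))
  # geometry itself scales linearly
  expect_equal(segment_table(g2)$length_um, 2 * segment_table(g1)$length_um,
               tolerance = 1e-9)
})

test_that("graphs round-trip through the on-disk formats", {
  m <- y_junction_mask()
  g <- extract_graph(skeletonize(m), m, c(1.5, 1.5, 2))
  dir <- tempfile("graph_")
  write_graph(g, dir)
  expect_true(all(file.exists(file.path(dir, c("nodes.csv", "segments.csv",
                                               "points.csv", "graph.graphml",
                                               "polylines.vtk")))))
  back <- read_graph(dir, spacing = c(1.5, 1.5, 2))
  expect_equal(segment_table(back), segment_table(g), tolerance = 1e-9)
  expect_equal(back$nodes$radius_um, g$nodes$radius_um)
  # graphml edge count matches the segment table
  ig <- igraph::read_graph(file.path(dir, "graph.graphml"), format = "graphml")
  expect_equal(igraph::ecount(ig), length(g$segments))

  # empty graph still writes valid, readable files
  e <- extract_graph(array(FALSE, c(4, 4, 4)), array(FALSE, c(4, 4, 4)))
  dire <- tempfile("graph_empty_")
  write_graph(e, dire)
  back_e <- read_graph(dire)
  expect_equal(length(back_e$segments), 0)
})
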