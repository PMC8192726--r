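# Fixture builders shared across the test files. Everything is generated in
# code; no binary fixtures.

# paint a solid tube of given radius between two voxel-space points
paint_tube <- function(vol, a, b, r) {
  d <- dim(vol)
  xx <- rep(seq_len(d[1]), times = d[2] * d[3])
  yy <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  zz <- rep(seq_len(d[3]), each = d[1] * d[2])
  u <- b - a
  L2 <- sum(u^2)
  t <- if (L2 > 0)
    pmin(1, pmax(0, ((xx - a[1]) * u[1] + (yy - a[2]) * u[2] + (zz - a[3]) * u[3]) / L2))
  else 0
  dist2 <- (xx - a[1] - t * u[1])^2 + (yy - a[2] - t * u[2])^2 + (zz - a[3] - t * u[3])^2
  vol | array(dist2 <= r^2, d)
}

straight_tube_mask <- function(dims = c(64, 16, 16), r = 3, x0 = 4, x1 = dims[1] - 3) {
  m <- array(FALSE, dims)
  cy <- (dims[2] + 1) / 2
  cz <- (dims[3] + 1) / 2
  paint_tube(m, c(x0, cy, cz), c(x1, cy, cz), r)
}

y_junction_mask <- function() {
  m <- array(FALSE, c(64, 64, 16))
  m <- paint_tube(m, c(5, 32, 8), c(32, 32, 8), 3.2)
  m <- paint_tube(m, c(32, 32, 8), c(56, 48, 8), 3.2)
  paint_tube(m, c(32, 32, 8), c(56, 16, 8), 3.2)
}

# two-intensity grid from a mask
mask_to_grid <- function(mask, fg = 200, bg = 10, spacing = c(1, 1, 1)) {
  a <- array(bg, dim(mask))
  a[mask] <- fg
  voxel_grid(a, spacing)
}

# small vascular phantom in the regime the coarse level resolves
small_phantom <- function(seed, dims = c(64, 64, 64), noise = 0, nb = 2,
                          r0 = 14, decay = 0.8) {
  phantom_spec(rng_seed = seed, dims = dims, spacing = c(2, 2, 2),
               n_bifurcations = nb, radius_root_um = r0, radius_decay = decay,
               noise_sigma = noise)
}

# graph pipeline from a clean mask
mask_to_pruned_graph <- function(mask, spacing, threshold = 3.0) {
  mask <- remove_spurious_and_fill(mask)
  g <- extract_graph(skeletonize(mask), mask, spacing)
  prune_graph(g, threshold)
}

# configuration bucket used for exact-topology phantoms of a given size
topology_spec <- function(nb, seed) {
  dims <- if (nb <= 3) c(128, 128, 128) else if (nb <= 7) c(208, 208, 208)
          else c(240, 240, 240)
  sp <- if (nb <= 3) 2 else 1.4
  r0 <- if (nb <= 3) 8 else 6.5
  dec <- if (nb <= 3) 0.72 else 0.8
  phantom_spec(rng_seed = seed, dims = dims, spacing = rep(sp, 3),
               n_bifurcations = nb, radius_root_um = r0, radius_decay = dec,
               noise_sigma = 0)
}

expect_topology_equal <- function(gp, n_bif) {
  expect_equal(length(gp$segments), 2L * n_bif + 1L)
  expect_equal(sum(gp$nodes$kind == "endpoint"), n_bif + 2L)
  expect_equal(sum(gp$nodes$kind == "branch"), n_bif)
}

# brute-force majority filter (independent oracle for median_smooth)
brute_majority <- function(mask, r) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    xs <- max(1, x - r):min(d[1], x + r)
    ys <- max(1, y - r):min(d[2], y + r)
    zs <- max(1, z - r):min(d[3], z + r)
    nb <- mask[xs, ys, zs]
    out[x, y, z] <- 2 * sum(nb) >= length(nb)
  }
  out
}

# do two label volumes define the same partition of the foreground?
same_partition <- function(l1, l2) {
  if (!identical(l1 > 0, l2 > 0)) return(FALSE)
  f <- l1 > 0
  key <- paste(l1[f], l2[f])
  map12 <- unique(cbind(l1[f], l2[f]))
  !any(duplicated(map12[, 1])) && !any(duplicated(map12[, 2]))
}

# dense direct solve of the random-walker system (independent oracle)
dense_rw_solve <- function(intens, spacing, fg, bg, cfg) {
  d <- dim(intens)
  n <- prod(d)
  scale <- max(intens) - min(intens)
  if (scale <= 0) scale <- 1
  cfg$intensity_scale <- scale
  idx <- array(seq_len(n), d)
  L <- matrix(0, n, n)
  for (ax in 1:3) {
    if (d[ax] < 2) next
    sl <- function(rng) {
      ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      ix[[ax]] <- rng
      idx[ix[[1]], ix[[2]], ix[[3]]]
    }
    a <- as.vector(sl(seq_len(d[ax] - 1)))
    b <- as.vector(sl(2:d[ax]))
    w <- edge_weight(intens[a], intens[b], cfg) / spacing[ax]^2
    for (k in seq_along(a)) {
      L[a[k], b[k]] <- L[a[k], b[k]] - w[k]
      L[b[k], a[k]] <- L[b[k], a[k]] - w[k]
    }
  }
  diag(L) <- -rowSums(L)
  lin <- function(m) 1L + m[, 1] + d[1] * (m[, 2] + d[2] * m[, 3])
  p <- rep(NA_real_, n)
  p[lin(bg)] <- 0
  p[lin(fg)] <- 1
  cset <- which(!is.na(p))
  u <- setdiff(seq_len(n), cset)
  p[u] <- solve(L[u, u], -L[u, cset, drop = FALSE] %*% p[cset])
  array(p, d)
}
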