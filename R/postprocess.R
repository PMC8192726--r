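## cumulative-sum ("integral volume") window counts: for every voxel, the sum
## of `a` over the cubic window of radius r, clipped at the volume border
window_sum <- function(a, r) {
  d <- dim(a)
  S <- array(0, d + 1L)
  S[-1, -1, -1] <- a
  S <- apply(S, c(2, 3), cumsum)          # along x
  S <- aperm(apply(S, c(1, 3), cumsum), c(2, 1, 3))  # along y
  S <- aperm(apply(S, c(1, 2), cumsum), c(2, 3, 1))  # along z
  lo <- lapply(1:3, function(ax) pmax(seq_len(d[ax]) - r, 1L))
  hi <- lapply(1:3, function(ax) pmin(seq_len(d[ax]) + r, d[ax]) + 1L)
  out <- array(0, d)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    sgn <- (-1)^(cx + cy + cz)
    ix <- if (cx == 0) hi[[1]] else lo[[1]]
    iy <- if (cy == 0) hi[[2]] else lo[[2]]
    iz <- if (cz == 0) hi[[3]] else lo[[3]]
    out <- out + sgn * S[ix, iy, iz]
  }
  out
}

#' Majority (median) smoothing of a binary mask
#'
#' Each voxel takes the majority value of its cubic `(2r+1)^3` neighborhood;
#' neighborhoods at the volume border use the existing voxels only. Ties go
#' to foreground. For a binary image this is exactly the median filter used
#' to smooth vessel surfaces before skeletonization.
#'
#' @param mask logical 3D array.
#' @param radius window radius in voxels (>= 1).
#' @return smoothed logical array.
#' @export
median_smooth <- function(mask, radius = 1L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, radius >= 1)
  fg <- window_sum(array(as.numeric(mask), dim(mask)), as.integer(radius))
  n <- window_sum(array(1, dim(mask)), as.integer(radius))
  2 * fg >= n
}

## positive brick-neighbor offsets that can carry voxel adjacencies
brick_neighbor_offsets <- function(connectivity) {
  if (connectivity == 6)
    return(list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L)))
  offs <- list()
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    if (dx + dy + dz > 0) offs[[length(offs) + 1L]] <- c(dx, dy, dz)
  offs
}

uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Connected-component labeling of a binary volume
#'
#' The default `"streaming"` method labels the volume brick by brick (local
#' flood fill per brick), records label equivalences across the one-voxel
#' border slabs of every pair of adjacent bricks (including diagonal brick
#' pairs for 26-connectivity), merges them with a union-find, and relabels
#' in a second pass — the structure needed for volumes that do not fit in
#' memory, where only two bricks and the label table are resident at a
#' time. The `"inmemory"` method is a single global flood fill and serves
#' as the reference implementation.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @param brick_size brick edge length of the streaming pass.
#' @param method `"streaming"` or `"inmemory"`.
#' @return list with `labels` (integer array, 0 = background, components
#'   numbered from 1 in scan order) and `sizes` (voxel count per label).
#' @export
connected_components <- function(mask, connectivity = 6L, brick_size = 32L,
                                 method = c("streaming", "inmemory")) {
  method <- match.arg(method)
  stopifnot(is.array(mask), length(dim(mask)) == 3L,
            connectivity %in% c(6L, 26L))
  d <- dim(mask)
  if (method == "inmemory") {
    lab <- .cc_label_cpp(as.logical(mask), as.integer(d), as.integer(connectivity))
    return(list(labels = lab, sizes = tabulate(lab[lab > 0])))
  }
  bs <- as.integer(brick_size)
  nb <- as.integer(ceiling(d / bs))
  ext_of <- function(b) brick_extent(d, bs, b)
  regions <- vector("list", prod(nb))
  bidx <- function(b) 1L + b[1] + nb[1] * (b[2] + nb[2] * b[3])

  ## pass 1: local labeling per brick, labels offset to be globally unique
  n_labels <- 0L
  for (bz in 0:(nb[3] - 1L)) for (by in 0:(nb[2] - 1L)) for (bx in 0:(nb[1] - 1L)) {
    b <- c(bx, by, bz)
    e <- ext_of(b)
    sub <- mask[e$lo[1]:e$hi[1], e$lo[2]:e$hi[2], e$lo[3]:e$hi[3], drop = FALSE]
    lab <- .cc_label_cpp(as.logical(sub), dim(sub), as.integer(connectivity))
    k <- max(lab)
    lab[lab > 0] <- lab[lab > 0] + n_labels
    n_labels <- n_labels + k
    regions[[bidx(b)]] <- lab
  }
  if (n_labels == 0L)
    return(list(labels = array(0L, d), sizes = integer(0)))

  ## pass 2: union labels across adjacent brick borders
  parent <- seq_len(n_labels)
  conn_off <- expand.grid(ox = -1:1, oy = -1:1, oz = -1:1)
  conn_off <- conn_off[rowSums(abs(conn_off)) > 0, ]
  if (connectivity == 6) conn_off <- conn_off[rowSums(abs(conn_off)) == 1, ]
  for (bz in 0:(nb[3] - 1L)) for (by in 0:(nb[2] - 1L)) for (bx in 0:(nb[1] - 1L)) {
    b <- c(bx, by, bz)
    eA <- ext_of(b)
    labA <- regions[[bidx(b)]]
    dA <- dim(labA)
    for (dv in brick_neighbor_offsets(connectivity)) {
      b2 <- b + dv
      if (any(b2 >= nb)) next
      eB <- ext_of(b2)
      labB <- regions[[bidx(b2)]]
      dB <- dim(labB)
      ## slab of A facing B, slab of B facing A (thickness 1 on fixed axes)
      idxA <- lapply(1:3, function(ax) if (dv[ax] == 1L) dA[ax] else seq_len(dA[ax]))
      idxB <- lapply(1:3, function(ax) if (dv[ax] == 1L) 1L else seq_len(dB[ax]))
      slabA <- labA[idxA[[1]], idxA[[2]], idxA[[3]], drop = FALSE]
      slabB <- labB[idxB[[1]], idxB[[2]], idxB[[3]], drop = FALSE]
      ## voxel offsets of the chosen connectivity crossing this brick border
      ok <- rep(TRUE, nrow(conn_off))
      for (ax in 1:3) if (dv[ax] == 1L) ok <- ok & conn_off[[ax]] == 1L
      for (o in which(ok)) {
        off <- as.integer(conn_off[o, ])
        ra <- list(); rb <- list()
        valid <- TRUE
        for (ax in 1:3) {
          if (dv[ax] == 1L) { ra[[ax]] <- 1L; rb[[ax]] <- 1L; next }
          n <- dim(slabA)[ax]
          aa <- max(1L, 1L - off[ax]):min(n, n - off[ax])
          if (length(aa) == 0 || aa[1] > aa[length(aa)]) { valid <- FALSE; break }
          ra[[ax]] <- aa
          rb[[ax]] <- aa + off[ax]
        }
        if (!valid) next
        la <- as.vector(slabA[ra[[1]], ra[[2]], ra[[3]]])
        lb <- as.vector(slabB[rb[[1]], rb[[2]], rb[[3]]])
        keep <- la > 0L & lb > 0L
        if (!any(keep)) next
        prs <- unique(cbind(la[keep], lb[keep]))
        for (r in seq_len(nrow(prs))) {
          ri <- uf_find(parent, prs[r, 1])
          rj <- uf_find(parent, prs[r, 2])
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }

  ## pass 3: relabel to consecutive ids in scan order of first appearance
  root <- vapply(seq_len(n_labels), function(i) uf_find(parent, i), integer(1))
  labels <- array(0L, d)
  remap <- integer(n_labels)
  next_id <- 0L
  for (bz in 0:(nb[3] - 1L)) for (by in 0:(nb[2] - 1L)) for (bx in 0:(nb[1] - 1L)) {
    b <- c(bx, by, bz)
    e <- ext_of(b)
    lab <- regions[[bidx(b)]]
    pos <- lab > 0L
    if (any(pos)) {
      r <- root[lab[pos]]
      newr <- unique(r[remap[r] == 0L])
      if (length(newr)) {
        remap[newr] <- next_id + seq_along(newr)
        next_id <- next_id + length(newr)
      }
      lab[pos] <- remap[r]
    }
    labels[e$lo[1]:e$hi[1], e$lo[2]:e$hi[2], e$lo[3]:e$hi[3]] <- lab
  }
  list(labels = labels, sizes = tabulate(labels[labels > 0L]))
}

#' Remove spurious fragments and fill cavities in a binary mask
#'
#' Foreground components smaller than `min_fg_size` voxels (default: all
#' but the largest component, matching the single-vessel-tree use case) are
#' deleted; background components not connected to the volume hull —
#' cavities, e.g. the lumen of hollow vessels — are filled to foreground.
#' Foreground uses 26-connectivity, background the dual 6-connectivity.
#'
#' @param mask logical 3D array.
#' @param min_fg_size minimum voxel count of a foreground component to
#'   keep; `NULL` keeps only the largest component.
#' @param connectivity_fg,connectivity_bg connectivities of the two phases.
#' @param brick_size brick edge for the streaming labeling.
#' @return cleaned logical array.
#' @export
remove_spurious_and_fill <- function(mask, min_fg_size = NULL,
                                     connectivity_fg = 26L,
                                     connectivity_bg = 6L,
                                     brick_size = 32L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  cc <- connected_components(mask, connectivity_fg, brick_size)
  if (length(cc$sizes) > 0) {
    keep <- if (is.null(min_fg_size)) which.max(cc$sizes)
            else which(cc$sizes >= min_fg_size)
    mask <- array(cc$labels %in% keep, d)
  }
  bg <- connected_components(!mask, connectivity_bg, brick_size)
  if (length(bg$sizes) > 0) {
    hull <- unique(c(bg$labels[c(1L, d[1]), , ], bg$labels[, c(1L, d[2]), ],
                     bg$labels[, , c(1L, d[3])]))
    hull <- hull[hull > 0L]
    cavity <- setdiff(seq_along(bg$sizes), hull)
    if (length(cavity)) mask[bg$labels %in% cavity] <- TRUE
  }
  mask
}
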