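#' Hierarchical segmentation configuration
#'
#' @param binary_threshold probability threshold for the final binary
#'   segmentation; a voxel is foreground iff `p >= binary_threshold`.
#' @param homogeneity_eps a brick whose coarse-level probabilities are all
#'   `>= 1 - eps` (and contains no background seed) is classified foreground
#'   without solving, and symmetrically for background; the whole subtree
#'   below it is skipped.
#' @param reuse_eps during incremental updates a solved brick is reused
#'   verbatim when its seed content is unchanged and its parent-supplied
#'   boundary values moved by at most `reuse_eps` in maximum norm.
#' @param upsample_mode interpolation used when sampling coarse probabilities
#'   onto a fine brick's border shell: `"trilinear"` or `"nearest"`.
#' @return an object of class `hierarchy_config`.
#' @export
hierarchy_config <- function(binary_threshold = 0.5, homogeneity_eps = 0.01,
                             reuse_eps = 0.01, upsample_mode = c("trilinear", "nearest")) {
  upsample_mode <- match.arg(upsample_mode)
  stopifnot(binary_threshold > 0, binary_threshold < 1,
            homogeneity_eps > 0, homogeneity_eps < 0.5,
            reuse_eps >= 0, reuse_eps < 0.5)
  structure(list(binary_threshold = binary_threshold,
                 homogeneity_eps = homogeneity_eps,
                 reuse_eps = reuse_eps, upsample_mode = upsample_mode),
            class = "hierarchy_config")
}

#' Scale level-0 seeds to a coarser pyramid level
#'
#' Seed coordinates are integer-divided by `2^level` so the same annotation
#' can be used at any resolution. Duplicates collapse; a coarse voxel
#' receiving both labels keeps neither (recorded in the `"conflicts"`
#' attribute).
#'
#' @param seeds a [seed_set()] in 0-based level-0 coordinates.
#' @param level target pyramid level (0 = identity).
#' @return a [seed_set()] in level coordinates.
#' @export
scale_seeds_to_level <- function(seeds, level) {
  stopifnot(inherits(seeds, "seed_set"), level >= 0)
  f <- 2L^as.integer(level)
  fg <- unique(seeds$fg %/% f)
  bg <- unique(seeds$bg %/% f)
  kf <- paste(fg[, 1], fg[, 2], fg[, 3])
  kb <- paste(bg[, 1], bg[, 2], bg[, 3])
  clash <- intersect(kf, kb)
  out <- seed_set(fg = fg[!kf %in% clash, , drop = FALSE],
                  bg = bg[!kb %in% clash, , drop = FALSE])
  attr(out, "conflicts") <- fg[kf %in% clash, , drop = FALSE]
  out
}

#' Classify a brick from its coarse-level probabilities
#'
#' Bricks lying completely inside the foreground structure or completely in
#' the background are decided at the coarse level and never refined:
#' `"foreground"` iff all coarse probabilities are `>= 1 - homogeneity_eps`
#' and the brick contains no background seed; `"background"` iff all are
#' `<= homogeneity_eps` and it contains no foreground seed; otherwise
#' `"mixed"`.
#'
#' @param coarse numeric vector/array of coarse probabilities over the
#'   brick's footprint.
#' @param has_fg_seed,has_bg_seed does the brick contain hard seeds?
#' @param cfg a [hierarchy_config()].
#' @return `"foreground"`, `"background"` or `"mixed"`.
#' @export
classify_homogeneous <- function(coarse, has_fg_seed = FALSE,
                                 has_bg_seed = FALSE, cfg = hierarchy_config()) {
  eps <- cfg$homogeneity_eps
  if (all(coarse >= 1 - eps) && !has_bg_seed) return("foreground")
  if (all(coarse <= eps) && !has_fg_seed) return("background")
  "mixed"
}

## ---- probability volume ---------------------------------------------------

new_probability_volume <- function(pyr, cache_budget, dir) {
  e <- new.env(parent = emptyenv())
  e$store <- new_brick_store(dir, pyr$brick_size, cache_budget)
  e$brick_size <- pyr$brick_size
  e$n_levels <- pyr$n_levels
  e$level_dims <- pyr$level_dims
  e$dims <- pyr$dims
  e$spacing <- pyr$spacing
  e$dir <- dir
  e$state <- new.env(parent = emptyenv())
  e$stats <- list()
  class(e) <- "probability_volume"
  e
}

#' @export
print.probability_volume <- function(x, ...) {
  cat(sprintf("<probability_volume> %s voxels, %d level(s), brick %d^3\n",
              paste(x$dims, collapse = " x "), x$n_levels, x$brick_size))
  s <- segmentation_stats(x)
  if (nrow(s)) print(s)
  invisible(x)
}

prob_get_region <- function(prob, level, lo, hi) {
  region_from_store(prob$store, level, prob$level_dims[[level + 1L]], lo, hi)
}

#' Whole level of a probability volume as one array
#'
#' @param prob a `probability_volume` from [run_hierarchical_rw()].
#' @param level 0-based level.
#' @return numeric array of probabilities with the level's dims.
#' @export
prob_level_array <- function(prob, level = 0L) {
  d <- prob$level_dims[[level + 1L]]
  prob_get_region(prob, level, c(1L, 1L, 1L), d)
}

#' Per-level brick statistics of a hierarchical segmentation
#'
#' @param prob a `probability_volume`.
#' @return data.frame with per-level counts of solved, determined
#'   (homogeneity-pruned) and reused bricks.
#' @export
segmentation_stats <- function(prob) {
  if (!length(prob$stats))
    return(data.frame(level = integer(0), solved = integer(0),
                      determined = integer(0), reused = integer(0)))
  do.call(rbind, prob$stats)
}

## valid extent (1-based inclusive) of brick b at a level
brick_extent <- function(level_dims, brick_size, b) {
  lo <- b * brick_size + 1L
  hi <- pmin(lo + brick_size - 1L, level_dims)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

## store a region array as a zero-padded brick
put_region_brick <- function(store, level, b, region) {
  bs <- store$bs
  brick <- array(0, rep(bs, 3))
  ext <- dim(region)
  brick[seq_len(ext[1]), seq_len(ext[2]), seq_len(ext[3])] <- region
  store_put(store, level, b, brick)
}

## sample the parent-level probability map at child-level voxel centers;
## x is an n x 3 matrix of 1-based child-level coordinates
sample_parent <- function(prob, parent_level, x, mode) {
  pd <- prob$level_dims[[parent_level + 1L]]
  q <- (x - 1) / 2 - 0.25          # 0-based continuous parent coordinate
  if (mode == "nearest") {
    iq <- pmin(pmax(round(q), 0), matrix(rep(pd - 1L, each = nrow(q)), ncol = 3))
    lo <- pmin(apply(iq, 2, min), pd - 1L) + 1L
    hi <- pmax(apply(iq, 2, max), 0) + 1L
    reg <- prob_get_region(prob, parent_level, lo, hi)
    idx <- cbind(iq[, 1] + 1L - lo[1] + 1L, iq[, 2] + 1L - lo[2] + 1L,
                 iq[, 3] + 1L - lo[3] + 1L)
    return(reg[idx])
  }
  qc <- pmin(pmax(q, 0), matrix(rep(pd - 1L, each = nrow(q)), ncol = 3))
  i0 <- floor(qc)
  f <- qc - i0
  i1 <- pmin(i0 + 1, matrix(rep(pd - 1L, each = nrow(q)), ncol = 3))
  lo <- as.integer(pmax(apply(i0, 2, min) + 1L, 1L))
  hi <- as.integer(pmin(apply(i1, 2, max) + 1L, pd))
  reg <- prob_get_region(prob, parent_level, lo, hi)
  val <- numeric(nrow(q))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx == 0) i0[, 1] else i1[, 1]
    iy <- if (cy == 0) i0[, 2] else i1[, 2]
    iz <- if (cz == 0) i0[, 3] else i1[, 3]
    wx <- if (cx == 0) 1 - f[, 1] else f[, 1]
    wy <- if (cy == 0) 1 - f[, 2] else f[, 2]
    wz <- if (cz == 0) 1 - f[, 3] else f[, 3]
    val <- val + wx * wy * wz *
      reg[cbind(ix + 2L - lo[1], iy + 2L - lo[2], iz + 2L - lo[3])]
  }
  val
}

## 1-based coordinates of the one-voxel halo ring of region [lo, hi],
## i.e. the shell of the expanded region [elo, ehi] minus the region itself,
## clipped to the level dims d (no halo on volume-border faces)
shell_coords <- function(lo, hi, d) {
  elo <- pmax(lo - 1L, 1L); ehi <- pmin(hi + 1L, d)
  g <- as.matrix(expand.grid(x = elo[1]:ehi[1], y = elo[2]:ehi[2],
                             z = elo[3]:ehi[3]))
  outside <- g[, 1] < lo[1] | g[, 1] > hi[1] |
             g[, 2] < lo[2] | g[, 2] > hi[2] |
             g[, 3] < lo[3] | g[, 3] > hi[3]
  g[outside, , drop = FALSE]
}

#' Boundary values for a brick from the coarser-level probability map
#'
#' The coarse level's output probabilities act as soft (non-binary) seeds on
#' the border of the current brick: the one-voxel halo ring just outside the
#' brick is clamped to probabilities sampled from the parent-level map at
#' the corresponding half-resolution positions, and the brick's own voxels
#' are then all solved against these Dirichlet values. Volume-border faces
#' carry no halo (free boundary, as in the monolithic solve).
#'
#' @param prob a `probability_volume` whose level `level + 1` is complete.
#' @param level 0-based level of the brick.
#' @param b 0-based brick coordinates.
#' @param mode `"trilinear"` or `"nearest"`.
#' @return list with `coords` (0-based level coordinates, n x 3) and
#'   `values` (probabilities in `[0, 1]`).
#' @export
boundary_from_coarse <- function(prob, level, b,
                                 mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  if (level + 1L >= prob$n_levels)
    stop("brick has no parent level (sequencing error)")
  ext <- brick_extent(prob$level_dims[[level + 1L]], prob$brick_size, as.integer(b))
  sh <- shell_coords(ext$lo, ext$hi, prob$level_dims[[level + 1L]])
  vals <- sample_parent(prob, level + 1L, sh, mode)
  list(coords = sh - 1L, values = pmin(1, pmax(0, vals)))
}

## solve one mixed brick: expand the region by the one-voxel halo, clamp the
## halo to coarse-level values (hard seeds override), solve, crop the halo
solve_brick_with_halo <- function(pyr, prob, lev, b, lo, hi, d, sp, sl,
                                  cfg, rw_cfg) {
  bnd <- boundary_from_coarse(prob, lev, b, cfg$upsample_mode)
  elo <- pmax(lo - 1L, 1L)
  ehi <- pmin(hi + 1L, d)
  bnd_loc <- list(coords = sweep(bnd$coords + 1L, 2, as.integer(elo)),
                  values = bnd$values)
  fg_e <- seeds_in_region(sl$fg, elo, ehi)
  bg_e <- seeds_in_region(sl$bg, elo, ehi)
  intens <- pyramid_get_region(pyr, lev, elo, ehi)
  p <- solve_random_walker(intens, seed_set(fg_e - 1L, bg_e - 1L),
                           boundary = bnd_loc, cfg = rw_cfg, spacing = sp)
  crop <- p[(lo[1] - elo[1] + 1L):(hi[1] - elo[1] + 1L),
            (lo[2] - elo[2] + 1L):(hi[2] - elo[2] + 1L),
            (lo[3] - elo[3] + 1L):(hi[3] - elo[3] + 1L), drop = FALSE]
  list(cropped = crop, boundary = bnd$values)
}

## signature of the seed content of a region (order-independent)
seed_sig <- function(fg_local, bg_local) {
  fmt <- function(m) {
    if (nrow(m) == 0) return("")
    paste(sort(paste(m[, 1], m[, 2], m[, 3], sep = ",")), collapse = ";")
  }
  paste(fmt(fg_local), fmt(bg_local), sep = "|")
}

## ---- the hierarchical solver ----------------------------------------------

#' Hierarchical random-walker segmentation over an octree pyramid
#'
#' Coarse-to-fine refinement of the random-walker probability map: an
#' initial map is solved on the coarsest level with the down-scaled hard
#' seeds; each finer level is then solved brick by brick with the hard
#' seeds inside the brick plus the parent level's probabilities clamped on
#' the brick's border shell. Bricks whose coarse footprint is homogeneous
#' foreground or background are decided immediately and their subtrees
#' skipped; all brick traffic flows through the bounded LRU caches, so peak
#' memory is independent of volume size.
#'
#' @param pyr an [build_octree()] pyramid.
#' @param seeds a [seed_set()] with 0-based level-0 coordinates; both
#'   classes must be non-empty.
#' @param cfg a [hierarchy_config()].
#' @param rw_cfg an [rw_config()]; when `intensity_scale` is `NULL` the
#'   global intensity range of the volume is used so all bricks share one
#'   weight normalization.
#' @param cache_budget resident-brick cap of the output probability store.
#' @param dir directory for the probability bricks.
#' @param order_seed internal: if non-`NULL`, bricks within each level are
#'   processed in a pseudo-random order (results are identical because
#'   bricks of one level are independent given the parent level).
#' @return a `probability_volume`; see [prob_level_array()],
#'   [threshold_segmentation()], [segmentation_stats()].
#' @export
run_hierarchical_rw <- function(pyr, seeds, cfg = hierarchy_config(),
                                rw_cfg = rw_config(),
                                cache_budget = pyr$store$budget,
                                dir = tempfile("prob_"), order_seed = NULL) {
  stopifnot(inherits(pyr, "octree_pyramid"), inherits(seeds, "seed_set"))
  if (nrow(seeds$fg) == 0 || nrow(seeds$bg) == 0)
    stop("both foreground and background seeds are required")
  if (is.null(rw_cfg$intensity_scale) && !is.null(pyr$intensity_range)) {
    s <- diff(pyr$intensity_range)
    rw_cfg$intensity_scale <- if (s > 0) s else 1
  }
  prob <- new_probability_volume(pyr, cache_budget, dir)
  ss <- lapply(0:(pyr$n_levels - 1L), function(l) scale_seeds_to_level(seeds, l))

  top <- pyr$n_levels - 1L
  for (lev in top:0) {
    d <- pyr$level_dims[[lev + 1L]]
    sp <- pyr$level_spacing[[lev + 1L]]
    sl <- ss[[lev + 1L]]
    nb <- as.integer(ceiling(d / pyr$brick_size))
    bricks <- as.matrix(expand.grid(bx = 0:(nb[1] - 1L), by = 0:(nb[2] - 1L),
                                    bz = 0:(nb[3] - 1L)))
    if (!is.null(order_seed)) {
      perm <- local({
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(order_seed + lev)
        sample.int(nrow(bricks))
      })
      bricks <- bricks[perm, , drop = FALSE]
    }
    n_solved <- 0L; n_det <- 0L
    for (k in seq_len(nrow(bricks))) {
      b <- as.integer(bricks[k, ])
      ext <- brick_extent(d, pyr$brick_size, b)
      lo <- ext$lo; hi <- ext$hi
      fg_loc <- seeds_in_region(sl$fg, lo, hi)
      bg_loc <- seeds_in_region(sl$bg, lo, hi)
      key <- store_key(lev, b)
      if (lev == top) {
        intens <- pyramid_get_region(pyr, lev, lo, hi)
        if (nrow(fg_loc) == 0 || nrow(bg_loc) == 0)
          stop("seeds of both classes collapsed away at the coarsest level; add more separated seeds")
        p <- solve_random_walker(intens, seed_set(fg_loc - 1L, bg_loc - 1L),
                                 boundary = NULL, cfg = rw_cfg, spacing = sp)
        put_region_brick(prob$store, lev, b, p)
        prob$state[[key]] <- list(status = "solved", boundary = NULL,
                                  sig = seed_sig(fg_loc, bg_loc))
        n_solved <- n_solved + 1L
        next
      }
      plo <- (lo - 1L) %/% 2L + 1L
      phi <- (hi - 1L) %/% 2L + 1L
      coarse <- prob_get_region(prob, lev + 1L, plo, phi)
      cls <- classify_homogeneous(coarse, nrow(fg_loc) > 0, nrow(bg_loc) > 0, cfg)
      if (cls != "mixed") {
        val <- if (cls == "foreground") 1 else 0
        put_region_brick(prob$store, lev, b, array(val, hi - lo + 1L))
        prob$state[[key]] <- list(status = paste0("determined_",
                                                  substr(cls, 1, 2)),
                                  boundary = NULL,
                                  sig = seed_sig(fg_loc, bg_loc))
        n_det <- n_det + 1L
        next
      }
      p <- solve_brick_with_halo(pyr, prob, lev, b, lo, hi, d, sp,
                                 sl, cfg, rw_cfg)
      put_region_brick(prob$store, lev, b, p$cropped)
      prob$state[[key]] <- list(status = "solved", boundary = p$boundary,
                                sig = seed_sig(fg_loc, bg_loc))
      n_solved <- n_solved + 1L
    }
    prob$stats[[length(prob$stats) + 1L]] <-
      data.frame(level = lev, solved = n_solved, determined = n_det,
                 reused = 0L)
  }
  prob
}

#' Update a segmentation after a seed edit, reusing unchanged bricks
#'
#' Re-runs the hierarchical scheme top-down but re-solves a brick only when
#' its seed content changed or its parent-supplied boundary values moved by
#' more than `reuse_eps` in maximum norm; all other bricks are copied
#' verbatim from the previous result, which bounds the response time of an
#' interactive seed-editing session by the size of the affected region.
#'
#' @param prev `probability_volume` from a previous [run_hierarchical_rw()]
#'   (or [incremental_update()]) on the same pyramid.
#' @param pyr the same [build_octree()] pyramid.
#' @param old_seeds,new_seeds the previous and the edited [seed_set()].
#' @inheritParams run_hierarchical_rw
#' @return a new `probability_volume`; `segmentation_stats()` reports how
#'   many bricks were re-solved vs reused.
#' @export
incremental_update <- function(prev, pyr, old_seeds, new_seeds,
                               cfg = hierarchy_config(), rw_cfg = rw_config(),
                               cache_budget = pyr$store$budget,
                               dir = tempfile("prob_")) {
  stopifnot(inherits(prev, "probability_volume"))
  if (!identical(prev$level_dims, pyr$level_dims) ||
      prev$brick_size != pyr$brick_size)
    stop("previous result was computed on a different pyramid")
  if (nrow(new_seeds$fg) == 0 || nrow(new_seeds$bg) == 0)
    stop("both foreground and background seeds are required")
  if (is.null(rw_cfg$intensity_scale) && !is.null(pyr$intensity_range)) {
    s <- diff(pyr$intensity_range)
    rw_cfg$intensity_scale <- if (s > 0) s else 1
  }
  prob <- new_probability_volume(pyr, cache_budget, dir)
  ss <- lapply(0:(pyr$n_levels - 1L), function(l) scale_seeds_to_level(new_seeds, l))

  top <- pyr$n_levels - 1L
  for (lev in top:0) {
    d <- pyr$level_dims[[lev + 1L]]
    sp <- pyr$level_spacing[[lev + 1L]]
    sl <- ss[[lev + 1L]]
    nb <- as.integer(ceiling(d / pyr$brick_size))
    n_solved <- 0L; n_det <- 0L; n_reused <- 0L
    for (bz in 0:(nb[3] - 1L)) for (by in 0:(nb[2] - 1L)) for (bx in 0:(nb[1] - 1L)) {
      b <- c(bx, by, bz)
      ext <- brick_extent(d, pyr$brick_size, b)
      lo <- ext$lo; hi <- ext$hi
      fg_loc <- seeds_in_region(sl$fg, lo, hi)
      bg_loc <- seeds_in_region(sl$bg, lo, hi)
      sig <- seed_sig(fg_loc, bg_loc)
      key <- store_key(lev, b)
      old <- prev$state[[key]]
      if (lev == top) {
        if (!is.null(old) && old$status == "solved" && identical(old$sig, sig)) {
          store_put(prob$store, lev, b, store_get(prev$store, lev, b))
          prob$state[[key]] <- old
          n_reused <- n_reused + 1L
        } else {
          if (nrow(fg_loc) == 0 || nrow(bg_loc) == 0)
            stop("seeds of both classes collapsed away at the coarsest level")
          intens <- pyramid_get_region(pyr, lev, lo, hi)
          p <- solve_random_walker(intens, seed_set(fg_loc - 1L, bg_loc - 1L),
                                   boundary = NULL, cfg = rw_cfg, spacing = sp)
          put_region_brick(prob$store, lev, b, p)
          prob$state[[key]] <- list(status = "solved", boundary = NULL, sig = sig)
          n_solved <- n_solved + 1L
        }
        next
      }
      plo <- (lo - 1L) %/% 2L + 1L
      phi <- (hi - 1L) %/% 2L + 1L
      coarse <- prob_get_region(prob, lev + 1L, plo, phi)
      cls <- classify_homogeneous(coarse, nrow(fg_loc) > 0, nrow(bg_loc) > 0, cfg)
      if (cls != "mixed") {
        status <- paste0("determined_", substr(cls, 1, 2))
        val <- if (cls == "foreground") 1 else 0
        put_region_brick(prob$store, lev, b, array(val, hi - lo + 1L))
        prob$state[[key]] <- list(status = status, boundary = NULL, sig = sig)
        if (!is.null(old) && old$status == status && identical(old$sig, sig))
          n_reused <- n_reused + 1L
        else n_det <- n_det + 1L
        next
      }
      bnd <- boundary_from_coarse(prob, lev, b, cfg$upsample_mode)
      reusable <- !is.null(old) && old$status == "solved" &&
        identical(old$sig, sig) && !is.null(old$boundary) &&
        length(old$boundary) == length(bnd$values) &&
        max(abs(old$boundary - bnd$values)) <= cfg$reuse_eps
      if (reusable) {
        store_put(prob$store, lev, b, store_get(prev$store, lev, b))
        prob$state[[key]] <- old
        n_reused <- n_reused + 1L
        next
      }
      p <- solve_brick_with_halo(pyr, prob, lev, b, lo, hi, d, sp,
                                 sl, cfg, rw_cfg)
      put_region_brick(prob$store, lev, b, p$cropped)
      prob$state[[key]] <- list(status = "solved", boundary = p$boundary, sig = sig)
      n_solved <- n_solved + 1L
    }
    prob$stats[[length(prob$stats) + 1L]] <-
      data.frame(level = lev, solved = n_solved, determined = n_det,
                 reused = n_reused)
  }
  prob
}

#' Threshold a probability volume into a binary segmentation
#'
#' @param prob a `probability_volume` with a complete level-0 map.
#' @param cfg a [hierarchy_config()]; a voxel is foreground iff
#'   `p >= binary_threshold` (ties go to foreground).
#' @return logical 3D array at full resolution.
#' @export
threshold_segmentation <- function(prob, cfg = hierarchy_config()) {
  stopifnot(inherits(prob, "probability_volume"))
  nb <- as.integer(ceiling(prob$level_dims[[1]] / prob$brick_size))
  for (bz in 0:(nb[3] - 1L)) for (by in 0:(nb[2] - 1L)) for (bx in 0:(nb[1] - 1L))
    if (!store_exists(prob$store, 0L, c(bx, by, bz)))
      stop("level-0 probability map is incomplete")
  prob_level_array(prob, 0L) >= cfg$binary_threshold
}
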