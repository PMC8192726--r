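#' Specification of a synthetic vascular phantom
#'
#' Deterministic generator of branching vessel trees rendered as intensity
#' volumes, emulating vessel-stained light-sheet data: tubes of known
#' centerline and radius on a dark background, either solid or hollow
#' (bright wall around a dark lumen, the "double line" appearance of
#' stained vessel walls), with optional additive Gaussian noise and
#' optional short stub branches for pruning tests.
#'
#' @param rng_seed integer seed; the same spec always produces the same
#'   phantom.
#' @param dims voxel counts (nx, ny, nz).
#' @param spacing micrometers per voxel.
#' @param n_bifurcations number of bifurcations; each splits one tip, so
#'   the tree has `n_bifurcations + 1` leaf segments.
#' @param radius_root_um radius of the root vessel, micrometers.
#' @param radius_decay child/parent radius ratio per generation, in (0, 1].
#' @param segment_length_um length range (min, max) of the root-caliber
#'   segments, micrometers; segment lengths scale with `sqrt(r / r_root)`
#'   so that thicker vessels run longer, as in real vascular trees.
#' @param branch_angle_deg range of branch angles from the parent axis.
#' @param wall_mode `"solid"` or `"hollow"`.
#' @param wall_thickness_frac wall thickness as a fraction of the radius
#'   (hollow mode).
#' @param fg_intensity,bg_intensity vessel and background intensities.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param stub_injection `NULL`, or `list(count, length_factor)` adding
#'   short spurious branches of length `length_factor * local diameter`
#'   (below 3 they are pruning fodder).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(rng_seed = 1L, dims = c(64L, 64L, 64L),
                         spacing = c(2, 2, 2), n_bifurcations = 3L,
                         radius_root_um = 8, radius_decay = 0.7,
                         segment_length_um = c(48, 90),
                         branch_angle_deg = c(20, 60),
                         wall_mode = c("solid", "hollow"),
                         wall_thickness_frac = 0.35,
                         fg_intensity = 200, bg_intensity = 10,
                         noise_sigma = 0, stub_injection = NULL) {
  wall_mode <- match.arg(wall_mode)
  stopifnot(radius_root_um > 0, radius_decay > 0, radius_decay <= 1,
            noise_sigma >= 0, n_bifurcations >= 0,
            all(dims >= 8), all(spacing > 0))
  structure(list(rng_seed = as.integer(rng_seed), dims = as.integer(dims),
                 spacing = as.numeric(spacing),
                 n_bifurcations = as.integer(n_bifurcations),
                 radius_root_um = radius_root_um, radius_decay = radius_decay,
                 segment_length_um = segment_length_um,
                 branch_angle_deg = branch_angle_deg,
                 wall_mode = wall_mode,
                 wall_thickness_frac = wall_thickness_frac,
                 fg_intensity = fg_intensity, bg_intensity = bg_intensity,
                 noise_sigma = noise_sigma, stub_injection = stub_injection),
            class = "phantom_spec")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

unit <- function(v) v / sqrt(sum(v^2))

## rotate unit vector u away from itself by theta, azimuth phi
tilt_direction <- function(u, theta, phi) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(pracma_cross(u, ref))
  e2 <- pracma_cross(u, e1)
  unit(cos(theta) * u + sin(theta) * (cos(phi) * e1 + sin(phi) * e2))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## minimum distance between segment (a1,b1) and point set, used to reject
## self-intersecting branches
point_segment_dist <- function(p, a, b) {
  u <- b - a
  L2 <- sum(u^2)
  if (L2 == 0) return(sqrt(sum((p - a)^2)))
  t <- min(1, max(0, sum((p - a) * u) / L2))
  sqrt(sum((p - a - t * u)^2))
}

#' Generate the ground-truth geometry of a phantom vessel tree
#'
#' Recursive binary branching from a root: each bifurcation replaces one
#' tip (always the thickest) by two children with radii scaled by
#' `radius_decay` and directions tilted 20-60 degrees off the parent axis.
#' New branches that would leave the volume or graze an existing vessel
#' are re-sampled up to a retry cap. Deterministic per seed.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_truth` list: `segments` (data.frame of straight
#'   centerline pieces with radii, one row per edge of the true graph),
#'   `nodes`, `mask` (true binary volume), `totals` (true length and
#'   volume), `spec`.
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  phys <- spec$dims * spec$spacing
  r0 <- spec$radius_root_um
  margin <- function(r) 2 * r + 2 * max(spec$spacing)
  if (any(phys < 2 * margin(r0) + min(spec$segment_length_um) / 2))
    stop("volume too small to fit the root segment")

  with_local_seed(spec$rng_seed, {
    segs <- list()
    ## root along +x from near a face, jittered slightly
    start <- c(margin(r0), phys[2] / 2, phys[3] / 2)
    dir <- unit(c(1, stats::runif(1, -0.2, 0.2), stats::runif(1, -0.2, 0.2)))
    len0 <- max(stats::runif(1, spec$segment_length_um[1],
                             spec$segment_length_um[2]), 12 * r0)
    clip_len <- function(a, u, len, r) {
      ## longest length <= len keeping the tube inside the volume
      hi <- len
      for (ax in 1:3) {
        if (u[ax] > 1e-12) hi <- min(hi, (phys[ax] - margin(r) - a[ax]) / u[ax])
        if (u[ax] < -1e-12) hi <- min(hi, (margin(r) - a[ax]) / u[ax])
      }
      hi
    }
    len0 <- clip_len(start, dir, len0, r0)
    segs[[1]] <- list(a = start, b = start + len0 * dir, r = r0, parent = 0L,
                      stub = FALSE)
    tips <- list(list(seg = 1L, p = segs[[1]]$b, dir = dir, r = r0))

    ang <- spec$branch_angle_deg * pi / 180
    n_placed <- 0L
    blocked <- logical(1)
    while (n_placed < spec$n_bifurcations) {
      ri <- vapply(tips, `[[`, numeric(1), "r")
      ri[blocked] <- -Inf
      if (all(!is.finite(ri))) break     # no tip has room left
      ti <- which.max(ri)
      tip <- tips[[ti]]
      children <- list()
      phi1 <- stats::runif(1, 0, 2 * pi)
      for (c in 1:2) {
        rc <- tip$r * spec$radius_decay
        placed <- FALSE
        for (try in 1:30) {
          theta <- stats::runif(1, ang[1], ang[2])
          ## daughters leave on opposite azimuths so the two tubes separate
          ## quickly after the bifurcation (near-parallel daughters are
          ## degenerate geometry)
          phi <- if (c == 1) phi1 + stats::runif(1, -0.4, 0.4)
                 else phi1 + pi + stats::runif(1, -0.4, 0.4)
          u <- tilt_direction(tip$dir, theta, phi)
          ## daughters must diverge enough that their tubes separate close
          ## to the junction
          if (c == 2 && sum(u * children[[1]]$dir) > cos(40 * pi / 180)) next
          len <- stats::runif(1, spec$segment_length_um[1],
                              spec$segment_length_um[2]) * sqrt(rc / r0)
          ## keep true branches clearly above the pruning regime: proper
          ## length at least 7x the branch diameter
          len <- max(len, 12 * rc)
          full <- len
          len <- clip_len(tip$p, u, len, rc)
          if (len < 12 * rc) next   # clipped out of the branch-length regime
          b <- tip$p + len * u
          ## reject candidates that graze or cross an existing vessel:
          ## sample points along the new axis and require clearance from
          ## every other segment (relaxed for the parent and sibling that
          ## legitimately share the junction point)
          ok <- TRUE
          for (si in seq_along(segs)) {
            s <- segs[[si]]
            adjacent <- si == tip$seg ||
              sum((s$a - tip$p)^2) < 1e-12 || sum((s$b - tip$p)^2) < 1e-12
            ts <- if (adjacent) seq(0.6, 1, by = 0.1) else seq(0.1, 1, by = 0.1)
            clr <- (if (adjacent) 1.1 else 2) * (rc + s$r)
            for (tt in ts) {
              if (point_segment_dist(tip$p + tt * len * u, s$a, s$b) < clr) {
                ok <- FALSE
                break
              }
            }
            if (!ok) break
          }
          if (!ok) next
          segs[[length(segs) + 1L]] <- list(a = tip$p, b = b, r = rc,
                                            parent = tip$seg, stub = FALSE)
          children[[c]] <- list(seg = length(segs), p = b, dir = u, r = rc)
          placed <- TRUE
          break
        }
        if (!placed) break
      }
      if (length(children) < 2L) {
        ## could not fit a regime-conforming bifurcation here: roll back any
        ## placed child and stop splitting this tip
        if (length(children) == 1L) segs[[children[[1]]$seg]] <- NULL
        blocked[ti] <- TRUE
        next
      }
      n_placed <- n_placed + 1L
      tips[[ti]] <- children[[1]]
      tips[[length(tips) + 1L]] <- children[[2]]
      blocked <- c(blocked, FALSE)
      blocked[ti] <- FALSE
    }

    ## injected stubs: short spurious leaves off segment midpoints; hosts
    ## are interior (branch-to-branch) segments where available, so the
    ## split pieces stay interior and the true leaf regime is untouched
    if (!is.null(spec$stub_injection)) {
      n_stub <- spec$stub_injection$count
      lf <- spec$stub_injection$length_factor
      parents <- unique(vapply(segs, `[[`, integer(1), "parent"))
      interior <- setdiff(intersect(seq_along(segs), parents), 1L)
      hosts <- if (length(interior)) interior
               else if (length(segs) > 1L) seq(2L, length(segs))
               else 1L
      host_ids <- rep(hosts, length.out = n_stub)
      for (s in seq_len(n_stub)) {
        host <- segs[[host_ids[s]]]
        t <- stats::runif(1, 0.35, 0.65)
        p <- host$a + t * (host$b - host$a)
        u <- tilt_direction(unit(host$b - host$a),
                            stats::runif(1, pi / 3, pi / 2),
                            stats::runif(1, 0, 2 * pi))
        rs <- host$r * 0.6
        len <- lf * 2 * rs + host$r   # proper length = lf * diameter
        segs[[length(segs) + 1L]] <- list(a = p, b = p + len * u, r = rs,
                                          parent = host_ids[s], stub = TRUE)
      }
    }

    seg_df <- do.call(rbind, lapply(seq_along(segs), function(i) {
      s <- segs[[i]]
      data.frame(id = i, ax = s$a[1], ay = s$a[2], az = s$a[3],
                 bx = s$b[1], by = s$b[2], bz = s$b[3], radius_um = s$r,
                 parent = s$parent, stub = s$stub,
                 length_um = sqrt(sum((s$b - s$a)^2)))
    }))
    real <- !seg_df$stub
    totals <- list(
      total_length_um = sum(seg_df$length_um[real]),
      total_volume_um3 = sum(pi * seg_df$radius_um[real]^2 * seg_df$length_um[real]),
      n_bifurcations = n_placed,
      n_leaves = n_placed + 1L)
    gt <- structure(list(segments = seg_df, totals = totals, spec = spec),
                    class = "phantom_truth")
    gt$mask <- rasterize_tubes(gt, mode = "mask")
    gt
  })
}

## distance-based tube painting; mode one of "mask", "solid", "hollow"
rasterize_tubes <- function(gt, mode, include_stubs = TRUE) {
  spec <- gt$spec
  d <- spec$dims; sp <- spec$spacing
  vol <- if (mode == "mask") array(FALSE, d) else array(spec$bg_intensity, d)
  lumen <- if (mode == "hollow") array(FALSE, d) else NULL
  sf <- gt$segments
  for (i in seq_len(nrow(sf))) {
    if (!include_stubs && sf$stub[i]) next
    a <- c(sf$ax[i], sf$ay[i], sf$az[i])
    b <- c(sf$bx[i], sf$by[i], sf$bz[i])
    r <- sf$radius_um[i]
    lo <- pmax(1L, floor((pmin(a, b) - r - sp) / sp))
    hi <- pmin(d, ceiling((pmax(a, b) + r + sp) / sp))
    if (any(lo > hi)) next
    xs <- (lo[1]:hi[1] - 0.5) * sp[1]
    ys <- (lo[2]:hi[2] - 0.5) * sp[2]
    zs <- (lo[3]:hi[3] - 0.5) * sp[3]
    nx <- length(xs); ny <- length(ys); nz <- length(zs)
    px <- rep(xs, times = ny * nz)
    py <- rep(rep(ys, each = nx), times = nz)
    pz <- rep(zs, each = nx * ny)
    u <- b - a
    L2 <- sum(u^2)
    t <- ((px - a[1]) * u[1] + (py - a[2]) * u[2] + (pz - a[3]) * u[3]) / L2
    t <- pmin(1, pmax(0, t))
    dist <- sqrt((px - a[1] - t * u[1])^2 + (py - a[2] - t * u[2])^2 +
                 (pz - a[3] - t * u[3])^2)
    sel <- array(FALSE, d)
    inside <- dist <= r
    sub <- array(inside, c(nx, ny, nz))
    sel[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
    if (mode == "mask") {
      vol[sel] <- TRUE
    } else if (mode == "solid") {
      vol[sel] <- spec$fg_intensity
    } else {
      vol[sel] <- spec$fg_intensity
      wall <- spec$wall_thickness_frac * r
      lum <- array(dist < r - wall, c(nx, ny, nz))
      lsel <- array(FALSE, d)
      lsel[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- lum
      lumen <- lumen | lsel
    }
  }
  if (mode == "hollow") vol[lumen] <- spec$bg_intensity
  vol
}

#' Render a phantom tree as an intensity volume
#'
#' Solid mode paints every voxel within the tube radius at the foreground
#' intensity; hollow mode paints only a wall shell and leaves the lumen at
#' background intensity, so an axial profile through a vessel shows the
#' two bright bands of a stained vessel wall. Additive Gaussian noise is
#' applied with a generator seeded from the spec, and intensities are
#' clipped to the 0..255 range.
#'
#' @param gt a `phantom_truth` from [generate_tree()].
#' @param spec the same [phantom_spec()] (defaults to the one in `gt`).
#' @return a [voxel_grid()].
#' @export
rasterize_phantom <- function(gt, spec = gt$spec) {
  vol <- rasterize_tubes(gt, mode = spec$wall_mode)
  if (spec$noise_sigma > 0) {
    noise <- with_local_seed(spec$rng_seed + 1L,
                             stats::rnorm(length(vol), 0, spec$noise_sigma))
    vol <- vol + array(noise, dim(vol))
  }
  vol <- pmin(255, pmax(0, vol))
  voxel_grid(array(vol, spec$dims), spec$spacing)
}

#' Deterministic seed strokes from a phantom's ground truth
#'
#' Stands in for interactive seed painting: foreground strokes sample the
#' true centerline of the thickest vessels; background strokes are placed
#' in guaranteed-background regions at a safety margin from the true mask.
#'
#' @param gt a `phantom_truth`.
#' @param n_fg_strokes,n_bg_strokes stroke counts (0 gives an empty set
#'   with a warning).
#' @param margin_um minimum distance of background seeds from the vessel
#'   surface.
#' @param path optional CSV path; if given, the seeds are also written
#'   with [write_seeds()].
#' @return a [seed_set()] in 0-based level-0 voxel coordinates.
#' @export
make_seed_file <- function(gt, n_fg_strokes = 1L, n_bg_strokes = 1L,
                           margin_um = NULL, path = NULL) {
  spec <- gt$spec
  if (is.null(margin_um)) margin_um <- 3 * max(spec$spacing)
  if (n_fg_strokes < 1 && n_bg_strokes < 1) {
    warning("no strokes requested; returning an empty seed set")
    return(seed_set())
  }
  sp <- spec$spacing; d <- spec$dims
  sf <- gt$segments[!gt$segments$stub, , drop = FALSE]
  sf <- sf[order(-sf$radius_um, sf$id), , drop = FALSE]
  fg <- NULL
  for (s in seq_len(min(n_fg_strokes, nrow(sf)))) {
    a <- c(sf$ax[s], sf$ay[s], sf$az[s]); b <- c(sf$bx[s], sf$by[s], sf$bz[s])
    t <- seq(0.15, 0.85, length.out = 7)
    pts <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
                 a[3] + t * (b[3] - a[3]))
    vox <- floor(sweep(pts, 2, sp, "/"))          # 0-based voxel containing p
    vox <- pmin(pmax(vox, 0), matrix(rep(d - 1L, each = nrow(vox)), ncol = 3))
    fg <- rbind(fg, vox)
  }
  bg <- NULL
  if (n_bg_strokes >= 1) {
    dist_to_vessel <- distance_transform(!gt$mask, sp)
    cand <- which(dist_to_vessel > margin_um, arr.ind = TRUE)
    ## also keep off the volume hull
    inner <- cand[, 1] > 1 & cand[, 2] > 1 & cand[, 3] > 1 &
      cand[, 1] < d[1] & cand[, 2] < d[2] & cand[, 3] < d[3]
    cand <- cand[inner, , drop = FALSE]
    if (nrow(cand) < n_bg_strokes * 5)
      stop("not enough background space for background seeds")
    pick <- with_local_seed(spec$rng_seed + 2L,
                            sample.int(nrow(cand), n_bg_strokes * 5))
    bg <- cand[pick, , drop = FALSE] - 1L
  }
  seeds <- seed_set(fg = unique(fg), bg = bg)
  if (!is.null(path)) write_seeds(seeds, path)
  seeds
}
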