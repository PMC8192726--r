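#' Create a 3D grayscale voxel grid
#'
#' A `voxel_grid` is the in-memory representation of a single-channel 3D
#' image: an `(nx, ny, nz)` numeric array of intensities plus the physical
#' voxel spacing in micrometers. Voxel indices are 0-based in all documented
#' coordinate interfaces (seed files, brick indices); the physical position of
#' the center of voxel `(i, j, k)` is `(i + 0.5) * sx` etc.
#'
#' @param intensities numeric or integer 3D array; all values must be finite.
#' @param spacing numeric length-3, micrometers per voxel along x, y, z; all > 0.
#' @return an object of class `voxel_grid` with elements `intensities`,
#'   `spacing` and `dims`.
#' @export
voxel_grid <- function(intensities, spacing = c(1, 1, 1)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  if (any(dim(intensities) < 1L)) stop("all dims must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (micrometers per voxel)")
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  structure(list(intensities = intensities, spacing = spacing,
                 dims = dim(intensities)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %s um, range [%g, %g]\n",
              x$dims[1], x$dims[2], x$dims[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Write a voxel grid to disk
#'
#' Two formats are supported. Paths ending in `.tif`/`.tiff` are written as a
#' multi-page 16-bit TIFF (one page per z slice; intensities must be integers
#' in 0..65535). Any other path is treated as a directory and written as a
#' lossless chunked container: per-chunk binary blobs of doubles plus a JSON
#' manifest carrying dims, spacing and chunk size.
#'
#' @param grid a [voxel_grid()].
#' @param path output file (TIFF) or directory (chunked container).
#' @param chunk_size chunk edge length for the container format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, chunk_size = 32L) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    a <- grid$intensities
    v <- round(a)
    if (any(v < 0) || any(v > 65535))
      stop("TIFF output requires integer intensities in 0..65535")
    slices <- lapply(seq_len(dim(a)[3]), function(z) t(v[, , z]) / 65535)
    tiff::writeTIFF(slices, path, bits.per.sample = 16L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    d <- grid$dims
    nb <- ceiling(d / chunk_size)
    for (bz in seq_len(nb[3])) for (by in seq_len(nb[2])) for (bx in seq_len(nb[1])) {
      lo <- (c(bx, by, bz) - 1L) * chunk_size + 1L
      hi <- pmin(lo + chunk_size - 1L, d)
      blk <- grid$intensities[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      f <- file.path(path, sprintf("chunk_%d_%d_%d.bin", bx - 1L, by - 1L, bz - 1L))
      con <- file(f, "wb"); writeBin(as.double(blk), con); close(con)
    }
    manifest <- list(format = "hiervess-chunked-v1", dims = as.integer(d),
                     spacing_um = grid$spacing, chunk_size = as.integer(chunk_size))
    jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a voxel grid from disk
#'
#' Reads multi-page TIFF stacks (8/16/32 bits per sample) or the chunked
#' container produced by [write_volume()]. TIFF files carry no physical
#' calibration, so the voxel spacing is declared by the caller; for the
#' chunked container the manifest's spacing is used unless overridden.
#'
#' @param path file or directory produced by [write_volume()] (or any
#'   multi-page TIFF stack).
#' @param spacing micrometers per voxel; required for TIFF input.
#' @return a [voxel_grid()].
#' @export
read_volume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    bits <- attr(pages[[1]], "bits.per.sample")
    if (!is.null(bits) && !bits %in% c(8L, 16L, 32L))
      stop("unsupported TIFF bit depth: ", bits)
    shp <- dim(pages[[1]])
    if (length(shp) != 2L) stop("unsupported TIFF: expected single-channel pages")
    for (p in pages)
      if (!identical(dim(p), shp)) stop("inconsistent slice shapes in TIFF stack")
    nx <- shp[2]; ny <- shp[1]; nz <- length(pages)
    a <- array(0, dim = c(nx, ny, nz))
    for (z in seq_len(nz)) a[, , z] <- t(pages[[z]])
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    voxel_grid(a, spacing)
  } else {
    mf <- file.path(path, "manifest.json")
    if (!file.exists(mf)) stop("not a chunked volume container: ", path)
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    d <- as.integer(manifest$dims); cs <- as.integer(manifest$chunk_size)
    a <- array(0, dim = d)
    nb <- ceiling(d / cs)
    for (bz in seq_len(nb[3])) for (by in seq_len(nb[2])) for (bx in seq_len(nb[1])) {
      lo <- (c(bx, by, bz) - 1L) * cs + 1L
      hi <- pmin(lo + cs - 1L, d)
      f <- file.path(path, sprintf("chunk_%d_%d_%d.bin", bx - 1L, by - 1L, bz - 1L))
      if (!file.exists(f)) stop("missing chunk file: ", f)
      n <- prod(hi - lo + 1L)
      con <- file(f, "rb"); blk <- readBin(con, "double", n = n); close(con)
      a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- array(blk, hi - lo + 1L)
    }
    if (is.null(spacing)) spacing <- as.numeric(manifest$spacing_um)
    voxel_grid(a, spacing)
  }
}

## ---- bounded-memory brick store ------------------------------------------

## An on-disk store of fixed-size bricks with a write-through LRU read cache.
## All brick traffic flows through the cache, whose occupancy is capped at
## `cache_budget` resident bricks; instrumentation counters record the peak.
new_brick_store <- function(dir, brick_size, cache_budget = 64L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- new.env(parent = emptyenv())
  e$dir <- dir
  e$bs <- as.integer(brick_size)
  e$budget <- max(1L, as.integer(cache_budget))
  e$cache <- new.env(parent = emptyenv())
  e$lru <- character(0)
  e$resident <- 0L
  e$peak <- 0L
  e$disk_reads <- 0L
  e$disk_writes <- 0L
  e$evictions <- 0L
  class(e) <- "brick_store"
  e
}

store_key <- function(level, b) sprintf("L%d_%d_%d_%d", level, b[1], b[2], b[3])

store_cache_insert <- function(store, key, arr) {
  if (!is.null(store$cache[[key]])) {
    store$cache[[key]] <- arr
    store$lru <- c(setdiff(store$lru, key), key)
    return(invisible(NULL))
  }
  while (store$resident >= store$budget && length(store$lru) > 0) {
    victim <- store$lru[1]
    store$lru <- store$lru[-1]
    rm(list = victim, envir = store$cache)
    store$resident <- store$resident - 1L
    store$evictions <- store$evictions + 1L
  }
  store$cache[[key]] <- arr
  store$lru <- c(store$lru, key)
  store$resident <- store$resident + 1L
  store$peak <- max(store$peak, store$resident)
  invisible(NULL)
}

store_put <- function(store, level, b, arr) {
  key <- store_key(level, b)
  con <- file(file.path(store$dir, paste0(key, ".bin")), "wb")
  writeBin(as.double(arr), con)
  close(con)
  store$disk_writes <- store$disk_writes + 1L
  store_cache_insert(store, key, arr)
  invisible(NULL)
}

store_get <- function(store, level, b) {
  key <- store_key(level, b)
  hit <- store$cache[[key]]
  if (!is.null(hit)) {
    store$lru <- c(setdiff(store$lru, key), key)
    return(hit)
  }
  f <- file.path(store$dir, paste0(key, ".bin"))
  if (!file.exists(f)) stop("brick not present in store: ", key)
  con <- file(f, "rb")
  arr <- array(readBin(con, "double", n = store$bs^3), rep(store$bs, 3))
  close(con)
  store$disk_reads <- store$disk_reads + 1L
  store_cache_insert(store, key, arr)
  arr
}

store_exists <- function(store, level, b) {
  key <- store_key(level, b)
  !is.null(store$cache[[key]]) ||
    file.exists(file.path(store$dir, paste0(key, ".bin")))
}

## ---- octree pyramid -------------------------------------------------------

#' Average up to eight child voxel intensities into one coarse voxel
#'
#' Half-sampling rule of the level-of-detail pyramid: a coarse voxel is the
#' arithmetic mean of its 2x2x2 children at the finer level. At volume
#' borders a coarse voxel may cover fewer than eight children, in which case
#' only the existing children are averaged (padding never contributes).
#'
#' @param children numeric vector of 1 to 8 child intensities.
#' @return their arithmetic mean.
#' @export
downsample_block <- function(children) {
  children <- children[!is.na(children)]
  if (length(children) < 1L || length(children) > 8L)
    stop("downsample_block needs 1 to 8 child values")
  mean(children)
}

## mean-halve a region array along all axes (odd extents padded with NA,
## which are excluded from the averages)
halve_region <- function(a) {
  d <- dim(a)
  d2 <- as.integer(ceiling(d / 2))
  if (any(2L * d2 != d)) {
    b <- array(NA_real_, 2L * d2)
    b[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
    a <- b
  }
  dim(a) <- c(2L, d2[1], 2L, d2[2], 2L, d2[3])
  a <- aperm(a, c(1L, 3L, 5L, 2L, 4L, 6L))
  dim(a) <- c(8L, prod(d2))
  array(colMeans(a, na.rm = TRUE), d2)
}

#' Build a bricked octree level-of-detail pyramid
#'
#' Subdivides the volume into cubic bricks (default 32^3, the standard brick
#' size for out-of-core volume processing) and builds coarser levels by
#' 2x2x2 mean half-sampling until the top level fits into a single brick.
#' Bricks are stored on disk and accessed through an LRU cache of at most
#' `cache_budget` resident bricks, so downstream computation is bounded in
#' memory regardless of volume size.
#'
#' @param grid a [voxel_grid()].
#' @param brick_size brick edge length; power of two, at least 8.
#' @param cache_budget maximum number of bricks resident in the read cache.
#' @param dir directory for the on-disk brick files (default: a fresh
#'   temporary directory).
#' @return an `octree_pyramid` with per-level dims and spacing.
#' @export
build_octree <- function(grid, brick_size = 32L, cache_budget = 64L,
                         dir = tempfile("octree_")) {
  stopifnot(inherits(grid, "voxel_grid"))
  brick_size <- as.integer(brick_size)
  if (brick_size < 8L || bitwAnd(brick_size, brick_size - 1L) != 0L)
    stop("brick_size must be a power of two >= 8")
  if (prod(grid$dims) == 0) stop("empty grid")

  store <- new_brick_store(dir, brick_size, cache_budget)
  level_dims <- list(as.integer(grid$dims))
  level_spacing <- list(grid$spacing)

  pyr <- structure(list(store = store, brick_size = brick_size,
                        n_levels = 1L, level_dims = level_dims,
                        level_spacing = level_spacing,
                        dims = grid$dims, spacing = grid$spacing, dir = dir,
                        intensity_range = range(grid$intensities)),
                   class = "octree_pyramid")

  ## level 0: brick the input grid (zero-padded at borders)
  nb <- n_bricks(pyr, 0L)
  for (bz in 0:(nb[3] - 1L)) for (by in 0:(nb[2] - 1L)) for (bx in 0:(nb[1] - 1L)) {
    b <- c(bx, by, bz)
    lo <- b * brick_size + 1L
    hi <- pmin(lo + brick_size - 1L, grid$dims)
    brick <- array(0, rep(brick_size, 3))
    ext <- hi - lo + 1L
    brick[seq_len(ext[1]), seq_len(ext[2]), seq_len(ext[3])] <-
      grid$intensities[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    store_put(store, 0L, b, brick)
  }

  ## coarser levels until the top level fits one brick
  while (any(pyr$level_dims[[pyr$n_levels]] > brick_size)) {
    lev <- pyr$n_levels            # new level index (0-based = lev)
    prev_d <- pyr$level_dims[[lev]]
    d <- as.integer(ceiling(prev_d / 2))
    pyr$level_dims[[lev + 1L]] <- d
    pyr$level_spacing[[lev + 1L]] <- pyr$level_spacing[[lev]] * 2
    pyr$n_levels <- pyr$n_levels + 1L
    nb <- as.integer(ceiling(d / brick_size))
    for (bz in 0:(nb[3] - 1L)) for (by in 0:(nb[2] - 1L)) for (bx in 0:(nb[1] - 1L)) {
      b <- c(bx, by, bz)
      lo <- b * brick_size + 1L
      hi <- pmin(lo + brick_size - 1L, d)
      clo <- 2L * (lo - 1L) + 1L
      chi <- pmin(2L * hi, prev_d)
      region <- pyramid_get_region(pyr, lev - 1L, clo, chi)
      coarse <- halve_region(region)
      brick <- array(0, rep(brick_size, 3))
      ext <- dim(coarse)
      brick[seq_len(ext[1]), seq_len(ext[2]), seq_len(ext[3])] <- coarse
      store_put(store, lev, b, brick)
    }
  }
  pyr
}

#' @export
print.octree_pyramid <- function(x, ...) {
  cat(sprintf("<octree_pyramid> %d level(s), brick %d^3, cache budget %d\n",
              x$n_levels, x$brick_size, x$store$budget))
  for (l in seq_len(x$n_levels))
    cat(sprintf("  level %d: %s voxels, spacing %s um\n", l - 1L,
                paste(x$level_dims[[l]], collapse = " x "),
                paste(signif(x$level_spacing[[l]], 4), collapse = " x ")))
  invisible(x)
}

## brick counts per axis at a level (level is 0-based)
n_bricks <- function(pyr, level) {
  as.integer(ceiling(pyr$level_dims[[level + 1L]] / pyr$brick_size))
}

#' Fetch one brick of the pyramid
#'
#' @param pyr an `octree_pyramid`.
#' @param level 0-based level (0 = full resolution).
#' @param b integer triple of 0-based brick coordinates.
#' @return a `brick_size^3` array; regions beyond the level's extent are
#'   zero-padded.
#' @export
get_brick <- function(pyr, level, b) {
  stopifnot(inherits(pyr, "octree_pyramid"))
  level <- as.integer(level)
  if (level < 0L || level >= pyr$n_levels)
    stop("level out of range: ", level)
  b <- as.integer(b)
  nb <- n_bricks(pyr, level)
  if (length(b) != 3L || any(b < 0L) || any(b >= nb))
    stop("brick index out of range: ", paste(b, collapse = ","))
  store_get(pyr$store, level, b)
}

## assemble an arbitrary (1-based, inclusive) region of a level from a
## brick store; all brick reads go through the bounded LRU cache
region_from_store <- function(store, level, d, lo, hi) {
  bs <- store$bs
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(all(lo >= 1L), all(hi <= d), all(lo <= hi))
  out <- array(0, hi - lo + 1L)
  b0 <- (lo - 1L) %/% bs
  b1 <- (hi - 1L) %/% bs
  for (bz in b0[3]:b1[3]) for (by in b0[2]:b1[2]) for (bx in b0[1]:b1[1]) {
    b <- c(bx, by, bz)
    brick <- store_get(store, level, b)
    glo <- pmax(lo, b * bs + 1L)
    ghi <- pmin(hi, (b + 1L) * bs)
    src_lo <- glo - b * bs
    src_hi <- ghi - b * bs
    dst_lo <- glo - lo + 1L
    dst_hi <- ghi - lo + 1L
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      brick[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  }
  out
}

pyramid_get_region <- function(pyr, level, lo, hi) {
  region_from_store(pyr$store, level, pyr$level_dims[[level + 1L]], lo, hi)
}

#' Whole level of a pyramid as one array (for small levels and testing)
#'
#' @param pyr an `octree_pyramid`.
#' @param level 0-based level.
#' @return numeric array with the level's true dims (no brick padding).
#' @export
pyramid_level_array <- function(pyr, level) {
  d <- pyr$level_dims[[level + 1L]]
  pyramid_get_region(pyr, level, c(1L, 1L, 1L), d)
}

#' Cache instrumentation counters of a pyramid or brick-backed volume
#'
#' @param x an `octree_pyramid` or `probability_volume`.
#' @return list with `resident`, `peak_resident`, `budget`, `disk_reads`,
#'   `disk_writes`, `evictions`.
#' @export
brick_cache_stats <- function(x) {
  store <- if (inherits(x, "brick_store")) x else x$store
  list(resident = store$resident, peak_resident = store$peak,
       budget = store$budget, disk_reads = store$disk_reads,
       disk_writes = store$disk_writes, evictions = store$evictions)
}
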