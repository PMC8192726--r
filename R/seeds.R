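#' Construct a seed set
#'
#' Hard user annotations for seeded segmentation: foreground seeds mark
#' voxels known to lie inside vessels, background seeds voxels known to lie
#' outside. Coordinates are 0-based level-0 voxel indices.
#'
#' @param fg,bg integer matrices with 3 columns (x, y, z), possibly 0 rows.
#' @return an object of class `seed_set`.
#' @export
seed_set <- function(fg = NULL, bg = NULL) {
  canon <- function(m) {
    if (is.null(m) || length(m) == 0) return(matrix(integer(0), ncol = 3))
    m <- matrix(as.integer(round(m)), ncol = 3)
    unique(m)
  }
  fg <- canon(fg); bg <- canon(bg)
  if (nrow(fg) > 0 && nrow(bg) > 0) {
    kf <- paste(fg[, 1], fg[, 2], fg[, 3])
    kb <- paste(bg[, 1], bg[, 2], bg[, 3])
    if (any(kf %in% kb)) stop("foreground and background seeds overlap")
  }
  structure(list(fg = fg, bg = bg), class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d foreground, %d background seeds\n",
              nrow(x$fg), nrow(x$bg)))
  invisible(x)
}

#' Read seeds from a CSV file
#'
#' Expected columns: `x`, `y`, `z` (0-based level-0 voxel indices) and
#' `label` (`fg` or `bg`).
#'
#' @param path CSV file.
#' @return a [seed_set()].
#' @export
read_seeds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "z", "label")
  if (!all(need %in% names(df))) stop("seed file must have columns x,y,z,label")
  if (!all(df$label %in% c("fg", "bg"))) stop("seed labels must be 'fg' or 'bg'")
  m <- as.matrix(df[, c("x", "y", "z")])
  seed_set(fg = m[df$label == "fg", , drop = FALSE],
           bg = m[df$label == "bg", , drop = FALSE])
}

#' Write seeds to a CSV file
#'
#' @param seeds a [seed_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_seeds <- function(seeds, path) {
  stopifnot(inherits(seeds, "seed_set"))
  df <- rbind(
    if (nrow(seeds$fg)) data.frame(x = seeds$fg[, 1], y = seeds$fg[, 2],
                                   z = seeds$fg[, 3], label = "fg"),
    if (nrow(seeds$bg)) data.frame(x = seeds$bg[, 1], y = seeds$bg[, 2],
                                   z = seeds$bg[, 3], label = "bg"))
  if (is.null(df)) df <- data.frame(x = integer(0), y = integer(0),
                                    z = integer(0), label = character(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## rasterize one polyline (matrix of 0-based, possibly fractional, voxel
## coordinates) to the unique voxels traversed, by dense sampling of each
## straight piece at sub-voxel steps
rasterize_polyline <- function(pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  if (nrow(pts) == 1) return(matrix(as.integer(round(pts)), ncol = 3))
  out <- NULL
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    n <- max(2L, ceiling(2 * sqrt(sum((b - a)^2))) + 1L)
    t <- seq(0, 1, length.out = n)
    seg <- cbind(a[1] + t * (b[1] - a[1]),
                 a[2] + t * (b[2] - a[2]),
                 a[3] + t * (b[3] - a[3]))
    out <- rbind(out, round(seg))
  }
  unique(matrix(as.integer(out), ncol = 3))
}

#' Read seed strokes from a JSON polyline file
#'
#' The file holds a list of strokes, each `{"label": "fg"|"bg",
#' "points": [[x,y,z], ...]}` in 0-based level-0 voxel coordinates; each
#' polyline is rasterized to the voxels it traverses.
#'
#' @param path JSON file.
#' @return a [seed_set()].
#' @export
read_strokes <- function(path) {
  strokes <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(strokes)) strokes <- split(strokes, seq_len(nrow(strokes)))
  fg <- NULL; bg <- NULL
  for (s in strokes) {
    lab <- if (is.data.frame(s)) s$label[[1]] else s$label
    pts <- if (is.data.frame(s)) s$points[[1]] else s$points
    if (is.list(pts)) pts <- do.call(rbind, pts)
    vox <- rasterize_polyline(pts)
    if (identical(lab, "fg")) fg <- rbind(fg, vox) else bg <- rbind(bg, vox)
  }
  seed_set(fg = fg, bg = bg)
}

## seeds restricted to a region [lo, hi] (1-based inclusive, level coords),
## returned as 1-based coordinates local to the region
seeds_in_region <- function(coords0, lo, hi) {
  if (nrow(coords0) == 0) return(matrix(integer(0), ncol = 3))
  c1 <- coords0 + 1L
  keep <- c1[, 1] >= lo[1] & c1[, 1] <= hi[1] &
          c1[, 2] >= lo[2] & c1[, 2] <= hi[2] &
          c1[, 3] >= lo[3] & c1[, 3] <= hi[3]
  sweep(c1[keep, , drop = FALSE], 2, as.integer(lo) - 1L)
}
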