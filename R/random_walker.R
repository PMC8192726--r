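#' Random-walker configuration
#'
#' Parameters of the seeded random-walker segmentation: the probability that
#' a random walker released at a voxel reaches a foreground seed before a
#' background seed is the discrete harmonic function of the edge-weighted
#' voxel lattice with seeds as Dirichlet boundary conditions. The linear
#' system is solved with a Jacobi-preconditioned conjugate-gradient solver.
#'
#' @param beta edge-weight contrast parameter (> 0); larger values make
#'   intensity steps harder to cross. Default 90, calibrated for intensities
#'   normalized to `[0, 1]` by `intensity_scale`.
#' @param solver_tol relative residual tolerance of the CG solver.
#' @param max_iter CG iteration cap.
#' @param intensity_scale normalization constant for intensity differences;
#'   `NULL` (default) uses the volume's `max - min` at solve time.
#' @param w_min small additive weight floor keeping the lattice connected.
#' @return an object of class `rw_config`.
#' @export
rw_config <- function(beta = 90, solver_tol = 1e-6, max_iter = 2000L,
                      intensity_scale = NULL, w_min = 1e-5) {
  stopifnot(beta > 0, solver_tol > 0, max_iter >= 1)
  structure(list(beta = beta, solver_tol = solver_tol,
                 max_iter = as.integer(max_iter),
                 intensity_scale = intensity_scale, w_min = w_min),
            class = "rw_config")
}

#' Random-walker edge weight between two voxel intensities
#'
#' Gaussian weighting of the normalized intensity difference,
#' `exp(-beta * ((i_a - i_b) / scale)^2) + w_min`. Symmetric in its
#' arguments and always positive; vectorized.
#'
#' @param i_a,i_b finite intensities.
#' @param cfg an [rw_config()]; if `intensity_scale` is `NULL`, 1 is used.
#' @return weights in `(0, 1 + w_min]`.
#' @export
edge_weight <- function(i_a, i_b, cfg = rw_config()) {
  s <- if (is.null(cfg$intensity_scale)) 1 else cfg$intensity_scale
  if (s <= 0) s <- 1
  exp(-cfg$beta * ((i_a - i_b) / s)^2) + cfg$w_min
}

## Graph Laplacian of the 6-connected voxel lattice with Gaussian intensity
## weights; weights are divided by the squared physical edge length so that
## diffusion is spacing-aware on anisotropic grids.
build_lattice_laplacian <- function(intensities, spacing, cfg) {
  d <- dim(intensities)
  n <- prod(d)
  scale <- cfg$intensity_scale
  if (is.null(scale)) {
    scale <- max(intensities) - min(intensities)
    if (scale <= 0) scale <- 1
  }
  cfg2 <- cfg
  cfg2$intensity_scale <- scale
  idx <- array(seq_len(n), d)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (ax in 1:3) {
    if (d[ax] < 2) next
    take <- function(range_ax) {
      ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      ix[[ax]] <- range_ax
      idx[ix[[1]], ix[[2]], ix[[3]]]
    }
    a <- as.vector(take(seq_len(d[ax] - 1L)))
    b <- as.vector(take(seq(2L, d[ax])))
    w <- edge_weight(intensities[a], intensities[b], cfg2) / spacing[ax]^2
    ii <- c(ii, a, b); jj <- c(jj, b, a); ww <- c(ww, w, w)
  }
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = -ww, dims = c(n, n))
  L + Matrix::Diagonal(n, -Matrix::rowSums(L))
}

## Jacobi-preconditioned conjugate gradient for SPD sparse systems;
## deterministic (fixed initial guess, no randomization).
pcg_solve <- function(A, b, x0, tol, maxit) {
  x <- as.numeric(x0)
  b <- as.numeric(b)
  r <- b - as.numeric(A %*% x)
  minv <- 1 / Matrix::diag(A)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) bnorm <- 1
  if (sqrt(sum(r^2)) <= tol * bnorm)
    return(list(x = x, iters = 0L, relres = sqrt(sum(r^2)) / bnorm))
  z <- minv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    relres <- sqrt(sum(r^2)) / bnorm
    if (relres <= tol)
      return(list(x = x, iters = it, relres = relres))
    z <- minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf("conjugate gradient did not converge in %d iterations (relative residual %.3e)",
               maxit, sqrt(sum(r^2)) / bnorm))
}

#' Solve the random-walker problem on one volume or brick
#'
#' Computes the per-voxel foreground probability as the discrete harmonic
#' function of the 6-connected weighted lattice: every unconstrained voxel's
#' probability is the weighted mean of its neighbors', with foreground seeds
#' clamped to 1, background seeds to 0, and soft boundary values (used by
#' the hierarchical scheme to pass coarse-level probabilities to fine-level
#' bricks) clamped to their given value in `[0, 1]`.
#'
#' @param grid a [voxel_grid()] or a 3D numeric array.
#' @param seeds a [seed_set()] with 0-based coordinates local to `grid`.
#' @param boundary `NULL`, or a list with `coords` (0-based integer matrix,
#'   3 columns) and `values` (probabilities in `[0, 1]`).
#' @param cfg an [rw_config()].
#' @param spacing voxel spacing, used only if `grid` is a bare array.
#' @return 3D array of foreground probabilities in `[0, 1]`.
#' @export
solve_random_walker <- function(grid, seeds, boundary = NULL,
                                cfg = rw_config(), spacing = c(1, 1, 1)) {
  if (inherits(grid, "voxel_grid")) {
    intens <- grid$intensities
    spacing <- grid$spacing
  } else intens <- grid
  d <- dim(intens)
  n <- prod(d)

  lin <- function(m) {
    if (is.null(m) || nrow(m) == 0) return(integer(0))
    if (any(m < 0) || any(sweep(m, 2, d, ">=")))
      stop("seed/boundary coordinate outside volume")
    as.integer(1L + m[, 1] + d[1] * (m[, 2] + d[2] * m[, 3]))
  }
  fg <- lin(seeds$fg)
  bg <- lin(seeds$bg)
  bidx <- integer(0); bval <- numeric(0)
  if (!is.null(boundary) && length(boundary$values) > 0) {
    bidx <- lin(boundary$coords)
    bval <- as.numeric(boundary$values)
    if (any(bval < 0 | bval > 1)) stop("boundary values must be in [0,1]")
  }

  p <- rep(NA_real_, n)
  p[bidx] <- bval          # hard seeds override coincident boundary values
  p[bg] <- 0
  p[fg] <- 1
  constrained <- which(!is.na(p))
  if (length(constrained) == 0)
    stop("under-determined: no seeds or boundary values supplied")
  u <- which(is.na(p))
  if (length(u) == 0) {
    out <- array(p, d)
    return(out)
  }

  L <- build_lattice_laplacian(intens, spacing, cfg)
  A <- L[u, u, drop = FALSE]
  rhs <- -as.numeric(L[u, constrained, drop = FALSE] %*% p[constrained])
  sol <- pcg_solve(A, rhs, x0 = rep(0.5, length(u)),
                   tol = cfg$solver_tol, maxit = cfg$max_iter)
  p[u] <- pmin(1, pmax(0, sol$x))
  array(p, d)
}

#' Monolithic random-walker solve of a whole volume
#'
#' The basic (non-hierarchical) method: one global linear system over the
#' full-resolution volume with the user's hard seeds as the only
#' constraints. Memory grows with the whole volume, so this is practical
#' only for small volumes; it serves as the reference the hierarchical
#' scheme is validated against.
#'
#' @inheritParams solve_random_walker
#' @return 3D array of foreground probabilities.
#' @export
flat_rw_oracle <- function(grid, seeds, cfg = rw_config()) {
  solve_random_walker(grid, seeds, boundary = NULL, cfg = cfg)
}
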