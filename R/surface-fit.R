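# Scattered-point set construction and tri-harmonic RBF implicit surface
# fitting. All fitting is done in voxel-index space (the subsampling grid,
# cube size and off-surface distance d are stated in pixels); the fitted
# surface records the spacing so it can be evaluated at mm coordinates.

#' Subsample the potential fissure points on a sparse grid
#'
#' Greedy selection in ascending (y, x) order: a point is kept as a grid
#' candidate when it is at least \code{grid_spacing} pixels from every
#' previously kept point in the (x, y) plane, and retained only if the
#' centered \code{cube}^3 voxel cube contains more than \code{min_count}
#' PFP points (isolated, unreliable candidates are discarded).
#'
#' @param pfp n x 3 matrix of PFP voxel indices.
#' @param grid_spacing minimum (x, y) spacing between kept points, pixels.
#' @param cube side of the verification cube, voxels.
#' @param min_count minimum number of PFP points in the cube (exclusive).
#' @return Subset matrix of \code{pfp} rows (the on-surface set).
#' @export
subsamplePFP <- function(pfp, grid_spacing = 30, cube = 11, min_count = 80) {
  stopifnot(nrow(pfp) >= 1)
  ord <- order(pfp[, 2], pfp[, 1], pfp[, 3])
  pfp_o <- pfp[ord, , drop = FALSE]
  half <- (cube - 1) / 2
  kept <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(pfp_o))) {
    p <- pfp_o[i, ]
    if (nrow(kept)) {
      dx <- abs(kept[, 1] - p[1]); dy <- abs(kept[, 2] - p[2])
      if (any(dx < grid_spacing & dy < grid_spacing)) next
    }
    cnt <- sum(abs(pfp[, 1] - p[1]) <= half &
               abs(pfp[, 2] - p[2]) <= half &
               abs(pfp[, 3] - p[3]) <= half)
    if (cnt > min_count) kept <- rbind(kept, p)
  }
  if (!nrow(kept))
    stop("too sparse: no subsampled point passed the cube-count check")
  rownames(kept) <- NULL
  kept
}

#' Average plane normal of a point neighbourhood
#'
#' For pairs of neighbourhood points (p, q) the plane through (center, p,
#' q) has normal proportional to \eqn{(p - c) \times (q - c)}; each
#' normal is flipped into the hemisphere of \code{reference_dir} and the
#' normalized average is returned. Dense neighbourhoods are subsampled to
#' at most \code{max_pairs} pairs (deterministically, by a fixed stride).
#'
#' @param center numeric(3) cube center.
#' @param cube_points matrix of neighbourhood points (excluding or
#'   including the center; the center row is ignored).
#' @param reference_dir orientation reference; the returned normal has a
#'   positive dot product with it.
#' @param max_pairs cap on the number of point pairs.
#' @return Unit normal vector, numeric(3).
#' @export
averageNormal <- function(center, cube_points, reference_dir,
                          max_pairs = 2000) {
  v <- sweep(cube_points, 2, center)
  v <- v[rowSums(v^2) > 1e-12, , drop = FALSE]
  n <- nrow(v)
  if (n < 2) stop("degenerate normal: fewer than 2 distinct cube points")
  pairs <- utils::combn(n, 2)
  if (ncol(pairs) > max_pairs)
    pairs <- pairs[, seq(1, ncol(pairs),
                         length.out = max_pairs), drop = FALSE]
  a <- v[pairs[1, ], , drop = FALSE]
  b <- v[pairs[2, ], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(cr^2))
  ok <- len > 1e-9
  if (!any(ok)) stop("degenerate normal: all cube points collinear")
  cr <- cr[ok, , drop = FALSE] / len[ok]
  sgn <- sign(cr %*% reference_dir)
  sgn[sgn == 0] <- 1
  avg <- colSums(cr * as.vector(sgn))
  nl <- sqrt(sum(avg^2))
  if (nl < 1e-9) stop("degenerate normal: normals cancel out")
  avg / nl
}

#' Construct off-surface points
#'
#' Each on-surface point is displaced by \code{d} pixels along its
#' average cube normal (oriented by \code{reference_dir}), producing one
#' off-surface point per on-surface point, all on the positive side of
#' the surface. Points with a degenerate normal are dropped from both
#' sets with a warning.
#'
#' @param pfp_sub on-surface points from [subsamplePFP].
#' @param pfp full PFP set (supplies the cube neighbourhoods).
#' @param d off-surface displacement in pixels.
#' @param reference_dir orientation reference for the normals.
#' @param cube side of the neighbourhood cube, voxels.
#' @return List with matrices \code{on} and \code{off} (paired rows).
#' @export
makeOffSurface <- function(pfp_sub, pfp, d = 10, reference_dir,
                           cube = 11) {
  half <- (cube - 1) / 2
  on <- off <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(pfp_sub))) {
    p <- pfp_sub[i, ]
    nb <- pfp[abs(pfp[, 1] - p[1]) <= half & abs(pfp[, 2] - p[2]) <= half &
              abs(pfp[, 3] - p[3]) <= half, , drop = FALSE]
    nrm <- tryCatch(averageNormal(p, nb, reference_dir),
                    error = function(e) NULL)
    if (is.null(nrm)) {
      warning("dropping on-surface point ", i, ": degenerate normal")
      next
    }
    on <- rbind(on, p)
    off <- rbind(off, p + d * nrm)
  }
  rownames(on) <- rownames(off) <- NULL
  list(on = on, off = off)
}

.triharmonic <- function(r) r^3

# Pairwise tri-harmonic kernel matrix between rows of a and b.
.phiMatrix <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  .triharmonic(sqrt(pmax(d2, 0)))
}

#' Fit the implicit tri-harmonic RBF fissure surface
#'
#' Solves the bordered symmetric system for \eqn{F(x) = \sum_i \lambda_i
#' |x - x_i|^3 + c_0 + c_1 x + c_2 y + c_3 z} with interpolation
#' conditions F = 0 at the on-surface centers and F = d at the
#' off-surface centers, plus the four side conditions \eqn{\sum\lambda_i
#' = \sum\lambda_i x_i = \sum\lambda_i y_i = \sum\lambda_i z_i = 0}. A
#' small ridge is added to the kernel diagonal and the solve retried if
#' the plain system is numerically singular.
#'
#' @param on,off on- and off-surface center matrices (index units).
#' @param d the off-surface distance used to build \code{off}.
#' @param fissure fissure identity recorded on the surface.
#' @param spacing voxel spacing (mm) recorded for mm-space evaluation.
#' @param ridge ridge added to the kernel diagonal on fallback.
#' @return An [ImplicitSurface-class].
#' @export
fitRBF <- function(on, off, d = 10, fissure = "left_oblique",
                   spacing = c(1, 1, 1), ridge = 1e-8) {
  centers <- rbind(on, off)
  m <- nrow(centers)
  if (m < 5) stop("need at least 5 centers (on + off)")
  Phi <- .phiMatrix(centers, centers)
  P <- cbind(1, centers)
  A <- rbind(cbind(Phi, P), cbind(t(P), matrix(0, 4, 4)))
  v <- c(rep(0, nrow(on)), rep(d, nrow(off)), rep(0, 4))
  sol <- tryCatch(solve(A, v), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) {
    A[cbind(1:m, 1:m)] <- A[cbind(1:m, 1:m)] + ridge
    sol <- solve(A, v)
  }
  res <- sqrt(sum((A %*% sol - v)^2))
  if (res > 1e-8 * max(1, sqrt(sum(v^2))))
    warning("RBF solve residual ", format(res), " above tolerance")
  new("ImplicitSurface", centers = centers, lambda = sol[1:m],
      poly = sol[(m + 1):(m + 4)], fissure = fissure, space = "index",
      spacing = as.numeric(spacing), d = d)
}

#' Evaluate an implicit surface
#'
#' Computes \eqn{F(x)} at arbitrary points; output order matches input
#' order. Points are interpreted in the surface's own coordinate space
#' unless \code{space} says otherwise, in which case they are converted
#' using the recorded voxel spacing.
#'
#' @param surface an [ImplicitSurface-class].
#' @param points n x 3 matrix of query points.
#' @param space coordinate space of \code{points} ("index" or "mm").
#' @return Numeric vector of F values.
#' @export
evalSurface <- function(surface, points, space = surface@space) {
  stopifnot(is(surface, "ImplicitSurface"))
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  if (space != surface@space) {
    points <- if (space == "mm")
      .mmToIndex(points, surface@spacing)
    else .indexToMM(points, surface@spacing)
  }
  K <- .phiMatrix(points, surface@centers)
  as.vector(K %*% surface@lambda + cbind(1, points) %*% surface@poly)
}

#' Sample the zero level set of a fitted surface
#'
#' Root-finds F along every z grid line of the mask (1-voxel spacing in
#' x and y): wherever F changes sign between consecutive in-mask voxels
#' the crossing is located by linear interpolation. Used to discretize
#' the algorithm surface for distance-based evaluation.
#'
#' @param surface an [ImplicitSurface-class] (index space).
#' @param mask 3D logical array restricting the sampling.
#' @param spacing voxel spacing (mm) for the returned coordinates.
#' @param stride sampling stride over the (x, y) grid.
#' @return n x 3 matrix of surface points in mm.
#' @export
sampleFittedSurface <- function(surface, mask, spacing = surface@spacing,
                                stride = 1L) {
  d <- dim(mask)
  pts <- list()
  xs <- seq(1L, d[1], by = stride)
  ys <- seq(1L, d[2], by = stride)
  zs <- seq_len(d[3])
  for (y in ys) {
    sub <- mask[xs, y, , drop = TRUE]
    if (!any(sub)) next
    xin <- xs[rowSums(sub) > 0]
    if (!length(xin)) next
    q <- cbind(rep(xin, each = d[3]), y, rep(zs, times = length(xin)))
    Fv <- matrix(evalSurface(surface, q), nrow = d[3])
    for (j in seq_along(xin)) {
      zin <- which(mask[xin[j], y, ])
      if (length(zin) < 2) next
      f <- Fv[, j]
      runs <- split(zin, cumsum(c(1, diff(zin) != 1)))
      for (zr in runs) {
        if (length(zr) < 2) next
        fz <- f[zr]
        sw <- which(fz[-length(fz)] * fz[-1] <= 0 &
                    (fz[-length(fz)] != 0 | fz[-1] != 0))
        for (s in sw) {
          z0 <- zr[s]
          t <- fz[s] / (fz[s] - fz[s + 1])
          pts[[length(pts) + 1L]] <- c(xin[j], y, z0 + t)
        }
      }
    }
  }
  if (!length(pts)) return(matrix(numeric(0), 0, 3))
  .indexToMM(do.call(rbind, pts), spacing)
}
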