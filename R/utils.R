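# Internal helpers shared across modules.

# Largest k components of a labeled array; returns label ids ordered by
# decreasing voxel count (ties by smaller label id, i.e. raster order).
.topLabels <- function(lab, k = 1L) {
  tab <- tabulate(lab[lab > 0L])
  if (!length(tab)) return(integer())
  ord <- order(-tab, seq_along(tab))
  head(ord[tab[ord] > 0], k)
}

# Per-axial-slice binary morphological closing with a square brush.
.closeAxial <- function(mask, size = 7L) {
  brush <- matrix(1, size, size)
  out <- mask
  for (k in seq_len(dim(mask)[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    out[, , k] <- EBImage::closing(sl * 1, brush) > 0.5
  }
  out
}

# Bresenham-style rasterization of the segment from p0 to p1 (2D, numeric).
# Steps along the dominant axis so consecutive pixels are 8-adjacent.
.rasterLine <- function(p0, p1) {
  d <- p1 - p0
  n <- max(abs(d))
  if (n < 1) return(matrix(round(p0), 1, 2))
  t <- seq(0, 1, length.out = floor(n) + 1L)
  cbind(round(p0[1] + t * d[1]), round(p0[2] + t * d[2]))
}

# Longest run of TRUE in a logical vector.
.longestRun <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

# Longest TRUE run with its position (first such run on ties).
.longestRunRange <- function(x) {
  if (!length(x) || !any(x)) return(list(length = 0L, start = 0L, end = 0L))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)[which.max(r$lengths[r$values])]
  list(length = r$lengths[i], start = starts[i], end = ends[i])
}

# z-standardize columns; a zero-variance column standardizes to all zeros.
.standardize <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- Inf
  sweep(sweep(m, 2, mu), 2, sd, "/")
}

# Euclidean distances from each row of a (n x 3) to the rows of b (m x 3),
# returning for each row of a the minimum distance. Chunked so memory stays
# bounded; numerically it is the plain double-loop distance.
.minDistances <- function(a, b, chunk = 256L) {
  n <- nrow(a)
  out <- numeric(n)
  bt <- t(b)
  b2 <- colSums(bt^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    ac <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(ac^2), b2, "+") - 2 * (ac %*% bt)
    j <- apply(d2, 1, which.min)
    # recompute the winning pair directly: the expanded-square form loses
    # precision for near-coincident points
    out[s:e] <- sqrt(rowSums((ac - b[j, , drop = FALSE])^2))
  }
  out
}

# Voxel indices (1-based, n x 3) to physical mm coordinates.
.indexToMM <- function(idx, spacing, origin = c(0, 0, 0)) {
  sweep(sweep(idx, 2, c(1, 1, 1)), 2, spacing, "*") +
    matrix(origin, nrow(idx), 3, byrow = TRUE)
}

.mmToIndex <- function(mm, spacing, origin = c(0, 0, 0)) {
  sweep(sweep(mm, 2, origin), 2, spacing, "/") + 1
}
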