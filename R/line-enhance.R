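# Multiscale Hessian ridge enhancement (Frangi), cost image, uniform cost
# search tracing, and the sagittal-to-coronal propagation that turns two
# sagittal fissure lines into a scattered 3D fissure point cloud.

.gaussKernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  w / sum(w)
}

# 1D convolution matrix with replicate boundary handling; y = K %*% x.
.convMatrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (t in -r:r) {
    src <- pmin(pmax(seq_len(n) - t, 1L), n)
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] +
      kernel[t + r + 1L]
  }
  K
}

.smoothSep <- function(m, sigma_row, sigma_col) {
  if (sigma_row > 0) m <- .convMatrix(nrow(m), .gaussKernel(sigma_row)) %*% m
  if (sigma_col > 0)
    m <- m %*% t(.convMatrix(ncol(m), .gaussKernel(sigma_col)))
  m
}

# Central-difference Hessian of a (smoothed) slice, in physical units,
# replicate boundary. Returns list(dyy, dzz, dyz) where axis 1 of the
# matrix is "y" (row) and axis 2 "z" (col) only by convention.
.hessian2d <- function(g, spacing) {
  nr <- nrow(g); nc <- ncol(g)
  up <- g[pmin(seq_len(nr) + 1L, nr), , drop = FALSE]
  dn <- g[pmax(seq_len(nr) - 1L, 1L), , drop = FALSE]
  rt <- g[, pmin(seq_len(nc) + 1L, nc), drop = FALSE]
  lt <- g[, pmax(seq_len(nc) - 1L, 1L), drop = FALSE]
  uprt <- up[, pmin(seq_len(nc) + 1L, nc), drop = FALSE]
  uplt <- up[, pmax(seq_len(nc) - 1L, 1L), drop = FALSE]
  dnrt <- dn[, pmin(seq_len(nc) + 1L, nc), drop = FALSE]
  dnlt <- dn[, pmax(seq_len(nc) - 1L, 1L), drop = FALSE]
  list(dyy = (up - 2 * g + dn) / spacing[1]^2,
       dzz = (rt - 2 * g + lt) / spacing[2]^2,
       dyz = (uprt - uplt - dnrt + dnlt) / (4 * spacing[1] * spacing[2]))
}

# Frangi vesselness for bright ridges from Hessian components; vectorized
# closed-form eigenvalues of the symmetric 2x2 Hessian.
.frangiResponse <- function(h, beta, cnorm) {
  tr2 <- (h$dyy + h$dzz) / 2
  disc <- sqrt(((h$dyy - h$dzz) / 2)^2 + h$dyz^2)
  e1 <- tr2 + disc
  e2 <- tr2 - disc
  swap <- abs(e1) > abs(e2)
  l1 <- ifelse(swap, e2, e1)   # |l1| <= |l2|
  l2 <- ifelse(swap, e1, e2)
  s2 <- l1^2 + l2^2
  if (is.null(cnorm)) cnorm <- sqrt(max(s2)) / 2
  # a numerically flat slice has no line structure at all
  if (cnorm <= 1e-8) return(array(0, dim = dim(h$dyy)))
  rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
  E <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cnorm^2)))
  E[l2 >= 0] <- 0
  E
}

#' Multiscale Hessian line enhancement of a 2D slice
#'
#' For each scale the slice is smoothed with an anisotropy-aware Gaussian
#' (sigma given in mm, converted to pixels per axis), the
#' sigma^2-normalized Hessian is computed by central differences, and the
#' bright-ridge (Frangi) response
#' \eqn{\exp(-(\lambda_1/\lambda_2)^2 / 2\beta^2)(1 -
#' \exp(-(\lambda_1^2+\lambda_2^2)/2c^2))} is evaluated, zero wherever
#' \eqn{\lambda_2 \ge 0}. The enhanced map E is the pointwise maximum
#' over scales.
#'
#' @param slice_hu 2D HU matrix.
#' @param spacing pixel spacing in mm along (rows, cols).
#' @param scales_mm Gaussian scales in mm; fissures are 1-3 mm thick.
#' @param beta blobness sensitivity.
#' @param cnorm structure-ness normalization; default half the maximum
#'   Hessian Frobenius norm of the slice at each scale.
#' @return Non-negative matrix E aligned with the slice.
#' @export
hessianLineEnhance <- function(slice_hu, spacing = c(1, 1),
                               scales_mm = c(0.7, 1, 1.4, 2),
                               beta = 0.5, cnorm = NULL) {
  stopifnot(is.matrix(slice_hu), all(spacing > 0), all(scales_mm > 0))
  support <- 2L * ceiling(4 * max(scales_mm) / min(spacing)) + 1L
  if (min(dim(slice_hu)) < support)
    stop("slice smaller than the largest kernel support (", support, " px)")
  E <- array(0, dim = dim(slice_hu))
  for (s in scales_mm) {
    g <- .smoothSep(slice_hu, s / spacing[1], s / spacing[2])
    h <- .hessian2d(g, spacing)
    h <- lapply(h, function(m) s^2 * m)
    E <- pmax(E, .frangiResponse(h, beta, cnorm))
  }
  E
}

#' Cost image for fissure tracing
#'
#' \code{C = max(E) - E}: pixels with a strong line response get low cost
#' so the minimal path follows the fissure.
#'
#' @param enhanced matrix E from [hessianLineEnhance].
#' @return Non-negative cost matrix with minimum 0.
#' @export
costImage <- function(enhanced) {
  m <- max(enhanced)
  if (m == 0) warning("enhancement is identically zero; cost is degenerate")
  m - enhanced
}

#' Uniform cost search over the 8-connected pixel graph
#'
#' Finds the minimum-cost path from any start pixel to any goal pixel,
#' restricted to \code{region}. The cost of an edge is the cost value of
#' its destination pixel (start pixels are free); by default diagonal
#' steps are not length-weighted, matching the edge-cost rule of the
#' tracing stage, but \code{diag_scale = TRUE} applies a sqrt(2) factor.
#' Ties are resolved by insertion order, making the search deterministic.
#'
#' @param cost cost matrix.
#' @param region logical matrix of admissible pixels.
#' @param start,goal 2-column (row, col) matrices of start and goal
#'   pixels; must be inside the region.
#' @param diag_scale weight diagonal steps by sqrt(2).
#' @return A [FissureLine-class] with the ordered path and its cost.
#' @export
ucsShortestPath <- function(cost, region, start, goal, diag_scale = FALSE) {
  stopifnot(identical(dim(cost), dim(region)),
            nrow(start) >= 1, nrow(goal) >= 1)
  lin <- function(px) px[, 1] + nrow(cost) * (px[, 2] - 1)
  s <- lin(start); g <- lin(goal)
  if (!all(region[s]) || !all(region[g]))
    stop("start and goal pixels must lie inside the region")
  res <- .ucs_path(cost, region, as.integer(s - 1L), as.integer(g - 1L),
                   diag_scale)
  if (!isTRUE(res$found))
    stop("path not found: start and goal are not connected in the region")
  p <- res$path + 1L
  path <- cbind(((p - 1L) %% nrow(cost)) + 1L,
                ((p - 1L) %/% nrow(cost)) + 1L)
  new("FissureLine", path = path, cost = res$cost, axis = "generic",
      index = 0L, lowConfidence = FALSE)
}

# Endpoint sets: project region pixels on their principal axis and take
# the extreme tails, so the path traverses the band lengthwise.
.regionEndpoints <- function(pixels, frac = 0.02) {
  ctr <- colMeans(pixels)
  cc <- sweep(pixels, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors[, 1]
  proj <- as.vector(cc %*% ev)
  if (max(proj) - min(proj) < 1e-9)
    stop("degenerate region: no principal extent")
  qs <- stats::quantile(proj, c(frac, 1 - frac), names = FALSE)
  list(start = pixels[proj <= qs[1], , drop = FALSE],
       goal = pixels[proj >= qs[2], , drop = FALSE])
}

#' Extract the fissure line from a candidate region
#'
#' Composition of the tracing stage on one slice: Hessian enhancement of
#' the slice around the region, cost image, endpoint sets from the region
#' extremes along its principal axis, and uniform cost search. The line
#' is flagged low-confidence when the traced path has essentially no
#' ridge support (mean enhancement along the path below 10% of the
#' region's maximum, or an all-zero enhancement).
#'
#' @param slice_hu 2D HU matrix.
#' @param region 2-column (row, col) matrix of region pixels.
#' @param spacing pixel spacing (mm) of the slice axes.
#' @param scales_mm,beta,cnorm passed to [hessianLineEnhance].
#' @param endpoint_frac tail fraction of the principal-axis projection
#'   used as start/goal sets.
#' @param diag_scale passed to [ucsShortestPath].
#' @param axis,index slice identity recorded on the result.
#' @return A [FissureLine-class].
#' @export
extractFissureLine <- function(slice_hu, region, spacing = c(1, 1),
                               scales_mm = c(0.7, 1, 1.4, 2), beta = 0.5,
                               cnorm = NULL, endpoint_frac = 0.02,
                               diag_scale = FALSE, axis = "sagittal",
                               index = 0L) {
  stopifnot(nrow(region) >= 2)
  pad <- ceiling(4 * max(scales_mm) / min(spacing)) + 1L
  r0 <- max(1L, min(region[, 1]) - pad)
  r1 <- min(nrow(slice_hu), max(region[, 1]) + pad)
  c0 <- max(1L, min(region[, 2]) - pad)
  c1 <- min(ncol(slice_hu), max(region[, 2]) + pad)
  crop <- slice_hu[r0:r1, c0:c1, drop = FALSE]
  E <- hessianLineEnhance(crop, spacing, scales_mm, beta, cnorm)
  regc <- cbind(region[, 1] - r0 + 1L, region[, 2] - c0 + 1L)
  rmask <- matrix(FALSE, nrow(crop), ncol(crop))
  rmask[regc] <- TRUE
  Emax <- max(E[regc])
  C <- Emax - E
  ep <- .regionEndpoints(regc, endpoint_frac)
  fl <- ucsShortestPath(C, rmask, ep$start, ep$goal, diag_scale)
  path <- cbind(fl@path[, 1] + r0 - 1L, fl@path[, 2] + c0 - 1L)
  support <- E[fl@path]
  lowconf <- Emax == 0 || mean(support) < 0.1 * Emax
  new("FissureLine", path = path, cost = fl@cost, axis = axis,
      index = as.integer(index), support = support,
      lowConfidence = lowconf)
}

# Trim a fissure line to its ridge-supported pixels: pixels whose
# enhancement is below `frac` of the path maximum are traversal filler
# (e.g. where the path runs past the end of an incomplete or absent
# fissure sheet) and carry no fissure evidence.
.supportedLine <- function(fl, frac = 0.2) {
  if (!length(fl@support) || max(fl@support) <= 0) return(fl)
  keep <- fl@support >= frac * max(fl@support)
  if (!any(keep)) return(fl)
  new("FissureLine", path = fl@path[keep, , drop = FALSE], cost = fl@cost,
      axis = fl@axis, index = fl@index, support = fl@support[keep],
      lowConfidence = fl@lowConfidence)
}

# Height of a sagittal fissure line at coronal index y (row of the path),
# linearly interpolated between path rows; NA outside a +/- tol overhang.
.lineHeightAt <- function(line, y, tol = 3) {
  rows <- line@path[, 1]
  if (y < min(rows) - tol || y > max(rows) + tol) return(NA_real_)
  z <- tapply(line@path[, 2], rows, mean)
  ys <- as.numeric(names(z))
  if (length(ys) == 1) return(as.numeric(z[1]))
  stats::approx(ys, as.numeric(z), xout = y, rule = 2)$y
}

#' Coronal candidate band between two sagittal marker points
#'
#' At coronal index \code{y} the two sagittal fissure lines provide marker
#' points m1 = (x1, z1(y)) and m2 = (x2, z2(y)); the band is every
#' lung-mask pixel of the coronal slice within \code{half_width} of the
#' infinite line through the markers.
#'
#' @param line1,line2 sagittal [FissureLine-class]s (their \code{index}
#'   slots hold the sagittal slice positions x1, x2).
#' @param y coronal slice index.
#' @param mask_slice 2D logical lung mask of the coronal slice (rows = x,
#'   cols = z).
#' @param half_width band half-width in pixels.
#' @return 2-column (row, col) matrix of band pixels, with the markers in
#'   attribute \code{"markers"}.
#' @export
coronalBand <- function(line1, line2, y, mask_slice, half_width = 10) {
  z1 <- .lineHeightAt(line1, y)
  z2 <- .lineHeightAt(line2, y)
  if (is.na(z1) || is.na(z2))
    stop("band unavailable: coronal index ", y,
         " outside the sagittal lines' extents")
  m1 <- c(line1@index, z1)
  m2 <- c(line2@index, z2)
  if (sqrt(sum((m1 - m2)^2)) < 1e-9)
    stop("degenerate markers: the two sagittal lines coincide at y = ", y)
  dir <- (m2 - m1) / sqrt(sum((m2 - m1)^2))
  px <- which(mask_slice, arr.ind = TRUE)
  rel <- cbind(px[, 1] - m1[1], px[, 2] - m1[2])
  dist <- abs(rel[, 1] * dir[2] - rel[, 2] * dir[1])
  band <- px[dist <= half_width, , drop = FALSE]
  colnames(band) <- NULL
  attr(band, "markers") <- rbind(m1, m2)
  band
}

#' Detect scattered fissure points for one fissure
#'
#' Orchestrates the per-fissure detection: the two sagittal slices at 40%
#' and 60% of the lung's x extent are scanned (SAFS) and traced; then for
#' every coronal slice spanned by both sagittal lines a candidate band is
#' interpolated between the two marker points and traced again. The
#' union of all coronal path pixels is returned as the potential fissure
#' point (PFP) set. For the right horizontal fissure the sagittal scan is
#' restricted to the part of the lung above the previously detected
#' oblique fissure line.
#'
#' @param volume a [CTVolume-class].
#' @param lung_mask one-sided [LungMask-class], ideally vessel-free (after
#'   [removeDenseStructures]).
#' @param fissure one of "left_oblique", "right_oblique",
#'   "right_horizontal".
#' @param safs_params a [safsParams] list (angle range chosen per fissure
#'   kind when NULL).
#' @param scales_mm,beta,half_width,stride tracing parameters: Frangi
#'   scales, blobness weight, coronal band half-width (pixels) and
#'   coronal slice stride.
#' @return n x 3 matrix of voxel indices (x, y, z), with mm coordinates
#'   in attribute \code{"mm"} and per-stage diagnostics in attribute
#'   \code{"diagnostics"}.
#' @export
detectFissurePoints <- function(volume, lung_mask, fissure,
                                safs_params = NULL,
                                scales_mm = c(0.7, 1, 1.4, 2), beta = 0.5,
                                half_width = 10, stride = 1L) {
  stopifnot(is(volume, "CTVolume"), is(lung_mask, "LungMask"),
            fissure %in% c("left_oblique", "right_oblique",
                           "right_horizontal"))
  if (is.null(safs_params))
    safs_params <- safsParams(
      if (fissure == "right_horizontal") "horizontal" else "oblique")
  sp <- volume@spacing
  yr <- range(which(apply(lung_mask@data, 2, any)))
  if (diff(yr) + 1L < 3L)
    stop("insufficient span: mask covers fewer than 3 coronal slices")
  xs <- selectSagittalSlices(lung_mask)
  sag <- vector("list", 2)
  obl_lines <- list()
  for (i in 1:2) {
    x <- xs[i]
    shu <- volume@data[x, , ]
    smk <- lung_mask@data[x, , ]
    if (fissure == "right_horizontal") {
      obl <- tryCatch({
        oreg <- runSAFS(shu, smk, safsParams("oblique",
                                             r = safs_params$r,
                                             k = safs_params$k,
                                             air_cut = safs_params$air_cut))
        extractFissureLine(shu, oreg@pixels, sp[c(2, 3)], scales_mm, beta,
                           axis = "sagittal", index = x)
      }, error = function(e)
        stop("SAFS failure (right oblique prerequisite, sagittal x = ", x,
             "): ", conditionMessage(e)))
      obl <- .supportedLine(obl)
      smk <- .maskAboveLine(smk, obl)
      obl_lines[[i]] <- obl
    }
    reg <- tryCatch(runSAFS(shu, smk, safs_params),
      error = function(e)
        stop("SAFS failure (", fissure, ", sagittal x = ", x, "): ",
             conditionMessage(e)))
    sag[[i]] <- .supportedLine(
      extractFissureLine(shu, reg@pixels, sp[c(2, 3)], scales_mm, beta,
                         axis = "sagittal", index = x))
    attr(sag[[i]], "theta") <- reg@theta
  }
  y0 <- max(min(sag[[1]]@path[, 1]), min(sag[[2]]@path[, 1]))
  y1 <- min(max(sag[[1]]@path[, 1]), max(sag[[2]]@path[, 1]))
  if (y1 < y0) stop("sagittal fissure lines do not overlap in y")
  pts <- list(); skipped <- 0L
  for (y in seq(y0, y1, by = stride)) {
    cmask <- lung_mask@data[, y, ]
    if (length(obl_lines) == 2) {
      # keep the horizontal search above the oblique fissure, as in the
      # sagittal stage: the oblique ridge would otherwise capture the
      # trace near the fissure crossing
      zo <- mean(c(.lineHeightAt(obl_lines[[1]], y, tol = Inf),
                   .lineHeightAt(obl_lines[[2]], y, tol = Inf)))
      if (is.finite(zo))
        cmask[, seq_len(min(ncol(cmask), max(1L, floor(zo + 2))))] <- FALSE
    }
    if (!any(cmask)) { skipped <- skipped + 1L; next }
    band <- tryCatch(coronalBand(sag[[1]], sag[[2]], y, cmask, half_width),
                     error = function(e) NULL)
    if (is.null(band) || nrow(band) < 5) { skipped <- skipped + 1L; next }
    fl <- tryCatch(
      extractFissureLine(volume@data[, y, ], band, sp[c(1, 3)], scales_mm,
                         beta, axis = "coronal", index = y),
      error = function(e) NULL)
    if (is.null(fl)) { skipped <- skipped + 1L; next }
    fl <- .supportedLine(fl)
    pts[[length(pts) + 1L]] <- cbind(fl@path[, 1], y, fl@path[, 2])
  }
  if (!length(pts)) stop("no coronal fissure line could be traced")
  pfp <- unique(do.call(rbind, pts))
  attr(pfp, "mm") <- .indexToMM(pfp, sp, volume@origin)
  attr(pfp, "diagnostics") <- list(
    sagittal_slices = xs,
    sagittal_angles = vapply(sag, function(l) attr(l, "theta"), numeric(1)),
    sagittal_low_confidence = vapply(sag, function(l) l@lowConfidence,
                                     logical(1)),
    coronal_range = c(y0, y1), coronal_skipped = skipped,
    n_points = nrow(pfp))
  pfp
}

# Restrict a sagittal mask to the part above (superior to) a fissure line,
# used to search the right horizontal fissure anterior-superior of the
# oblique one.
.maskAboveLine <- function(mask, line, clearance = 2) {
  rows <- line@path[, 1]
  z <- tapply(line@path[, 2], rows, mean)
  ys <- as.numeric(names(z))
  out <- mask
  allc <- col(mask)
  zline <- stats::approx(ys, as.numeric(z), xout = seq_len(nrow(mask)),
                         rule = 2)$y
  out[allc <= zline[row(out)] + clearance] <- FALSE
  out
}
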