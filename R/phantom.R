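#' Specification of a synthetic thorax phantom
#'
#' The phantom emulates the CT appearance the detection pipeline relies on:
#' two ellipsoidal lungs of aerated parenchyma (default -880 +/- 20 HU)
#' embedded in soft tissue (0 HU) surrounded by air (-1000 HU); thin
#' fissure sheets rendered slightly denser than parenchyma (-660 HU, 1-2
#' voxels thick) so they stay inside the lung-segmentation HU band; bright
#' vessels (+50 HU) radiating from the hilum that never enter a vessel-free
#' margin around the fissures; and optional nodules and emphysema blobs
#' (below -950 HU). Fissure surfaces are graphs \eqn{z = c_0 + c_1 (y -
#' y_c) + c_2 (y - y_c)^2} in voxel-index units (\eqn{y_c} the lung centre),
#' so the ground-truth lobe labels and surface samples are analytic.
#'
#' @param shape grid dimensions (x, y, z) in voxels.
#' @param spacing voxel spacing in mm.
#' @param parenchyma_hu,parenchyma_sd mean and SD of parenchymal HU noise.
#' @param body_hu,air_hu HU of soft tissue and surrounding air.
#' @param fissure_hu,fissure_thickness HU and thickness (voxels) of the
#'   fissure sheets.
#' @param vessel_hu,vessels_per_lung,vessel_radius HU of the vessels, the
#'   number of root branches radiating from each hilum (the tree
#'   bifurcates over four generations), and the root radius range
#'   (voxels).
#' @param vessel_margin vessel-free margin around fissure sheets (voxels);
#'   must be at least the fissure thickness.
#' @param peripheral_spacing,peripheral_radius jittered-grid spacing and
#'   radius (voxels) of the small peripheral vessels that fill the
#'   parenchyma between the tree branches; 0 spacing disables them.
#' @param left_center,left_semiaxes,right_center,right_semiaxes lung
#'   ellipsoid geometry in voxel indices.
#' @param left_oblique,right_oblique,right_horizontal fissure coefficients
#'   \code{c(z0, slope, quad)}; set to NULL to omit a fissure.
#' @param incomplete_fraction fraction of each fissure sheet erased in
#'   random patches (models incomplete fissures).
#' @param nodules,emphysema lists of \code{list(center, radius, hu)}
#'   spheres added to the volume.
#' @param seed RNG seed; the phantom is deterministic given the seed.
#' @return A validated spec list for [generatePhantom].
#' @export
phantomSpec <- function(shape = c(96, 128, 128), spacing = c(1, 1, 1),
                        parenchyma_hu = -880, parenchyma_sd = 20,
                        body_hu = 0, air_hu = -1000,
                        fissure_hu = -660, fissure_thickness = 2,
                        vessel_hu = 50, vessels_per_lung = 12,
                        vessel_radius = c(1.4, 2), vessel_margin = 5,
                        peripheral_spacing = 8, peripheral_radius = 1.6,
                        left_center = c(70, 64, 64),
                        left_semiaxes = c(19, 40, 50),
                        right_center = c(27, 64, 64),
                        right_semiaxes = c(19, 40, 50),
                        left_oblique = c(64.25, 0.9, 0),
                        right_oblique = c(64.25, 0.9, 0),
                        right_horizontal = c(80.3, 0, 0),
                        incomplete_fraction = 0,
                        nodules = list(),
                        emphysema = list(list(center = c(70, 50, 90),
                                              radius = 3, hu = -980)),
                        seed = 1L) {
  if (vessel_margin < fissure_thickness)
    stop("spec error: vessel_margin must be >= fissure_thickness")
  if (any(shape < 32)) stop("spec error: grid too small")
  if (any(spacing <= 0)) stop("spec error: spacing must be positive")
  spec <- as.list(environment())
  class(spec) <- c("phantomSpec", class(spec))
  spec
}

.ellipsoidValue <- function(X, Y, Z, center, semi) {
  ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2
}

# Fissure surface height z = f(y) and local slope df/dy, index units.
.fissureZ <- function(coef, y, yc) {
  coef[1] + coef[2] * (y - yc) + coef[3] * (y - yc)^2
}
.fissureSlope <- function(coef, y, yc) coef[2] + 2 * coef[3] * (y - yc)

# Vertical-to-perpendicular correction: distance from (y, z) to the sheet.
.fissureDistance <- function(coef, y, z, yc) {
  abs(z - .fissureZ(coef, y, yc)) / sqrt(1 + .fissureSlope(coef, y, yc)^2)
}

.sphereVoxels <- function(center, radius, shape) {
  r <- ceiling(radius)
  gx <- max(1, floor(center[1] - r)):min(shape[1], ceiling(center[1] + r))
  gy <- max(1, floor(center[2] - r)):min(shape[2], ceiling(center[2] + r))
  gz <- max(1, floor(center[3] - r)):min(shape[3], ceiling(center[3] + r))
  g <- expand.grid(x = gx, y = gy, z = gz)
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  as.matrix(g[d2 <= radius^2, , drop = FALSE])
}

#' Generate a seeded synthetic thorax phantom
#'
#' Builds the HU volume, the analytic lung mask, ground-truth five-lobe
#' labels (derived from the signs of the generating surface functions with
#' the same precedence used by [classifyLobes]) and dense ground-truth
#' surface samples for every fissure present in the spec.
#'
#' @param spec a [phantomSpec] list.
#' @return A [Phantom-class] object.
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  set.seed(spec$seed)
  sh <- spec$shape
  X <- array(rep(seq_len(sh[1]), times = sh[2] * sh[3]), dim = sh)
  Y <- array(rep(rep(seq_len(sh[2]), each = sh[1]), times = sh[3]), dim = sh)
  Z <- array(rep(seq_len(sh[3]), each = sh[1] * sh[2]), dim = sh)

  body_center <- c((sh[1] + 1) / 2, (sh[2] + 1) / 2, (sh[3] + 1) / 2)
  body_semi <- (sh - 4) / 2
  body <- .ellipsoidValue(X, Y, Z, body_center, body_semi) <= 1
  leftMask <- .ellipsoidValue(X, Y, Z, spec$left_center,
                              spec$left_semiaxes) <= 1
  rightMask <- .ellipsoidValue(X, Y, Z, spec$right_center,
                               spec$right_semiaxes) <= 1
  lungMask <- leftMask | rightMask

  hu <- array(spec$air_hu, dim = sh)
  hu[body] <- spec$body_hu
  npar <- sum(lungMask)
  hu[lungMask] <- spec$parenchyma_hu +
    if (spec$parenchyma_sd > 0) stats::rnorm(npar, 0, spec$parenchyma_sd)
    else 0

  fissures <- list(left_oblique = spec$left_oblique,
                   right_oblique = spec$right_oblique,
                   right_horizontal = spec$right_horizontal)
  fissures <- fissures[!vapply(fissures, is.null, logical(1))]
  lungOf <- c(left_oblique = "left", right_oblique = "right",
              right_horizontal = "right")
  ycOf <- c(left = spec$left_center[2], right = spec$right_center[2])

  sheetAll <- array(FALSE, dim = sh)
  for (nm in names(fissures)) {
    side <- lungOf[[nm]]
    inLung <- if (side == "left") leftMask else rightMask
    dz <- abs(Z - .fissureZ(fissures[[nm]], Y, ycOf[[side]]))
    sheet <- inLung & dz <= spec$fissure_thickness / 2
    if (nm == "right_horizontal" && !is.null(fissures$right_oblique)) {
      # the horizontal fissure only exists anterior to the oblique one,
      # where it separates the upper from the middle lobe
      sheet <- sheet &
        .fissureZ(fissures$right_horizontal, Y, ycOf[["right"]]) >
          .fissureZ(fissures$right_oblique, Y, ycOf[["right"]])
    }
    if (!any(sheet))
      stop("spec error: fissure ", nm, " does not intersect its lung")
    if (spec$incomplete_fraction > 0)
      sheet <- .erasePatches(sheet, spec$incomplete_fraction)
    hu[sheet] <- spec$fissure_hu
    sheetAll <- sheetAll | sheet
  }

  # vessels: tubes radiating from each hilum, clipped to the lung and kept
  # outside the vessel-free margin of every fissure in that lung
  for (side in c("left", "right")) {
    inLung <- if (side == "left") leftMask else rightMask
    center <- if (side == "left") spec$left_center else spec$right_center
    semi <- if (side == "left") spec$left_semiaxes else spec$right_semiaxes
    medial <- if (side == "left") -1 else 1  # toward the mediastinum
    hilum <- center + c(medial * 0.6 * semi[1], 0, 0)
    fset <- fissures[lungOf[names(fissures)] == side]
    vox <- .vesselVoxels(spec, hilum, center, semi, fset, ycOf[[side]], sh)
    if (nrow(vox)) {
      lin <- vox[, 1] + sh[1] * (vox[, 2] - 1 + sh[2] * (vox[, 3] - 1))
      lin <- lin[inLung[lin] & !sheetAll[lin]]
      hu[lin] <- spec$vessel_hu
    }
  }

  for (nd in c(spec$nodules, spec$emphysema)) {
    vox <- .sphereVoxels(nd$center, nd$radius, sh)
    lin <- vox[, 1] + sh[1] * (vox[, 2] - 1 + sh[2] * (vox[, 3] - 1))
    hu[lin] <- nd$hu
  }

  truth <- .truthLobes(spec, leftMask, rightMask, Y, Z, fissures, ycOf)
  for (side in c("left", "right")) {
    want <- if (side == "left") {
      if (!is.null(fissures$left_oblique)) c(1L, 2L) else 1L
    } else {
      c(5L,
        if (!is.null(fissures$right_oblique)) 4L,
        if (!is.null(fissures$right_horizontal)) 3L)
    }
    have <- unique(truth[if (side == "left") leftMask else rightMask])
    if (!all(want %in% have))
      stop("spec error: a fissure fails to split the ", side,
           " lung into its lobes")
  }

  surfaces <- lapply(names(fissures), function(nm) {
    side <- lungOf[[nm]]
    .truthSurfaceGrid(spec, fissures[[nm]], side, ycOf[[side]],
                      clip = .horizontalClip(spec, nm))
  })
  names(surfaces) <- names(fissures)

  new("Phantom",
      volume = CTVolume(hu, spacing = spec$spacing),
      truthLobes = LabelMap(truth, spacing = spec$spacing),
      truthLungMask = lungMask,
      truthSurfaces = surfaces,
      spec = unclass(spec))
}

# Ground-truth labels from the analytic surface functions, evaluated with
# the same precedence as classifyLobes: right upper wins when F3 > 0, then
# the oblique sign splits middle from lower; on the left the lower lobe
# takes F1 >= 0.
.truthLobes <- function(spec, leftMask, rightMask, Y, Z, fissures, ycOf) {
  truth <- array(0L, dim = spec$shape)
  if (!is.null(fissures$left_oblique)) {
    F1 <- .fissureZ(fissures$left_oblique, Y, ycOf[["left"]]) - Z
    truth[leftMask] <- ifelse(F1[leftMask] >= 0, 2L, 1L)
  } else truth[leftMask] <- 1L
  F2 <- if (!is.null(fissures$right_oblique))
    Z - .fissureZ(fissures$right_oblique, Y, ycOf[["right"]]) else NULL
  F3 <- if (!is.null(fissures$right_horizontal))
    Z - .fissureZ(fissures$right_horizontal, Y, ycOf[["right"]]) else NULL
  r <- which(rightMask)
  lab <- rep(5L, length(r))
  if (!is.null(F2)) lab[F2[r] > 0] <- 4L
  if (!is.null(F3)) lab[F3[r] > 0] <- 3L
  truth[r] <- lab
  truth
}

# Clip rule for the horizontal fissure: it exists only where it lies
# above (superior to) the oblique fissure surface.
.horizontalClip <- function(spec, fissure) {
  if (fissure == "right_horizontal" && !is.null(spec$right_oblique))
    spec$right_oblique
  else NULL
}

.truthSurfaceGrid <- function(spec, coef, side, yc, clip = NULL) {
  center <- if (side == "left") spec$left_center else spec$right_center
  semi <- if (side == "left") spec$left_semiaxes else spec$right_semiaxes
  g <- expand.grid(x = seq_len(spec$shape[1]), y = seq_len(spec$shape[2]))
  z <- .fissureZ(coef, g$y, yc)
  keep <- .ellipsoidValue(g$x, g$y, z, center, semi) <= 1 &
    z >= 1 & z <= spec$shape[3]
  if (!is.null(clip)) keep <- keep & z > .fissureZ(clip, g$y, yc)
  pts <- cbind(g$x[keep], g$y[keep], z[keep])
  .indexToMM(pts, spec$spacing)
}

.erasePatches <- function(sheet, fraction) {
  vox <- which(sheet, arr.ind = TRUE)
  target <- ceiling(fraction * nrow(vox))
  erased <- rep(FALSE, nrow(vox))
  radius <- 6
  while (sum(erased) < target) {
    c0 <- vox[sample.int(nrow(vox), 1), ]
    d2 <- (vox[, 1] - c0[1])^2 + (vox[, 2] - c0[2])^2 + (vox[, 3] - c0[3])^2
    erased <- erased | d2 <= radius^2
  }
  sheet[vox[erased, , drop = FALSE]] <- FALSE
  sheet
}

# Vessel tree: root branches radiate from the hilum and bifurcate over
# several generations with shrinking radius, so the vasculature fills the
# parenchyma out to the periphery — the density the fissure scan relies on
# to reject non-fissure lines — while every voxel within the vessel-free
# margin of a fissure sheet is left untouched.
.vesselVoxels <- function(spec, hilum, center, semi, fset, yc, sh) {
  n <- spec$vessels_per_lung
  if (n <= 0) return(matrix(numeric(0), 0, 3))
  segs <- list()
  frontier <- lapply(seq_len(n), function(i) {
    dir <- stats::rnorm(3)
    list(p = hilum, dir = dir / sqrt(sum(dir^2)),
         radius = stats::runif(1, spec$vessel_radius[1],
                               spec$vessel_radius[2]))
  })
  lengths <- max(semi) * c(0.35, 0.3, 0.25, 0.2)
  for (gen in seq_along(lengths)) {
    nxt <- list()
    for (br in frontier) {
      q <- br$p + lengths[gen] * br$dir
      segs[[length(segs) + 1L]] <- list(a = br$p, b = q, radius = br$radius)
      if (gen < length(lengths)) {
        for (child in 1:2) {
          dd <- br$dir + 0.7 * stats::rnorm(3)
          nxt[[length(nxt) + 1L]] <-
            list(p = q, dir = dd / sqrt(sum(dd^2)),
                 radius = max(0.8, br$radius * 0.78))
        }
      }
    }
    frontier <- nxt
  }
  vox <- lapply(segs, function(sg) {
    ts <- seq(0, 1, by = 0.5 / max(1, sqrt(sum((sg$b - sg$a)^2))))
    pts <- cbind(sg$a[1] + ts * (sg$b[1] - sg$a[1]),
                 sg$a[2] + ts * (sg$b[2] - sg$a[2]),
                 sg$a[3] + ts * (sg$b[3] - sg$a[3]))
    r <- ceiling(sg$radius)
    off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
    off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= sg$radius^2, ,
               drop = FALSE]
    cbind(rep(round(pts[, 1]), each = nrow(off)) + off$dx,
          rep(round(pts[, 2]), each = nrow(off)) + off$dy,
          rep(round(pts[, 3]), each = nrow(off)) + off$dz)
  })
  # small peripheral vessels: spheres on a jittered grid filling the lung,
  # so that every scan line away from a fissure crosses vasculature
  gs <- spec$peripheral_spacing
  if (gs > 0) {
    ctr <- expand.grid(
      x = seq(center[1] - semi[1], center[1] + semi[1], by = gs),
      y = seq(center[2] - semi[2], center[2] + semi[2], by = gs),
      z = seq(center[3] - semi[3], center[3] + semi[3], by = gs))
    ctr <- ctr + matrix(stats::runif(3 * nrow(ctr), -gs / 4, gs / 4),
                        ncol = 3)
    keep <- .ellipsoidValue(ctr[, 1], ctr[, 2], ctr[, 3], center,
                            semi) <= 0.98
    ctr <- as.matrix(ctr[keep, , drop = FALSE])
    pr <- spec$peripheral_radius
    off <- expand.grid(dx = -2:2, dy = -2:2, dz = -2:2)
    off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= pr^2, , drop = FALSE]
    vox[[length(vox) + 1L]] <-
      cbind(rep(round(ctr[, 1]), each = nrow(off)) + off$dx,
            rep(round(ctr[, 2]), each = nrow(off)) + off$dy,
            rep(round(ctr[, 3]), each = nrow(off)) + off$dz)
  }
  vox <- unique(do.call(rbind, vox))
  ok <- vox[, 1] >= 1 & vox[, 1] <= sh[1] & vox[, 2] >= 1 &
    vox[, 2] <= sh[2] & vox[, 3] >= 1 & vox[, 3] <= sh[3]
  vox <- vox[ok, , drop = FALSE]
  if (!nrow(vox)) return(vox)
  far <- rep(TRUE, nrow(vox))
  for (nm in names(fset)) {
    near <- .fissureDistance(fset[[nm]], vox[, 2], vox[, 3], yc) <=
      spec$vessel_margin
    clip <- .horizontalClip(spec, nm)
    if (!is.null(clip))
      near <- near & .fissureZ(fset[[nm]], vox[, 2], yc) >
        .fissureZ(clip, vox[, 2], yc)
    far <- far & !near
  }
  vox[far, , drop = FALSE]
}

#' Sample points on an analytic ground-truth fissure surface
#'
#' Draws \code{n} points uniformly over the surface's (x, y) footprint
#' inside the lung, deterministic given the phantom's seed.
#'
#' @param phantom a [Phantom-class].
#' @param fissure one of "left_oblique", "right_oblique",
#'   "right_horizontal".
#' @param n number of points (>= 1).
#' @return n x 3 matrix of points in mm.
#' @export
sampleTruthSurface <- function(phantom, fissure, n) {
  stopifnot(is(phantom, "Phantom"), n >= 1)
  spec <- phantom@spec
  coef <- spec[[fissure]]
  if (is.null(coef) || !fissure %in% names(phantom@truthSurfaces))
    stop("lookup error: fissure '", fissure, "' is absent from the spec")
  side <- if (fissure == "left_oblique") "left" else "right"
  center <- if (side == "left") spec$left_center else spec$right_center
  semi <- if (side == "left") spec$left_semiaxes else spec$right_semiaxes
  set.seed(spec$seed + 1000L +
           match(fissure, c("left_oblique", "right_oblique",
                            "right_horizontal")))
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n) {
    m <- max(4L * n, 64L)
    x <- stats::runif(m, center[1] - semi[1], center[1] + semi[1])
    y <- stats::runif(m, center[2] - semi[2], center[2] + semi[2])
    z <- .fissureZ(coef, y, center[2])
    keep <- .ellipsoidValue(x, y, z, center, semi) <= 1
    clip <- .horizontalClip(spec, fissure)
    if (!is.null(clip)) keep <- keep & z > .fissureZ(clip, y, center[2])
    pts <- rbind(pts, cbind(x, y, z)[keep, , drop = FALSE])
  }
  .indexToMM(pts[seq_len(n), , drop = FALSE], spec$spacing)
}
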