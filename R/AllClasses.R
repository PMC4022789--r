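#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib lobeseg, .registration = TRUE
NULL

#' Five-lobe label legend
#'
#' Integer codes used in every [LabelMap-class] produced by the package:
#' 0 = background, 1 = left upper, 2 = left lower, 3 = right upper,
#' 4 = right middle (intermediate), 5 = right lower.
#'
#' @export
lobeLegend <- c(background = 0L, left_upper = 1L, left_lower = 2L,
                right_upper = 3L, right_middle = 4L, right_lower = 5L)

#' CTVolume: a 3D Hounsfield-unit volume on a physical lattice
#'
#' Canonical anatomical orientation is enforced on construction and load:
#' axis 1 runs right to left (a sagittal slice fixes this index), axis 2
#' anterior to posterior (coronal), axis 3 inferior to superior (axial).
#' Voxel indices are 1-based; the physical coordinate of voxel
#' \eqn{(i,j,k)} is \code{origin + (c(i,j,k) - 1) * spacing}, in mm.
#'
#' @slot data 3D numeric array of Hounsfield units.
#' @slot spacing numeric(3), voxel size in mm along (x, y, z); all > 0.
#' @slot origin numeric(3), physical coordinate of voxel (1,1,1) in mm.
#' @slot orientation single string; always \code{"LPS"} after canonicalization.
#' @export
setClass("CTVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 orientation = "character"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), orientation = "LPS"))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers")
  if (!identical(object@orientation, "LPS"))
    msg <- c(msg, "orientation must be the canonical 'LPS'")
  if (length(msg)) msg else TRUE
})

#' Construct a CTVolume
#'
#' @param data 3D array of Hounsfield units (assumed already canonical).
#' @param spacing voxel size in mm per axis.
#' @param origin physical coordinate of voxel (1,1,1) in mm.
#' @return A [CTVolume-class] object.
#' @export
CTVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("CTVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = "LPS")
}

#' LabelMap: integer labels on a CT lattice
#'
#' @slot data 3D integer array on the same lattice as its source volume.
#' @slot spacing,origin lattice geometry, as in [CTVolume-class].
#' @slot legend named integer vector mapping label names to codes.
#' @export
setClass("LabelMap",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 legend = "integer"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), legend = lobeLegend))

setValidity("LabelMap", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
  lv <- unique(as.vector(object@data))
  if (length(lv) && !all(lv %in% object@legend))
    msg <- c(msg, "labels present that are not in the legend")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelMap
#' @param data 3D array of small non-negative integer labels.
#' @param spacing,origin lattice geometry in mm.
#' @param legend named integer vector of permitted codes.
#' @return A [LabelMap-class] object.
#' @export
LabelMap <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     legend = lobeLegend) {
  storage.mode(data) <- "integer"
  new("LabelMap", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), legend = legend)
}

#' LungMask: a binary lung mask with side tag and bounding box
#'
#' @slot data 3D logical array on the CT lattice.
#' @slot spacing,origin lattice geometry, as in [CTVolume-class].
#' @slot side one of "left", "right", "both".
#' @export
setClass("LungMask",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 side = "character"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), side = "both"))

setValidity("LungMask", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L || !is.logical(object@data))
    msg <- c(msg, "data must be a 3D logical array")
  if (!object@side %in% c("left", "right", "both"))
    msg <- c(msg, "side must be left, right or both")
  if (length(msg)) msg else TRUE
})

#' Construct a LungMask
#' @param data 3D logical array.
#' @param spacing,origin lattice geometry in mm.
#' @param side "left", "right" or "both".
#' @return A [LungMask-class] object.
#' @export
LungMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     side = "both") {
  storage.mode(data) <- "logical"
  new("LungMask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), side = side)
}

#' FissureRegion: a candidate fissure band in a 2D slice
#'
#' The pixel set is the largest 8-connected component of the union of the
#' accepted scan lines' vessel-free run segments at one angle, together
#' with the score features: N (number of accepted scan lines intersecting
#' the component), sdR and meanR (standard deviation and mean of the
#' lengths of those lines' segments inside the component), and the
#' likelihood score P.
#'
#' @slot theta scan angle in degrees.
#' @slot pixels 2-column integer matrix of (row, col) pixel indices.
#' @slot nLines number of contributing accepted scan lines.
#' @slot sdR,meanR standard deviation / mean of the in-region scan-line
#'   segment lengths (pixels).
#' @slot score likelihood score P (set by [scoreRegion]).
#' @export
setClass("FissureRegion",
  representation(theta = "numeric", pixels = "matrix", nLines = "integer",
                 sdR = "numeric", meanR = "numeric", score = "numeric"),
  prototype(score = NA_real_))

#' FissureLine: an ordered minimal-cost pixel path
#'
#' @slot path 2-column integer matrix of (row, col) pixels, consecutive
#'   pixels 8-adjacent.
#' @slot cost total path cost under the cost image.
#' @slot axis slicing axis the line lives in ("sagittal" or "coronal").
#' @slot index slice index along that axis.
#' @slot support per-path-pixel line-enhancement response (empty when the
#'   line was not produced by the enhancement stage); pixels without
#'   ridge support are path filler, not fissure evidence.
#' @slot lowConfidence flag set when the traced path shows no ridge support.
#' @export
setClass("FissureLine",
  representation(path = "matrix", cost = "numeric", axis = "character",
                 index = "integer", support = "numeric",
                 lowConfidence = "logical"),
  prototype(lowConfidence = FALSE, support = numeric()))

#' ImplicitSurface: tri-harmonic RBF implicit fissure surface
#'
#' Represents \eqn{F(x) = \sum_i \lambda_i |x - x_i|^3 + c_0 + c_1 x + c_2 y
#' + c_3 z}; the zero level set is the fissure, and the sign of F encodes
#' the lobe side (positive on the off-surface-point side).
#'
#' @slot centers m x 3 matrix of RBF centers (on- and off-surface points).
#' @slot lambda numeric(m) RBF coefficients.
#' @slot poly numeric(4) polynomial coefficients c0..c3.
#' @slot fissure one of "left_oblique", "right_oblique", "right_horizontal".
#' @slot space coordinate convention of the centers: "index" or "mm".
#' @slot spacing voxel spacing used to convert between index and mm.
#' @slot d off-surface distance used during the fit.
#' @export
setClass("ImplicitSurface",
  representation(centers = "matrix", lambda = "numeric", poly = "numeric",
                 fissure = "character", space = "character",
                 spacing = "numeric", d = "numeric"),
  prototype(space = "index", spacing = c(1, 1, 1), d = 10))

setValidity("ImplicitSurface", function(object) {
  msg <- character()
  if (ncol(object@centers) != 3L) msg <- c(msg, "centers must be m x 3")
  if (length(object@lambda) != nrow(object@centers))
    msg <- c(msg, "lambda length must equal number of centers")
  if (length(object@poly) != 4L) msg <- c(msg, "poly must have length 4")
  if (!object@space %in% c("index", "mm"))
    msg <- c(msg, "space must be 'index' or 'mm'")
  if (length(msg)) msg else TRUE
})

#' Phantom: synthetic thorax volume with analytic ground truth
#'
#' @slot volume synthetic [CTVolume-class].
#' @slot truthLobes ground-truth five-lobe [LabelMap-class].
#' @slot truthLungMask 3D logical array, the analytic lung field.
#' @slot truthSurfaces named list of n x 3 matrices of points (mm) sampled
#'   densely on the generating fissure surfaces.
#' @slot spec the [phantomSpec] list the phantom was generated from.
#' @export
setClass("Phantom",
  representation(volume = "CTVolume", truthLobes = "LabelMap",
                 truthLungMask = "array", truthSurfaces = "list",
                 spec = "list"))

#' DistanceStats: shortest-distance surface accuracy summary
#'
#' Distances are measured from each reference point to the nearest
#' algorithm point (reference to algorithm direction), in mm.
#'
#' @slot distances numeric vector of per-reference-point distances (mm).
#' @slot mean,sd,rms,max summary statistics of the distances (mm).
#' @slot n number of reference points.
#' @export
setClass("DistanceStats",
  representation(distances = "numeric", mean = "numeric", sd = "numeric",
                 rms = "numeric", max = "numeric", n = "integer"))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("CTVolume %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  HU range [%g, %g], orientation %s\n",
              min(object@data), max(object@data), object@orientation))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@data)
  tab <- table(factor(as.vector(object@data), levels = object@legend,
                      labels = names(object@legend)))
  cat(sprintf("LabelMap %d x %d x %d voxels\n", d[1], d[2], d[3]))
  for (nm in names(tab))
    if (tab[[nm]] > 0) cat(sprintf("  %-13s %d voxels\n", nm, tab[[nm]]))
})

setMethod("show", "LungMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("LungMask (%s) %d x %d x %d, %d voxels set\n", object@side,
              d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "FissureRegion", function(object) {
  cat(sprintf(
    "FissureRegion theta=%.2f deg: %d px, N=%d, meanR=%.1f, sdR=%.2f, P=%s\n",
    object@theta, nrow(object@pixels), object@nLines, object@meanR,
    object@sdR, format(object@score)))
})

setMethod("show", "FissureLine", function(object) {
  cat(sprintf("FissureLine (%s slice %d): %d px, cost %.4g%s\n",
              object@axis, object@index, nrow(object@path), object@cost,
              if (object@lowConfidence) " [low confidence]" else ""))
})

setMethod("show", "ImplicitSurface", function(object) {
  cat(sprintf("ImplicitSurface '%s': %d centers (%s space), d = %g\n",
              object@fissure, nrow(object@centers), object@space, object@d))
})

setMethod("show", "Phantom", function(object) {
  cat("Synthetic thorax phantom\n")
  show(object@volume)
  cat(sprintf("  truth surfaces: %s\n",
              paste(names(object@truthSurfaces), collapse = ", ")))
})

setMethod("show", "DistanceStats", function(object) {
  cat(sprintf(
    "Surface distances (n=%d): mean %.3f +/- %.3f, RMS %.3f, max %.3f mm\n",
    object@n, object@mean, object@sd, object@rms, object@max))
})
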