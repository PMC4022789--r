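#' Extract the lung field by dual-threshold growing and closing
#'
#' Voxels inside the acceptance band \code{[lower_hu, upper_hu]} (default
#' [-930, -650] HU) are grown into 3D connected components; the band is
#' deliberately conservative so that outside air and the tracheal lumen
#' (below -930 HU) and soft tissue (above -650 HU) never leak into the
#' lung. The two largest components (the lungs) are kept and a 7 x 7
#' square morphological closing is applied on every axial slice to fill
#' vessel holes.
#'
#' @param volume a [CTVolume-class] in HU.
#' @param lower_hu,upper_hu acceptance band in HU.
#' @param closing_size side of the square closing kernel (pixels).
#' @param min_volume_cm3 minimum total lung volume; below it the
#'   segmentation is considered failed.
#' @return A [LungMask-class] with side "both".
#' @export
segmentLungs <- function(volume, lower_hu = -930, upper_hu = -650,
                         closing_size = 7L, min_volume_cm3 = 200) {
  stopifnot(is(volume, "CTVolume"))
  band <- volume@data >= lower_hu & volume@data <= upper_hu
  if (!any(band))
    stop("segmentation failure: no voxel in [", lower_hu, ", ", upper_hu,
         "] HU")
  lab <- .label3d6(band, dim(band))
  keep <- .topLabels(lab, 2L)
  mask <- array(lab %in% keep, dim = dim(band))
  mask <- .closeAxial(mask, closing_size)
  vox_cm3 <- prod(volume@spacing) / 1000
  if (sum(mask) * vox_cm3 < min_volume_cm3)
    stop("segmentation failure: lung volume ",
         round(sum(mask) * vox_cm3, 1), " cm^3 below ", min_volume_cm3)
  LungMask(mask, spacing = volume@spacing, origin = volume@origin,
           side = "both")
}

#' Remove dense structures (vessels, tracheal walls) from a lung mask
#'
#' Discards every mask voxel whose HU exceeds \code{hu_cut} (default
#' -300 HU), removing vascular and airway-wall voxels that the closing
#' step folded into the lung field.
#'
#' @param volume the HU [CTVolume-class].
#' @param lung_mask a [LungMask-class] on the same lattice.
#' @param hu_cut threshold in HU.
#' @return The filtered [LungMask-class].
#' @export
removeDenseStructures <- function(volume, lung_mask, hu_cut = -300) {
  stopifnot(is(volume, "CTVolume"), is(lung_mask, "LungMask"),
            identical(dim(volume@data), dim(lung_mask@data)))
  mask <- lung_mask@data & volume@data <= hu_cut
  LungMask(mask, spacing = lung_mask@spacing, origin = lung_mask@origin,
           side = lung_mask@side)
}

#' Split a lung mask into left and right lungs
#'
#' The two largest 3D components are assigned by centroid along the
#' right-to-left axis (the right lung has the smaller x centroid in the
#' canonical frame). If the lungs are merged into a single component, the
#' mask is cut at the sagittal plane of minimum cross-sectional area
#' searched over the middle third of the x range.
#'
#' @param lung_mask a [LungMask-class] (side "both").
#' @return List with elements \code{left} and \code{right}
#'   ([LungMask-class] each); with a warning, one element may be an empty
#'   mask if only a single lung is present.
#' @export
splitLungs <- function(lung_mask) {
  stopifnot(is(lung_mask, "LungMask"))
  if (!any(lung_mask@data)) stop("empty lung mask")
  d <- dim(lung_mask@data)
  lab <- .label3d6(lung_mask@data, d)
  top <- .topLabels(lab, 2L)
  sizes <- tabulate(lab[lab > 0L])
  mk <- function(arr, side)
    LungMask(arr, spacing = lung_mask@spacing, origin = lung_mask@origin,
             side = side)
  if (length(top) >= 2 && sizes[top[2]] > 0.2 * sizes[top[1]]) {
    m1 <- array(lab == top[1], dim = d)
    m2 <- array(lab == top[2], dim = d)
    cx1 <- mean(which(m1, arr.ind = TRUE)[, 1])
    cx2 <- mean(which(m2, arr.ind = TRUE)[, 1])
    if (cx1 < cx2) list(left = mk(m2, "left"), right = mk(m1, "right"))
    else list(left = mk(m1, "left"), right = mk(m2, "right"))
  } else {
    # single merged component: cut at the minimum-area sagittal plane
    merged <- array(lab == top[1], dim = d)
    xs <- range(which(apply(merged, 1, any)))
    lo <- xs[1] + floor((xs[2] - xs[1]) / 3)
    hi <- xs[1] + ceiling(2 * (xs[2] - xs[1]) / 3)
    areas <- vapply(lo:hi, function(x) sum(merged[x, , ]), numeric(1))
    xcut <- (lo:hi)[which.min(areas)]
    right <- merged; right[(xcut + 1):d[1], , ] <- FALSE
    left <- merged; left[1:xcut, , ] <- FALSE
    if (!any(left) || !any(right)) {
      warning("single lung detected; returning a one-sided result")
      if (any(left)) return(list(left = mk(left, "left"),
                                 right = mk(array(FALSE, d), "right")))
      return(list(left = mk(array(FALSE, d), "left"),
                  right = mk(right, "right")))
    }
    list(left = mk(left, "left"), right = mk(right, "right"))
  }
}
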