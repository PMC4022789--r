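#' Classify lung voxels into five lobes from the implicit surfaces
#'
#' Left lung: voxels with \eqn{F_1 \ge 0} are left lower, the rest left
#' upper (the oblique surface is fitted with its positive side
#' posterior-inferior). Right lung, evaluated with first-match
#' precedence: \eqn{F_3 > 0} right upper; otherwise \eqn{F_2 > 0} right
#' middle (intermediate); otherwise right lower. Exact zeros fall
#' through to the more inferior lobe. A missing surface degrades that
#' side to a single lobe with a warning.
#'
#' @param left_mask,right_mask one-sided [LungMask-class]es (disjoint).
#' @param F1 left oblique [ImplicitSurface-class] (or NULL).
#' @param F2 right oblique surface (or NULL).
#' @param F3 right horizontal surface (or NULL).
#' @return A [LabelMap-class] with the five-lobe legend.
#' @export
classifyLobes <- function(left_mask, right_mask, F1, F2, F3) {
  stopifnot(is(left_mask, "LungMask"), is(right_mask, "LungMask"))
  d <- dim(left_mask@data)
  lab <- array(0L, dim = d)
  lidx <- which(left_mask@data)
  if (length(lidx)) {
    if (is.null(F1)) {
      warning("left oblique surface missing: left lung left as one lobe")
      lab[lidx] <- 1L
    } else {
      f1 <- evalSurface(F1, .linearToIndex(lidx, d))
      lab[lidx] <- ifelse(f1 >= 0, 2L, 1L)
    }
  }
  ridx <- which(right_mask@data)
  if (length(ridx)) {
    if (is.null(F2) && is.null(F3)) {
      warning("right surfaces missing: right lung left as one lobe")
      lab[ridx] <- 3L
    } else {
      pts <- .linearToIndex(ridx, d)
      rl <- rep(5L, length(ridx))
      if (!is.null(F2)) rl[evalSurface(F2, pts) > 0] <- 4L
      else warning("right oblique surface missing: no middle/lower split")
      if (!is.null(F3)) rl[evalSurface(F3, pts) > 0] <- 3L
      else warning("right horizontal surface missing: no upper lobe")
      lab[ridx] <- rl
    }
  }
  LabelMap(lab, spacing = left_mask@spacing, origin = left_mask@origin)
}

.linearToIndex <- function(lin, d) {
  lin0 <- lin - 1L
  cbind(lin0 %% d[1], (lin0 %/% d[1]) %% d[2],
        lin0 %/% (d[1] * d[2])) + 1L
}

#' Per-lobe volumes and percentages
#'
#' Volume is voxel count times voxel volume
#' (\code{prod(spacing) / 1000} cm^3); percentages are relative to the
#' total labeled lung volume.
#'
#' @param labelmap a five-lobe [LabelMap-class].
#' @return data.frame with columns lobe, voxels, volume_cm3, percent.
#' @export
lobeVolumes <- function(labelmap) {
  stopifnot(is(labelmap, "LabelMap"))
  lobes <- labelmap@legend[labelmap@legend > 0]
  cnt <- vapply(lobes, function(l) sum(labelmap@data == l), numeric(1))
  if (any(cnt == 0))
    warning("empty lobe(s): ", paste(names(cnt)[cnt == 0], collapse = ", "))
  vox_cm3 <- prod(labelmap@spacing) / 1000
  vol <- cnt * vox_cm3
  data.frame(lobe = names(lobes), voxels = as.integer(cnt),
             volume_cm3 = vol,
             percent = if (sum(vol) > 0) 100 * vol / sum(vol) else 0 * vol,
             row.names = NULL)
}

#' Per-lobe emphysema index (LAA%)
#'
#' For each lobe, LAA% is the percentage of voxels below the emphysema
#' cut-off (-950 HU) among the lobe's lung voxels (below -600 HU):
#' \code{100 * #\{HU < laa_cut\} / #\{HU < lung_cut\}}. An empty
#' denominator yields NA.
#'
#' @param volume the HU [CTVolume-class].
#' @param labelmap aligned five-lobe [LabelMap-class].
#' @param laa_cut emphysema threshold, HU.
#' @param lung_cut lung-tissue threshold for the denominator, HU.
#' @return data.frame with columns lobe, laa_percent, n_lung_voxels.
#' @export
emphysemaIndex <- function(volume, labelmap, laa_cut = -950,
                           lung_cut = -600) {
  stopifnot(is(volume, "CTVolume"), is(labelmap, "LabelMap"),
            identical(dim(volume@data), dim(labelmap@data)))
  lobes <- labelmap@legend[labelmap@legend > 0]
  out <- lapply(names(lobes), function(nm) {
    sel <- labelmap@data == lobes[[nm]]
    hu <- volume@data[sel]
    den <- sum(hu < lung_cut)
    data.frame(lobe = nm,
               laa_percent = if (den > 0) 100 * sum(hu < laa_cut) / den
                             else NA_real_,
               n_lung_voxels = den)
  })
  do.call(rbind, out)
}
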