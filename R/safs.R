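#' Parameters for sagittal adaptive fissure scanning
#'
#' @param fissure "oblique" or "horizontal"; sets the default angle range
#'   (30-60 degrees for oblique fissures, -15 to 15 for the horizontal).
#' @param r minimum lung-intersection length of a scan line, in pixels.
#'   A line is considered only when \code{R > r}.
#' @param k minimum ratio \code{L / R} of the longest vessel-free run to
#'   the lung intersection.
#' @param air_cut HU threshold below which a pixel counts as "empty"
#'   (vessel-free) when measuring L.
#' @param angles scan angles in degrees, measured from the
#'   anterior-posterior (y) axis in the sagittal (y, z) plane.
#' @param weights weights (w1, w2, w3) applied to the region features
#'   (N, sdR, meanR); w2 is negative so lower spread scores higher.
#' @param standardize z-standardize the features across the per-slice
#'   candidate set before weighting (recommended; the raw mode applies
#'   the weights to the bare features).
#' @return A parameter list for [runSAFS] and friends.
#' @export
safsParams <- function(fissure = c("oblique", "horizontal"), r = 50,
                       k = 0.6, air_cut = -970, angles = NULL,
                       weights = c(1, -1, 1), standardize = TRUE) {
  fissure <- match.arg(fissure)
  if (is.null(angles))
    angles <- if (fissure == "oblique") seq(30, 60, by = 1)
              else seq(-15, 15, by = 1)
  stopifnot(r > 0, k > 0, k < 1, length(angles) >= 1,
            length(weights) == 3)
  list(fissure = fissure, r = r, k = k, air_cut = air_cut,
       angles = angles, weights = weights, standardize = standardize)
}

#' Select the two sagittal scanning slices of a lung
#'
#' Returns the slice indices at 40% and 60% of the lung's x extent,
#' \code{x1 = round(xmin + 0.4 (xmax - xmin))} and
#' \code{x2 = round(xmin + 0.6 (xmax - xmin))} (round half away from
#' zero).
#'
#' @param lung_mask one-sided [LungMask-class].
#' @return Integer vector \code{c(x1, x2)}.
#' @export
selectSagittalSlices <- function(lung_mask) {
  bb <- maskBoundingBox(lung_mask)
  xmin <- bb["min", 1]; xmax <- bb["max", 1]
  if (xmin == xmax) stop("degenerate bounding box: single sagittal slice")
  half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  c(half_away(xmin + 0.4 * (xmax - xmin)),
    half_away(xmin + 0.6 * (xmax - xmin)))
}

#' Trace parallel scan lines over a sagittal slice
#'
#' Rasterizes one Bresenham line per integer perpendicular offset at angle
#' \code{theta} (degrees from the y axis in the (y, z) plane) and, for
#' each line, measures R (pixels intersecting the lung mask), L (longest
#' contiguous run of mask pixels below \code{air_cut}) and the acceptance
#' flag \code{R > r & L/R > k}.
#'
#' @param slice_hu 2D HU matrix (rows = y, cols = z).
#' @param slice_mask 2D logical lung mask aligned with \code{slice_hu}.
#' @param theta scan angle in degrees.
#' @param params a [safsParams] list.
#' @return List of scan lines, each a list with elements \code{pixels}
#'   (ordered 2-column matrix), \code{offset}, \code{R}, \code{L},
#'   \code{run_pixels} (the pixels of the longest vessel-free run, the
#'   candidate fissure segment of the line) and \code{accepted}.
#' @export
traceScanLines <- function(slice_hu, slice_mask, theta, params) {
  stopifnot(identical(dim(slice_hu), dim(slice_mask)))
  if (!any(slice_mask)) return(list())
  d <- c(cos(theta * pi / 180), sin(theta * pi / 180))
  p <- c(-d[2], d[1])
  idx <- which(slice_mask, arr.ind = TRUE)
  off <- idx %*% p
  offsets <- seq(floor(min(off)), ceiling(max(off)))
  corners <- rbind(c(1, 1), c(nrow(slice_hu), 1), c(1, ncol(slice_hu)),
                   dim(slice_hu))
  trange <- range(corners %*% d)
  lines <- vector("list", length(offsets))
  for (i in seq_along(offsets)) {
    q <- offsets[i] * p
    pix <- .rasterLine(q + trange[1] * d, q + trange[2] * d)
    ok <- pix[, 1] >= 1 & pix[, 1] <= nrow(slice_hu) &
      pix[, 2] >= 1 & pix[, 2] <= ncol(slice_hu)
    pix <- pix[ok, , drop = FALSE]
    if (!nrow(pix)) {
      lines[[i]] <- list(pixels = pix, offset = offsets[i], R = 0L,
                         L = 0L, accepted = FALSE)
      next
    }
    lin <- pix[, 1] + nrow(slice_hu) * (pix[, 2] - 1)
    inmask <- slice_mask[lin]
    R <- sum(inmask)
    empty <- inmask & slice_hu[lin] < params$air_cut
    run <- .longestRunRange(empty)
    lines[[i]] <- list(pixels = pix, offset = offsets[i], R = R,
                       L = run$length,
                       run_pixels = if (run$length > 0)
                         pix[run$start:run$end, , drop = FALSE]
                       else pix[0, , drop = FALSE],
                       accepted = R > params$r &&
                         run$length / max(R, 1) > params$k)
  }
  lines
}

#' Largest connected region of accepted scan lines
#'
#' Forms the union of the vessel-free run segments of all accepted lines
#' at one angle (so the region contains no vessel pixel by construction)
#' and returns its largest 8-connected component as a
#' [FissureRegion-class], carrying N, sdR and meanR computed over the
#' in-region segment lengths of the accepted lines that intersect the
#' component. Ties on component size are broken by the component
#' containing the lexicographically smallest (row, col) pixel.
#'
#' @param lines output of [traceScanLines].
#' @param theta the scan angle the lines were traced at.
#' @param dim_slice dimensions of the slice.
#' @return A [FissureRegion-class], or NULL if no line was accepted.
#' @export
largestConnectedRegion <- function(lines, theta, dim_slice) {
  acc <- Filter(function(l) isTRUE(l$accepted), lines)
  if (!length(acc)) return(NULL)
  u <- matrix(FALSE, dim_slice[1], dim_slice[2])
  for (l in acc) u[l$run_pixels] <- TRUE
  lab <- .label2d8(u)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # lexicographic (row, col) tie-break
    keyOf <- function(b) {
      px <- which(lab == b, arr.ind = TRUE)
      px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
      px[1, ]
    }
    keys <- t(vapply(best, keyOf, numeric(2)))
    best <- best[order(keys[, 1], keys[, 2])[1]]
  }
  pixels <- which(lab == best, arr.ind = TRUE)
  colnames(pixels) <- NULL
  lens <- vapply(acc, function(l) {
    if (!nrow(l$run_pixels)) return(0)
    lin <- l$run_pixels[, 1] + dim_slice[1] * (l$run_pixels[, 2] - 1)
    sum(lab[lin] == best)
  }, numeric(1))
  lens <- lens[lens > 0]
  new("FissureRegion", theta = theta, pixels = pixels,
      nLines = length(lens),
      sdR = if (length(lens) > 1) stats::sd(lens) else 0,
      meanR = mean(lens), score = NA_real_)
}

#' Score candidate fissure regions
#'
#' Computes the likelihood score \eqn{P = w_1 N' + w_2 \sigma_R' + w_3
#' \bar R'} for every candidate region of a slice, where primes denote
#' features z-standardized across the candidate set (or the raw features
#' when \code{standardize = FALSE}). With the default weights P increases
#' with the number and mean length of the accepted lines and decreases
#' with the spread of their lengths.
#'
#' @param regions list of [FissureRegion-class] candidates (one slice).
#' @param params a [safsParams] list.
#' @return The regions with their \code{score} slot filled.
#' @export
scoreRegions <- function(regions, params) {
  regions <- Filter(Negate(is.null), regions)
  if (!length(regions)) return(list())
  feats <- t(vapply(regions, function(rg) {
    if (rg@nLines < 2)
      warning("region with fewer than 2 lines: sdR treated as 0")
    c(rg@nLines, rg@sdR, rg@meanR)
  }, numeric(3)))
  f <- if (params$standardize && nrow(feats) > 1) .standardize(feats)
       else feats
  P <- as.vector(f %*% params$weights)
  for (i in seq_along(regions)) regions[[i]]@score <- P[i]
  regions
}

#' Run sagittal adaptive fissure scanning on one slice
#'
#' For every angle in the parameter set, traces scan lines, keeps the
#' accepted ones, extracts the largest connected region and scores it;
#' the region with the maximum score is the fissure region (FR) of the
#' slice. Ties on the score keep the earliest angle in the list.
#'
#' @param slice_hu,slice_mask 2D HU matrix and lung mask (rows = y,
#'   cols = z).
#' @param params a [safsParams] list.
#' @return The winning [FissureRegion-class].
#' @export
runSAFS <- function(slice_hu, slice_mask, params = safsParams()) {
  cands <- lapply(params$angles, function(theta) {
    lines <- traceScanLines(slice_hu, slice_mask, theta, params)
    largestConnectedRegion(lines, theta, dim(slice_hu))
  })
  cands <- scoreRegions(cands, params)
  if (!length(cands))
    stop("SAFS failure: no scan line accepted at any angle; ",
         "verify the slice before continuing")
  scores <- vapply(cands, function(rg) rg@score, numeric(1))
  cands[[which.max(scores)]]
}
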