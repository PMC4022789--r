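#' Shortest-distance surface accuracy statistics
#'
#' For every reference point the shortest Euclidean distance to the
#' algorithm point set is computed (reference-to-algorithm direction; the
#' statistic is asymmetric by design) and summarized as mean, standard
#' deviation, RMS (\eqn{\sqrt{\sum d_i^2 / l}}) and maximum, all in mm.
#'
#' @param algo_points_mm algorithm surface samples, n x 3 matrix in mm.
#' @param ref_points_mm reference surface samples, l x 3 matrix in mm.
#' @return A [DistanceStats-class].
#' @export
surfaceDistanceStats <- function(algo_points_mm, ref_points_mm) {
  if (!is.matrix(algo_points_mm)) algo_points_mm <-
      matrix(algo_points_mm, ncol = 3)
  if (!is.matrix(ref_points_mm)) ref_points_mm <-
      matrix(ref_points_mm, ncol = 3)
  if (!nrow(algo_points_mm) || !nrow(ref_points_mm))
    stop("empty point set")
  d <- .minDistances(ref_points_mm, algo_points_mm)
  new("DistanceStats", distances = d, mean = mean(d),
      sd = stats::sd(d), rms = sqrt(mean(d^2)), max = max(d),
      n = nrow(ref_points_mm))
}
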