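#' Pipeline configuration
#'
#' Bundles every stage's parameters with their standard defaults: lung
#' HU band [-930, -650] with 7 x 7 axial closing and -300 HU vessel
#' removal; SAFS with r = 50, k = 0.6, vessel-free HU cut -970, oblique
#' angles 30-60 degrees and horizontal -15 to 15; Frangi scales
#' 0.7/1/1.4/2 mm with beta 0.5; coronal band half-width 10 px; PFP
#' subsampling on a 30 px grid with an 11^3 cube and count threshold 80;
#' off-surface distance d = 10 px; emphysema thresholds -950/-600 HU.
#' The configuration round-trips through YAML via [writeConfig] /
#' [readConfig].
#'
#' @param ... named overrides of the defaults (nested lists are replaced
#'   wholesale).
#' @return A config list for [runPipeline].
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    lung = list(lower_hu = -930, upper_hu = -650, closing_size = 7,
                vessel_cut = -300, min_volume_cm3 = 200),
    safs = list(r = 50, k = 0.6, air_cut = -970,
                oblique_angles = seq(30, 60, by = 1),
                horizontal_angles = seq(-15, 15, by = 1),
                weights = c(1, -1, 1), standardize = TRUE),
    frangi = list(scales_mm = c(0.7, 1, 1.4, 2), beta = 0.5),
    tracing = list(half_width = 10, stride = 1),
    surface = list(grid_spacing = 30, cube = 11, min_count = 80, d = 10,
                   reference_dirs = list(
                     left_oblique = c(0, 0.9, -1),
                     right_oblique = c(0, -0.9, 1),
                     right_horizontal = c(0, 0, 1))),
    emphysema = list(laa_cut = -950, lung_cut = -600),
    seed = 0, verbose = FALSE)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Pipeline configuration adapted to a phantom's HU model
#'
#' Two parameters are tied to the acquisition rather than the method and
#' are rescaled to the phantom: the SAFS vessel-free HU cut must lie
#' between the HU of the tissue the scan should treat as empty
#' (parenchyma and fissure sheet) and the HU of vessels, so it is placed
#' just above the fissure-sheet HU (for clinical data the default -970
#' HU plays this role); and the surface-point subsampling grid, about
#' 20 mm on a clinical 512-grid lung, is scaled to the phantom's smaller
#' lungs (12 voxels) so the fissure is still supported by a dozen or
#' more centers.
#'
#' @param spec the [phantomSpec] the volume was generated from.
#' @param ... further overrides, as in [pipelineConfig].
#' @return A config list.
#' @export
phantomConfig <- function(spec, ...) {
  pipelineConfig(safs = list(air_cut = spec$fissure_hu + 20),
                 surface = list(grid_spacing = 12), ...)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipelineConfig] list.
#' @param path YAML file path.
#' @return \code{writeConfig}: the path, invisibly; \code{readConfig}:
#'   the config list.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- pipelineConfig()
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    } else base[[nm]] <- cfg[[nm]]
  }
  # restore numeric vectors that YAML may have kept as lists
  rapply(base, unlist, classes = "list", how = "replace")
  for (grp in names(base))
    if (is.list(base[[grp]]) && grp != "surface")
      base[[grp]] <- lapply(base[[grp]], unlist)
  base$surface$reference_dirs <- lapply(base$surface$reference_dirs, unlist)
  base
}

#' Run the full fissure-detection and lobe-segmentation pipeline
#'
#' Executes the four stages in order: (1) lung segmentation (HU band
#' growing, axial closing, vessel removal, left/right split); (2)
#' fissure detection (SAFS on two sagittal slices per fissure, Hessian
#' line enhancement, uniform cost search); (3) fissure extension
#' (coronal band tracing, PFP subsampling, off-surface construction,
#' tri-harmonic RBF fit); (4) lobe segmentation and reporting. The
#' three fissures are processed independently; a failed right horizontal
#' fissure degrades the right lung to a two-lobe result instead of
#' aborting, while a failed oblique fissure aborts with a stage
#' diagnostic. The pipeline draws no random numbers: the same volume
#' and config always give identical output.
#'
#' @param volume a [CTVolume-class] in HU.
#' @param config a [pipelineConfig] list.
#' @return List with elements \code{lobes} ([LabelMap-class]),
#'   \code{surfaces} (named list of [ImplicitSurface-class]),
#'   \code{report} (lobe volumes), \code{laa} (emphysema indices),
#'   \code{masks} (lung masks) and \code{diagnostics}.
#' @export
runPipeline <- function(volume, config = pipelineConfig()) {
  stopifnot(is(volume, "CTVolume"))
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  diag <- list()

  say("stage 1: lung segmentation")
  both <- segmentLungs(volume, config$lung$lower_hu, config$lung$upper_hu,
                       config$lung$closing_size, config$lung$min_volume_cm3)
  clean <- removeDenseStructures(volume, both, config$lung$vessel_cut)
  sides <- splitLungs(both)
  cleanSide <- lapply(sides, function(m)
    LungMask(m@data & clean@data, spacing = m@spacing, origin = m@origin,
             side = m@side))
  diag$lung <- list(voxels_both = sum(both@data),
                    voxels_vessel_removed = sum(clean@data))

  fissureSides <- c(left_oblique = "left", right_oblique = "right",
                    right_horizontal = "right")
  surfaces <- list(left_oblique = NULL, right_oblique = NULL,
                   right_horizontal = NULL)
  for (f in names(fissureSides)) {
    side <- fissureSides[[f]]
    say("stages 2-3: ", f)
    kind <- if (f == "right_horizontal") "horizontal" else "oblique"
    sp <- safsParams(kind, r = config$safs$r, k = config$safs$k,
                     air_cut = config$safs$air_cut,
                     angles = if (kind == "oblique")
                       config$safs$oblique_angles
                     else config$safs$horizontal_angles,
                     weights = config$safs$weights,
                     standardize = config$safs$standardize)
    fitOne <- function() {
      pfp <- detectFissurePoints(volume, cleanSide[[side]], f,
                                 safs_params = sp,
                                 scales_mm = config$frangi$scales_mm,
                                 beta = config$frangi$beta,
                                 half_width = config$tracing$half_width,
                                 stride = config$tracing$stride)
      sub <- subsamplePFP(pfp, config$surface$grid_spacing,
                          config$surface$cube, config$surface$min_count)
      osp <- makeOffSurface(sub, pfp, config$surface$d,
                            config$surface$reference_dirs[[f]],
                            config$surface$cube)
      surf <- fitRBF(osp$on, osp$off, config$surface$d, fissure = f,
                     spacing = volume@spacing)
      list(surf = surf,
           diag = c(attr(pfp, "diagnostics"),
                    list(n_on = nrow(osp$on),
                         fit_residual = max(abs(evalSurface(surf,
                                                            osp$on))))))
    }
    if (f == "right_horizontal") {
      res <- tryCatch(fitOne(), error = function(e) e)
      if (inherits(res, "error")) {
        warning("right horizontal fissure failed (",
                conditionMessage(res),
                "); right lung degraded to a two-lobe result")
        diag[[f]] <- list(failed = conditionMessage(res))
        next
      }
    } else {
      res <- tryCatch(fitOne(), error = function(e)
        stop("pipeline failure at fissure detection [", f, ", ", side,
             " lung]: ", conditionMessage(e), call. = FALSE))
    }
    surfaces[[f]] <- res$surf
    diag[[f]] <- res$diag
  }

  say("stage 4: lobe segmentation")
  lobes <- classifyLobes(sides$left, sides$right,
                         surfaces$left_oblique, surfaces$right_oblique,
                         surfaces$right_horizontal)
  report <- lobeVolumes(lobes)
  laa <- emphysemaIndex(volume, lobes, config$emphysema$laa_cut,
                        config$emphysema$lung_cut)
  list(lobes = lobes, surfaces = surfaces, report = report, laa = laa,
       masks = list(both = both, vessel_removed = clean,
                    left = sides$left, right = sides$right),
       diagnostics = diag)
}
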