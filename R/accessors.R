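#' Accessors for volume-like objects
#'
#' \code{hounsfield} returns the raw HU array of a [CTVolume-class];
#' \code{voxelSpacing} and \code{voxelOrigin} return the lattice geometry;
#' \code{maskArray} returns the logical array of a [LungMask-class];
#' \code{labelArray} the integer array of a [LabelMap-class];
#' \code{maskSide} the side tag; \code{maskBoundingBox} the tight voxel
#' bounding box of a mask.
#'
#' @param x the object.
#' @return See details; geometry accessors return numeric(3).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("hounsfield", function(x) standardGeneric("hounsfield"))
#' @rdname accessors
#' @export
setMethod("hounsfield", "CTVolume", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "LabelMap", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "LungMask", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))
#' @rdname accessors
#' @export
setMethod("voxelOrigin", "CTVolume", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("voxelOrigin", "LabelMap", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("voxelOrigin", "LungMask", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setMethod("maskArray", "LungMask", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @rdname accessors
#' @export
setMethod("labelArray", "LabelMap", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("maskSide", function(x) standardGeneric("maskSide"))
#' @rdname accessors
#' @export
setMethod("maskSide", "LungMask", function(x) x@side)

#' @rdname accessors
#' @export
setGeneric("maskBoundingBox", function(x) standardGeneric("maskBoundingBox"))
#' @rdname accessors
#' @export
setMethod("maskBoundingBox", "LungMask", function(x) {
  if (!any(x@data)) stop("empty mask has no bounding box")
  idx <- which(x@data, arr.ind = TRUE)
  rbind(min = apply(idx, 2, min), max = apply(idx, 2, max))
})

#' @describeIn accessors dimensions of the HU array.
#' @export
setMethod("dim", "CTVolume", function(x) dim(x@data))
#' @rdname accessors
#' @export
setMethod("dim", "LabelMap", function(x) dim(x@data))
#' @rdname accessors
#' @export
setMethod("dim", "LungMask", function(x) dim(x@data))
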