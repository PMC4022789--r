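#' Read a 3D medical volume into canonical orientation
#'
#' Supports NIfTI-1 (.nii / .nii.gz) via the RNifti library and uncompressed
#' MetaImage (.mha / .mhd with axis-aligned direction matrix). On load the
#' volume is reoriented to the canonical frame: axis 1 right-to-left, axis 2
#' anterior-to-posterior, axis 3 inferior-to-superior ("LPS"), so that a
#' sagittal slice fixes the first index, a coronal slice the second and an
#' axial slice the third. Hounsfield units are assumed stored directly
#' (NIfTI scl slope/intercept are applied by RNifti).
#'
#' @param path file path.
#' @param format one of "auto", "nifti", "metaimage".
#' @return A [CTVolume-class] in canonical orientation.
#' @export
readVolume <- function(path, format = c("auto", "nifti", "metaimage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    if (dir.exists(path))
      stop("DICOM series directories are not supported; ",
           "convert to NIfTI or MetaImage first")
    format <- if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE))
      "metaimage" else "nifti"
  }
  if (format == "nifti") .readNiftiCanonical(path) else .readMetaImage(path)
}

.readNiftiCanonical <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ",
                                           conditionMessage(e)))
  xf <- RNifti::xform(img)
  if (!is.null(attr(xf, "code")) && attr(xf, "code") > 0) {
    RNifti::orientation(img) <- "LPS"
    xf <- RNifti::xform(img)
    spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
    origin <- c(-xf[1, 4], -xf[2, 4], xf[3, 4])
  } else {
    spacing <- abs(RNifti::pixdim(img))
    origin <- c(0, 0, 0)
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("header error: missing or invalid voxel spacing")
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 3L) stop("expected a 3D volume")
  CTVolume(data, spacing = spacing, origin = origin)
}

#' Write a CTVolume to NIfTI or MetaImage
#'
#' Integer-valued HU data are stored as 16-bit integers (lossless
#' round-trip); otherwise 32/64-bit float is used.
#'
#' @param volume a [CTVolume-class].
#' @param path destination; format chosen from the extension
#'   (.nii/.nii.gz vs .mha/.mhd).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "CTVolume"))
  if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE))
    return(.writeMetaImage(volume@data, volume@spacing, volume@origin, path))
  .writeNiftiCanonical(volume@data, volume@spacing, volume@origin, path)
}

.writeNiftiCanonical <- function(data, spacing, origin, path,
                                 integer = NULL) {
  if (is.null(integer))
    integer <- max(abs(data - round(data))) == 0
  if (integer) storage.mode(data) <- "integer"
  img <- RNifti::asNifti(data,
    datatype = if (integer) "int16" else "double")
  m <- diag(c(-spacing[1], -spacing[2], spacing[3], 1))
  m[1:3, 4] <- c(-origin[1], -origin[2], origin[3])
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a five-lobe label map
#'
#' Label maps are written as integer NIfTI with a JSON sidecar
#' (\code{<stem>.labels.json}) holding the label legend, and re-read
#' losslessly together with the legend.
#'
#' @param labelmap a [LabelMap-class].
#' @param path destination .nii or .nii.gz path.
#' @return \code{writeLabelMap}: the path, invisibly. \code{readLabelMap}:
#'   a [LabelMap-class].
#' @export
writeLabelMap <- function(labelmap, path) {
  stopifnot(is(labelmap, "LabelMap"))
  .writeNiftiCanonical(labelmap@data, labelmap@spacing, labelmap@origin,
                       path, integer = TRUE)
  jsonlite::write_json(as.list(labelmap@legend), .sidecarPath(path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeLabelMap
#' @export
readLabelMap <- function(path) {
  vol <- .readNiftiCanonical(path)
  sidecar <- .sidecarPath(path)
  legend <- if (file.exists(sidecar)) {
    lg <- jsonlite::read_json(sidecar)
    stats::setNames(as.integer(unlist(lg)), names(lg))
  } else lobeLegend
  LabelMap(vol@data, spacing = vol@spacing, origin = vol@origin,
           legend = legend)
}

.sidecarPath <- function(path)
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")

# --- MetaImage (.mha single-file / .mhd + .raw), uncompressed ------------

.metaTypes <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                MET_SHORT = "integer", MET_USHORT = "integer",
                MET_INT = "integer", MET_FLOAT = "double",
                MET_DOUBLE = "double")
.metaSizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L,
                MET_USHORT = 2L, MET_INT = 4L, MET_FLOAT = 4L,
                MET_DOUBLE = 8L)

.readMetaImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("format error: truncated MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("format error: malformed header line: ", line)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (identical(tolower(hdr[["CompressedData"]]), "true"))
    stop("format error: compressed MetaImage is not supported")
  if (is.null(hdr[["DimSize"]])) stop("format error: DimSize missing")
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  if (length(dims) != 3L) stop("expected a 3D volume")
  if (is.null(hdr[["ElementSpacing"]]))
    stop("header error: ElementSpacing missing")
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  origin <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  type <- hdr[["ElementType"]]
  if (is.null(type) || !type %in% names(.metaTypes))
    stop("format error: unsupported ElementType ", type)
  n <- prod(dims)
  if (identical(hdr[["ElementDataFile"]], "LOCAL")) {
    raw <- readBin(con, .metaTypes[[type]], n = n, size = .metaSizes[[type]],
                   signed = !type %in% c("MET_UCHAR", "MET_USHORT"),
                   endian = "little")
  } else {
    rawpath <- file.path(dirname(path), hdr[["ElementDataFile"]])
    if (!file.exists(rawpath)) stop("format error: missing data file ",
                                    rawpath)
    con2 <- file(rawpath, "rb")
    on.exit(close(con2), add = TRUE)
    raw <- readBin(con2, .metaTypes[[type]], n = n, size = .metaSizes[[type]],
                   signed = !type %in% c("MET_UCHAR", "MET_USHORT"),
                   endian = "little")
  }
  if (length(raw) != n) stop("format error: truncated MetaImage data")
  data <- array(as.numeric(raw), dim = dims)
  tm <- hdr[["TransformMatrix"]]
  if (!is.null(tm)) {
    m <- matrix(as.numeric(strsplit(tm, "\\s+")[[1]]), 3, 3)
    can <- .canonicalizeDirection(data, spacing, origin, m)
    data <- can$data; spacing <- can$spacing; origin <- can$origin
  }
  CTVolume(data, spacing = spacing, origin = origin)
}

# Reorder/flip a volume whose direction matrix is a signed permutation so
# that the direction becomes the identity; physical coordinates of every
# voxel are preserved.
.canonicalizeDirection <- function(data, spacing, origin, m) {
  if (max(abs(m - diag(3))) < 1e-6)
    return(list(data = data, spacing = spacing, origin = origin))
  perm <- apply(abs(m), 2, which.max)
  if (!setequal(perm, 1:3) || any(abs(abs(m[cbind(perm, 1:3)]) - 1) > 1e-6))
    stop("format error: only axis-aligned direction matrices are supported")
  sgn <- sign(m[cbind(perm, 1:3)])
  # world axis perm[j] is fed by data axis j with sign sgn[j]
  inv <- order(perm)                      # data axis feeding world axis i
  data <- aperm(data, inv)
  spacing2 <- spacing[inv]
  sgn2 <- sgn[inv]
  dims <- dim(data)
  origin2 <- numeric(3)
  idx <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  for (i in 1:3) {
    if (sgn2[i] < 0) {
      idx[[i]] <- rev(idx[[i]])
      origin2[i] <- origin[i] - (dims[i] - 1) * spacing2[i]
    } else origin2[i] <- origin[i]
  }
  list(data = data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
       spacing = spacing2, origin = origin2)
}

.writeMetaImage <- function(data, spacing, origin, path) {
  integer <- max(abs(data - round(data))) == 0 && max(abs(data)) < 32767
  type <- if (integer) "MET_SHORT" else "MET_DOUBLE"
  mha <- grepl("\\.mha$", path, ignore.case = TRUE)
  datafile <- if (mha) "LOCAL" else
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image", "NDims = 3", "BinaryData = True",
    "BinaryDataByteOrderMSB = False", "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(origin, trim = TRUE), collapse = " ")),
    paste("ElementSpacing =",
          paste(format(spacing, trim = TRUE), collapse = " ")),
    paste("DimSize =", paste(dim(data), collapse = " ")),
    paste("ElementType =", type),
    paste("ElementDataFile =", datafile))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("I/O error: cannot write ", path))
  writeLines(hdr, con)
  vals <- if (integer) as.integer(data) else as.numeric(data)
  if (mha) {
    writeBin(vals, con, size = if (integer) 2L else 8L, endian = "little")
    close(con)
  } else {
    close(con)
    con2 <- file(file.path(dirname(path), datafile), "wb")
    writeBin(vals, con2, size = if (integer) 2L else 8L, endian = "little")
    close(con2)
  }
  invisible(path)
}
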