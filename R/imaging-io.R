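## Reading and writing of CT volumes and label maps.
##
## Supported formats: NIfTI (.nii/.nii.gz, via RNifti), MetaImage
## (.mha single-file / .mhd + .raw), and uncompressed little-endian DICOM
## series (directories). Everything is normalized to the internal (x, y, z)
## convention with z the slice direction and values in Hounsfield units.

detectFormat <- function(path) {
  if (dir.exists(path)) return("dicom-series")
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.(mha|mhd)$", lp)) return("metaimage")
  stop("cannot infer image format from '", path, "'", call. = FALSE)
}

#' Read a CT volume
#'
#' Reads a CT volume from NIfTI, MetaImage, or an uncompressed little-endian
#' DICOM series directory, applying the DICOM rescale slope/intercept so the
#' returned values are Hounsfield units, and ordering slices by physical
#' position along z.
#'
#' @param path file (NIfTI/MetaImage) or directory (DICOM series).
#' @param format one of "auto", "nifti", "metaimage", "dicom-series".
#' @return a [CTVolume-class].
#' @export
readVolume <- function(path, format = c("auto", "nifti", "metaimage",
                                        "dicom-series")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input path does not exist: ", path, call. = FALSE)
  if (format == "auto") format <- detectFormat(path)
  switch(format,
    "nifti" = readNiftiVolume(path),
    "metaimage" = readMetaImageVolume(path),
    "dicom-series" = readDicomSeries(path))
}

#' Write a CT volume
#'
#' @param volume a [CTVolume-class].
#' @param path output file (.nii/.nii.gz or .mha/.mhd).
#' @param format "auto", "nifti" or "metaimage".
#' @return invisibly, `path`.
#' @export
writeVolume <- function(volume, path, format = c("auto", "nifti",
                                                 "metaimage")) {
  format <- match.arg(format)
  if (format == "auto") format <- detectFormat(path)
  switch(format,
    "nifti" = writeNiftiVolume(volume@values, volume@spacing, volume@origin,
                               path, integer = FALSE),
    "metaimage" = writeMetaImage(volume@values, volume@spacing,
                                 volume@origin, path, "MET_DOUBLE"))
  invisible(path)
}

#' Write a label map (with its channels) to disk
#'
#' The primary channel and any extra channels are stacked into a 4-D integer
#' volume; [readLabelMap()] splits them back out. The label map must be
#' congruent with the volume it annotates.
#'
#' @param labelmap a [LabelMap-class].
#' @param volume the paired [CTVolume-class] (shape check).
#' @param path output file (.nii/.nii.gz or .mha/.mhd).
#' @param format "auto", "nifti" or "metaimage".
#' @return invisibly, `path`.
#' @export
writeLabelMap <- function(labelmap, volume, path,
                          format = c("auto", "nifti", "metaimage")) {
  format <- match.arg(format)
  stopIfNotCongruent(labelmap, volume)
  if (format == "auto") format <- detectFormat(path)
  arrs <- c(list(labelmap@labels), labelmap@channels)
  stacked <- array(0L, c(dim(labelmap@labels), length(arrs)))
  for (i in seq_along(arrs)) stacked[, , , i] <- arrs[[i]]
  if (length(arrs) == 1L) stacked <- array(stacked, dim(labelmap@labels))
  switch(format,
    "nifti" = writeNiftiVolume(stacked, labelmap@spacing, labelmap@origin,
                               path, integer = TRUE),
    "metaimage" = writeMetaImage(stacked, labelmap@spacing, labelmap@origin,
                                 path, "MET_INT"))
  invisible(path)
}

#' Read a label map written by [writeLabelMap()]
#'
#' @param path label image on disk.
#' @param kind semantics of the primary channel.
#' @param channelNames optional names for extra channels (4th dimension).
#' @param format "auto", "nifti" or "metaimage".
#' @return a [LabelMap-class].
#' @export
readLabelMap <- function(path, kind = "mask", channelNames = NULL,
                         format = c("auto", "nifti", "metaimage")) {
  format <- match.arg(format)
  if (format == "auto") format <- detectFormat(path)
  vol <- switch(format,
    "nifti" = readNiftiVolume(path, allow4d = TRUE),
    "metaimage" = readMetaImageVolume(path, allow4d = TRUE))
  arr <- vol$values
  channels <- list()
  if (length(dim(arr)) == 4L) {
    nch <- dim(arr)[4]
    primary <- arr[, , , 1]
    if (nch > 1L) {
      channels <- lapply(seq_len(nch - 1L) + 1L, function(i) {
        a <- arr[, , , i]; storage.mode(a) <- "integer"; a
      })
      names(channels) <- channelNames %||%
        paste0("channel", seq_len(nch - 1L))
    }
    arr <- primary
  }
  storage.mode(arr) <- "integer"
  labelMap(arr, kind = kind, spacing = vol$spacing, origin = vol$origin,
           channels = channels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- NIfTI ----------------------------------------------------------------

readNiftiVolume <- function(path, allow4d = FALSE) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim(img))
  nd <- length(dim(arr))
  if (nd == 4L && dim(arr)[4] == 1L) { arr <- arr[, , , 1]; nd <- 3L }
  if (nd != 3L && !(allow4d && nd == 4L))
    stop("expected a 3-D volume in ", path, call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  ## RNifti xforms are RAS-oriented; our convention takes the stored voxel
  ## lattice as (x, y, z) directly, so only the translation is used.
  if (allow4d && nd == 4L)
    return(list(values = arr, spacing = spacing, origin = origin))
  if (allow4d) return(list(values = arr, spacing = spacing, origin = origin))
  ctVolume(arr, spacing = spacing, origin = origin)
}

writeNiftiVolume <- function(values, spacing, origin, path, integer = FALSE) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- spacing
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path,
                     datatype = if (integer) "int32" else "double")
  invisible(path)
}

## ---- MetaImage ------------------------------------------------------------

metaTypes <- list(
  MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
  MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
  MET_INT = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE))

writeMetaImage <- function(values, spacing, origin, path, elementType) {
  nd <- length(dim(values))
  local <- grepl("\\.mha$", tolower(path))
  rawName <- if (local) "LOCAL" else
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    paste0("NDims = ", nd),
    paste0("DimSize = ", paste(dim(values), collapse = " ")),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste0("ElementSpacing = ",
           paste(c(spacing, rep(1, nd - 3L)), collapse = " ")),
    paste0("Offset = ", paste(c(origin, rep(0, nd - 3L)), collapse = " ")),
    paste0("ElementType = ", elementType),
    paste0("ElementDataFile = ", rawName))
  tinfo <- metaTypes[[elementType]]
  vec <- as.vector(values)
  if (tinfo$what == "integer") vec <- as.integer(vec)
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (local) {
    writeBin(vec, con, size = tinfo$size, endian = "little")
    close(con)
  } else {
    close(con)
    rcon <- file(file.path(dirname(path), rawName), "wb")
    writeBin(vec, rcon, size = tinfo$size, endian = "little")
    close(rcon)
  }
  invisible(path)
}

readMetaImageVolume <- function(path, allow4d = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readMetaLine(con)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1",
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  tinfo <- metaTypes[[hdr$ElementType]]
  if (is.null(tinfo))
    stop("unsupported MetaImage ElementType: ", hdr$ElementType,
         call. = FALSE)
  n <- prod(dims)
  msb <- identical(hdr$BinaryDataByteOrderMSB, "True") ||
    identical(hdr$ElementByteOrderMSB, "True")
  endian <- if (msb) "big" else "little"
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vec <- readBin(con, tinfo$what, n = n, size = tinfo$size,
                   signed = tinfo$signed, endian = endian)
  } else {
    rawPath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawPath))
      stop("MetaImage data file missing: ", rawPath, call. = FALSE)
    rcon <- file(rawPath, "rb")
    on.exit(close(rcon), add = TRUE)
    vec <- readBin(rcon, tinfo$what, n = n, size = tinfo$size,
                   signed = tinfo$signed, endian = endian)
  }
  arr <- array(vec, dims)
  if (length(dims) == 4L && dims[4] == 1L) arr <- arr[, , , 1]
  if (allow4d)
    return(list(values = arr, spacing = spacing[1:3], origin = origin[1:3]))
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume in ", path, call. = FALSE)
  ctVolume(arr, spacing = spacing[1:3], origin = origin[1:3])
}

readMetaLine <- function(con) {
  chars <- character()
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L || ch == "\n") break
    chars <- c(chars, ch)
  }
  sub("\r$", "", paste(chars, collapse = ""))
}

## ---- resampling -----------------------------------------------------------

#' Resample a volume or label map to a new voxel spacing
#'
#' HU volumes are resampled trilinearly, label maps nearest-neighbour. The
#' field of view is preserved; the FE mesh requires near-isotropic spacing
#' (max/min ratio <= 1.5), so anisotropic acquisitions go through here first.
#'
#' @param x a [CTVolume-class] or [LabelMap-class].
#' @param newSpacing numeric(3) target spacing (mm).
#' @return an object of the same class on the new grid.
#' @export
resampleVolume <- function(x, newSpacing) {
  newSpacing <- rep_len(as.numeric(newSpacing), 3L)
  isLabel <- is(x, "LabelMap")
  arr <- voxelValues(x)
  d <- dim(arr); sp <- voxelSpacing(x)
  extent <- (d - 1) * sp
  nd <- pmax(2L, as.integer(round(extent / newSpacing)) + 1L)
  out <- array(0, nd)
  gx <- (seq_len(nd[1]) - 1) * newSpacing[1] / sp[1]
  gy <- (seq_len(nd[2]) - 1) * newSpacing[2] / sp[2]
  gz <- (seq_len(nd[3]) - 1) * newSpacing[3] / sp[3]
  gx <- pmin(gx, d[1] - 1); gy <- pmin(gy, d[2] - 1); gz <- pmin(gz, d[3] - 1)
  if (isLabel) {
    ix <- round(gx) + 1L; iy <- round(gy) + 1L; iz <- round(gz) + 1L
    out <- arr[ix, iy, iz]
    storage.mode(out) <- "integer"
    return(labelMap(out, kind = x@kind, spacing = newSpacing,
                    origin = x@origin,
                    channels = lapply(x@channels,
                                      function(ch) ch[ix, iy, iz]),
                    meta = x@meta))
  }
  ## trilinear: interpolate along x, then y, then z
  x0 <- pmin(floor(gx), d[1] - 2); fx <- gx - x0
  y0 <- pmin(floor(gy), d[2] - 2); fy <- gy - y0
  z0 <- pmin(floor(gz), d[3] - 2); fz <- gz - z0
  ax <- arr[x0 + 1L, , , drop = FALSE] * (1 - fx) +
        arr[x0 + 2L, , , drop = FALSE] * fx
  ay <- ax[, y0 + 1L, , drop = FALSE] * rep(1 - fy, each = nd[1]) +
        ax[, y0 + 2L, , drop = FALSE] * rep(fy, each = nd[1])
  az <- ay[, , z0 + 1L, drop = FALSE] *
          rep(1 - fz, each = nd[1] * nd[2]) +
        ay[, , z0 + 2L, drop = FALSE] * rep(fz, each = nd[1] * nd[2])
  ctVolume(array(az, nd), spacing = newSpacing, origin = voxelOrigin(x))
}
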