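## Minimal DICOM series support.
##
## Covers exactly what the pipeline needs: uncompressed little-endian
## explicit-VR (and implicit-VR) single-frame CT slices with integer pixel
## data, rescale slope/intercept applied on read, slices ordered by physical
## z position. The writer emits explicit-VR little endian and exists to
## produce synthetic series; it is not a general DICOM implementation.

dcmTag <- function(group, element) bitwShiftL(group, 16) + element

DCM_TAGS <- list(
  rows = dcmTag(0x0028, 0x0010),
  cols = dcmTag(0x0028, 0x0011),
  bitsAllocated = dcmTag(0x0028, 0x0100),
  pixelRepresentation = dcmTag(0x0028, 0x0103),
  pixelSpacing = dcmTag(0x0028, 0x0030),
  sliceThickness = dcmTag(0x0018, 0x0050),
  imagePosition = dcmTag(0x0020, 0x0032),
  imageOrientation = dcmTag(0x0020, 0x0037),
  sliceLocation = dcmTag(0x0020, 0x1041),
  rescaleIntercept = dcmTag(0x0028, 0x1052),
  rescaleSlope = dcmTag(0x0028, 0x1053),
  pixelData = dcmTag(0x7FE0, 0x0010))

readUint <- function(raw, size) {
  sum(as.numeric(raw[seq_len(size)]) * 256^(seq_len(size) - 1))
}

## parse one DICOM file; returns the fields the reader needs
parseDicomFile <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  pos <- 1L
  if (length(raw) >= 132 && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  explicit <- TRUE
  ## peek at the first element after the preamble to detect implicit VR
  vrPeek <- rawToChar(raw[pos + 4L:5L])
  if (!grepl("^[A-Z]{2}$", vrPeek)) explicit <- FALSE
  out <- list()
  n <- length(raw)
  longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n) {
    group <- readUint(raw[pos:(pos + 1L)], 2L)
    element <- readUint(raw[(pos + 2L):(pos + 3L)], 2L)
    tag <- dcmTag(group, element)
    pos <- pos + 4L
    isExplicitHere <- explicit || group == 0x0002
    if (isExplicitHere) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% longVRs) {
        len <- readUint(raw[(pos + 4L):(pos + 7L)], 4L)
        pos <- pos + 8L
      } else {
        len <- readUint(raw[(pos + 2L):(pos + 3L)], 2L)
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- readUint(raw[pos:(pos + 3L)], 4L)
      pos <- pos + 4L
    }
    if (len > n - pos + 1L)
      stop("corrupt DICOM element in ", path, call. = FALSE)
    body <- raw[pos + seq_len(len) - 1L]
    pos <- pos + len
    nm <- names(DCM_TAGS)[match(tag, unlist(DCM_TAGS))]
    if (is.na(nm)) next
    out[[nm]] <- body
    if (nm == "pixelData") break
  }
  need <- c("rows", "cols", "pixelData")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("DICOM file ", path, " missing required element(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  numify <- function(x) if (is.null(x)) NULL else
    as.numeric(strsplit(trimws(rawToChar(x)), "\\\\")[[1]])
  rows <- readUint(out$rows, 2L)
  cols <- readUint(out$cols, 2L)
  bits <- if (is.null(out$bitsAllocated)) 16 else readUint(out$bitsAllocated, 2L)
  signed <- !is.null(out$pixelRepresentation) &&
    readUint(out$pixelRepresentation, 2L) == 1
  if (bits != 16)
    stop("only 16-bit DICOM pixel data supported (", path, ")",
         call. = FALSE)
  px <- readBin(out$pixelData, "integer", n = rows * cols, size = 2L,
                signed = signed, endian = "little")
  list(rows = rows, cols = cols,
       pixels = matrix(px, nrow = cols, ncol = rows),  # x fastest
       pixelSpacing = numify(out$pixelSpacing) %||% c(1, 1),
       sliceThickness = (numify(out$sliceThickness) %||% 1)[1],
       imagePosition = numify(out$imagePosition),
       sliceLocation = numify(out$sliceLocation),
       rescaleIntercept = (numify(out$rescaleIntercept) %||% 0)[1],
       rescaleSlope = (numify(out$rescaleSlope) %||% 1)[1])
}

readDicomSeries <- function(path) {
  files <- sort(list.files(path, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (!length(files))
    stop("no files in DICOM directory ", path, call. = FALSE)
  slices <- lapply(files, parseDicomFile)
  dims <- vapply(slices, function(s) c(s$rows, s$cols), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("heterogeneous slice dimensions in series; first offender: ",
         files[which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]],
         call. = FALSE)
  sp <- vapply(slices, function(s) s$pixelSpacing[1:2], numeric(2))
  if (any(abs(sp - sp[, 1]) > 1e-9))
    stop("heterogeneous in-plane spacing in series; first offender: ",
         files[which(colSums(abs(sp - sp[, 1])) > 1e-9)[1]], call. = FALSE)
  zpos <- vapply(slices, function(s) {
    if (!is.null(s$imagePosition)) s$imagePosition[3]
    else if (!is.null(s$sliceLocation)) s$sliceLocation[1]
    else NA_real_
  }, numeric(1))
  if (any(is.na(zpos)))
    stop("slice position missing in series; first offender: ",
         files[which(is.na(zpos))[1]], call. = FALSE)
  ord <- order(zpos)
  slices <- slices[ord]; zpos <- zpos[ord]
  dz <- if (length(zpos) > 1L) diff(zpos) else slices[[1]]$sliceThickness
  if (length(zpos) > 1L && any(abs(dz - dz[1]) > 1e-6))
    warning("non-uniform slice gaps; using the mean gap")
  zSpacing <- if (length(zpos) > 1L) mean(dz) else
    slices[[1]]$sliceThickness
  nx <- slices[[1]]$cols; ny <- slices[[1]]$rows
  arr <- array(0, c(nx, ny, length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    arr[, , k] <- s$pixels * s$rescaleSlope + s$rescaleIntercept
  }
  origin <- if (!is.null(slices[[1]]$imagePosition))
    slices[[1]]$imagePosition[1:3] else c(0, 0, zpos[1])
  ctVolume(arr,
           spacing = c(slices[[1]]$pixelSpacing[2],
                       slices[[1]]$pixelSpacing[1], zSpacing),
           origin = origin)
}

## ---- writer (synthetic series) --------------------------------------------

uintRaw <- function(x, size) {
  out <- raw(size)
  for (i in seq_len(size)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

dcmElement <- function(group, element, vr, body) {
  if (length(body) %% 2L == 1L)
    body <- c(body, as.raw(if (vr %in% c("DS", "IS", "LO", "SH", "CS")) 0x20
                           else 0x00))
  head <- c(uintRaw(group, 2L), uintRaw(element, 2L), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(head, raw(2L), uintRaw(length(body), 4L), body)
  else c(head, uintRaw(length(body), 2L), body)
}

dcmText <- function(group, element, vr, text)
  dcmElement(group, element, vr, charToRaw(text))

#' Write a CT volume as a synthetic DICOM series
#'
#' Emits one uncompressed explicit-VR little-endian file per slice with the
#' geometry and rescale tags the reader consumes. Intended for generating
#' test and demonstration series, not for clinical interchange.
#'
#' @param volume a [CTVolume-class].
#' @param dir output directory (created if needed).
#' @param rescaleSlope,rescaleIntercept stored-value to HU mapping; stored
#'   values are `(HU - intercept)/slope`, rounded to integers.
#' @param shuffleNames if TRUE, file names are unrelated to slice order
#'   (exercises position-based sorting).
#' @return invisibly, the slice file paths in stored order.
#' @export
writeDicomSeries <- function(volume, dir, rescaleSlope = 1,
                             rescaleIntercept = -1024,
                             shuffleNames = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arr <- volume@values
  d <- dim(arr); sp <- volume@spacing; or <- volume@origin
  nz <- d[3]
  fileIdx <- if (shuffleNames) sample.int(nz) else seq_len(nz)
  paths <- character(nz)
  for (k in seq_len(nz)) {
    stored <- as.integer(round((arr[, , k] - rescaleIntercept) / rescaleSlope))
    if (any(stored < -32768 | stored > 32767))
      stop("stored values out of int16 range; adjust rescale", call. = FALSE)
    body <- c(
      dcmText(0x0008, 0x0060, "CS", "CT"),
      dcmText(0x0018, 0x0050, "DS", format(sp[3])),
      dcmText(0x0020, 0x0032, "DS",
              paste(format(c(or[1], or[2], or[3] + (k - 1) * sp[3])),
                    collapse = "\\")),
      dcmText(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      dcmText(0x0020, 0x1041, "DS", format(or[3] + (k - 1) * sp[3])),
      dcmElement(0x0028, 0x0010, "US", uintRaw(d[2], 2L)),  # Rows (y)
      dcmElement(0x0028, 0x0011, "US", uintRaw(d[1], 2L)),  # Columns (x)
      dcmText(0x0028, 0x0030, "DS",
              paste(format(c(sp[2], sp[1])), collapse = "\\")),
      dcmElement(0x0028, 0x0100, "US", uintRaw(16L, 2L)),
      dcmElement(0x0028, 0x0103, "US", uintRaw(1L, 2L)),
      dcmText(0x0028, 0x1052, "DS", format(rescaleIntercept)),
      dcmText(0x0028, 0x1053, "DS", format(rescaleSlope)),
      dcmElement(0x7FE0, 0x0010, "OW",
                 writeBin(stored, raw(), size = 2L, endian = "little")))
    meta <- c(
      dcmElement(0x0002, 0x0010, "UI",
                 charToRaw("1.2.840.10008.1.2.1")))  # explicit VR LE
    file <- file.path(dir, sprintf("slice_%04d.dcm", fileIdx[k]))
    con <- file(file, "wb")
    writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
    close(con)
    paths[k] <- file
  }
  invisible(paths)
}
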