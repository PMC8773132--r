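#' Construct a CT volume
#'
#' @param values 3-D numeric array of Hounsfield units.
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) physical position of voxel (0,0,0) in mm.
#' @return a [CTVolume-class].
#' @examples
#' vol <- ctVolume(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
#' voxelSpacing(vol)
#' @export
ctVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(values) <- "double"
  obj <- new("CTVolume", values = values, spacing = as.numeric(spacing),
             origin = as.numeric(origin))
  rng <- range(values)
  if (rng[1] < -2000 || rng[2] > 10000)
    warning(sprintf(
      "HU values outside the sanity window [-2000, 10000] (range %.0f..%.0f)",
      rng[1], rng[2]))
  obj
}

#' Construct a label map
#'
#' @param labels 3-D integer array.
#' @param kind semantics of the primary channel ("mask", "compartment",
#'   "segment" or "group").
#' @param spacing,origin voxel geometry (mm).
#' @param channels named list of congruent integer arrays.
#' @param meta list of per-label metadata.
#' @return a [LabelMap-class].
#' @export
labelMap <- function(labels, kind = "mask", spacing = c(1, 1, 1),
                     origin = c(0, 0, 0), channels = list(), meta = list()) {
  storage.mode(labels) <- "integer"
  channels <- lapply(channels, function(ch) { storage.mode(ch) <- "integer"; ch })
  new("LabelMap", labels = labels, kind = kind, channels = channels,
      spacing = as.numeric(spacing), origin = as.numeric(origin), meta = meta)
}

## run code under a fixed RNG state without disturbing the caller's stream
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

## congruence check between a label map and a volume
stopIfNotCongruent <- function(labelmap, volume) {
  if (!identical(dim(labelmap@labels), dim(voxelValues(volume))))
    stop("label map shape ", paste(dim(labelmap@labels), collapse = "x"),
         " does not match volume shape ",
         paste(dim(voxelValues(volume)), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

## physical coordinates (mm) of the voxel centres indexed by `idx`
## (integer matrix of 1-based array indices)
voxelCenters <- function(idx, spacing, origin) {
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}
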