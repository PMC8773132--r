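#' Voxel geometry accessors
#'
#' `voxelSpacing` and `voxelOrigin` return the per-axis voxel size and the
#' physical position of voxel (0,0,0), both in mm; `voxelDim` returns the
#' grid dimensions.
#'
#' @param x a [CTVolume-class], [LabelMap-class] or [DensityVolume-class].
#' @return numeric(3) (or integer(3) for `voxelDim`).
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' @rdname voxelSpacing
#' @export
setGeneric("voxelDim", function(x) standardGeneric("voxelDim"))

#' Extract the raw array of a gridded object
#' @param x a [CTVolume-class], [LabelMap-class] or [DensityVolume-class].
#' @return the underlying 3-D array (HU, integer labels, or g/cm^3).
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

for (cls in c("CTVolume", "DensityVolume")) {
  setMethod("voxelSpacing", cls, function(x) x@spacing)
  setMethod("voxelOrigin", cls, function(x) x@origin)
  setMethod("voxelDim", cls, function(x) dim(x@values))
  setMethod("voxelValues", cls, function(x) x@values)
}
setMethod("voxelSpacing", "LabelMap", function(x) x@spacing)
setMethod("voxelOrigin", "LabelMap", function(x) x@origin)
setMethod("voxelDim", "LabelMap", function(x) dim(x@labels))
setMethod("voxelValues", "LabelMap", function(x) x@labels)

#' @describeIn voxelSpacing show method helpers
#' @param object object to display.
#' @export
setMethod("show", "CTVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("CTVolume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 4), collapse = " x ")))
  cat(sprintf("  HU range [%.1f, %.1f]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@labels)
  tab <- table(object@labels[object@labels > 0L])
  cat(sprintf("LabelMap (%s): %d x %d x %d voxels, %d nonzero labels\n",
              object@kind, d[1], d[2], d[3], length(tab)))
  if (length(object@channels))
    cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
})

setMethod("show", "DensityVolume", function(object) {
  v <- object@values[object@values > 0]
  cat(sprintf("DensityVolume: %s voxels in mask, rho in [%.4f, %.4f] g/cm^3\n",
              length(v), if (length(v)) min(v) else NA,
              if (length(v)) max(v) else NA))
  cat(sprintf("  calibration: rho = %g * HU + %g\n",
              object@calibration@slope, object@calibration@intercept))
})

setMethod("show", "MaterialCardSet", function(object) {
  cat(sprintf("MaterialCardSet: %d %s cards (%d cortical, %d trabecular)\n",
              length(object@cards), object@law,
              sum(object@groups$compartment == 1L),
              sum(object@groups$compartment == 2L)))
})

setMethod("show", "VoxelMesh", function(object) {
  cat(sprintf("VoxelMesh: %d hexahedral elements, %d nodes, spacing %s mm\n",
              nrow(object@elements), nrow(object@nodes),
              paste(format(object@spacing, digits = 4), collapse = " x ")))
})

setMethod("show", "FEResult", function(object) {
  cat(sprintf("FEResult: %d steps, %d elements; global max von Mises %.4g MPa (element %d, step %d)\n",
              length(object@maxVonMises), nrow(object@vonMises),
              object@globalMax$value, object@globalMax$element,
              object@globalMax$step))
})

setMethod("show", "DamageField", function(object) {
  ns <- ncol(object@utilization)
  cat(sprintf("DamageField: %d elements, %d steps; final failed fraction %.4f\n",
              nrow(object@utilization), ns, object@failedFraction[ns]))
})

setMethod("show", "BivariateFit", function(object) {
  cat(sprintf("BivariateFit: %s = %.7g %+.7g * %s  (R^2 = %.4f, n = %d)\n",
              object@yName, object@intercept, object@slope, object@xName,
              object@rSquared, object@n))
})
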