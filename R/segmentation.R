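## Compartment, longitudinal-segment and material-group labelling.
##
## Thresholding stands in for interactive segmentation: bone above a global
## HU threshold, cortical above a second threshold within the bone mask.
## The bone axis is the principal axis of the masked voxel cloud, so tilted
## specimens segment correctly.

#' Segmentation configuration
#'
#' @param boneHuThreshold HU above which a voxel counts as bone (default 200).
#' @param corticalHuThreshold HU separating cortical from trabecular bone
#'   within the mask (default 700; must exceed `boneHuThreshold`).
#' @param nSegments number of longitudinal segments S (default 8).
#' @param nGroupsPerSegment density bins K per (segment x compartment)
#'   stratum (default 10).
#' @param binning "equal-width" (default) or "quantile".
#' @return a validated list of class "SegmentationConfig".
#' @export
segmentationConfig <- function(boneHuThreshold = 200,
                               corticalHuThreshold = 700,
                               nSegments = 8L, nGroupsPerSegment = 10L,
                               binning = c("equal-width", "quantile")) {
  binning <- match.arg(binning)
  if (corticalHuThreshold <= boneHuThreshold)
    stop("corticalHuThreshold must exceed boneHuThreshold", call. = FALSE)
  if (nSegments < 1L || nGroupsPerSegment < 1L)
    stop("nSegments and nGroupsPerSegment must be >= 1", call. = FALSE)
  structure(list(boneHuThreshold = boneHuThreshold,
                 corticalHuThreshold = corticalHuThreshold,
                 nSegments = as.integer(nSegments),
                 nGroupsPerSegment = as.integer(nGroupsPerSegment),
                 binning = binning),
            class = "SegmentationConfig")
}

## 6-connected component labelling by iterative label propagation
connectedComponents6 <- function(mask) {
  d <- dim(mask)
  lab <- array(NA_real_, d)
  lab[mask] <- which(mask)
  shift <- function(a, axis, by) {
    idx <- lapply(d, seq_len)
    src <- lapply(d, seq_len)
    if (by == 1L) { idx[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1L) }
    else { idx[[axis]] <- 1:(d[axis] - 1L); src[[axis]] <- 2:d[axis] }
    out <- array(NA_real_, d)
    out[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  repeat {
    new <- lab
    for (axis in 1:3) for (by in c(1L, -1L)) {
      sh <- shift(lab, axis, by)
      new <- pmin(new, sh, na.rm = TRUE)
    }
    new[!mask] <- NA_real_
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

#' Binary bone mask
#'
#' Thresholds the volume at `boneHuThreshold` and keeps only the largest
#' 6-connected component, discarding detached specks.
#'
#' @param volume a [CTVolume-class].
#' @param config a [segmentationConfig()].
#' @return a binary [LabelMap-class] (kind "mask").
#' @export
boneMask <- function(volume, config = segmentationConfig()) {
  mask <- volume@values >= config$boneHuThreshold
  if (!any(mask))
    stop("no bone found at threshold ", config$boneHuThreshold, " HU",
         call. = FALSE)
  comp <- connectedComponents6(mask)
  tab <- table(comp[mask])
  keep <- as.numeric(names(tab)[which.max(tab)])
  out <- array(0L, dim(mask))
  out[!is.na(comp) & comp == keep] <- 1L
  labelMap(out, kind = "mask", spacing = volume@spacing,
           origin = volume@origin)
}

#' Split the bone mask into cortical and trabecular compartments
#'
#' Within the mask, HU at or above `corticalHuThreshold` is cortical (label
#' 1), the rest trabecular (label 2).
#'
#' @param volume a [CTVolume-class].
#' @param mask binary [LabelMap-class] from [boneMask()].
#' @param config a [segmentationConfig()].
#' @return a [LabelMap-class] of kind "compartment".
#' @export
splitCompartments <- function(volume, mask, config = segmentationConfig()) {
  stopIfNotCongruent(mask, volume)
  m <- mask@labels > 0L
  if (!any(m)) stop("empty bone mask", call. = FALSE)
  out <- array(0L, dim(m))
  out[m] <- ifelse(volume@values[m] >= config$corticalHuThreshold, 1L, 2L)
  if (!any(out == 2L))
    warning("no trabecular voxels at cutoff ",
            config$corticalHuThreshold, " HU")
  if (!any(out == 1L))
    warning("no cortical voxels at cutoff ",
            config$corticalHuThreshold, " HU")
  labelMap(out, kind = "compartment", spacing = volume@spacing,
           origin = volume@origin)
}

## principal axis (largest-variance direction) of the masked voxel centres
principalAxis <- function(mask) {
  idx <- which(mask@labels > 0L, arr.ind = TRUE)
  xyz <- voxelCenters(idx, mask@spacing, mask@origin)
  ctr <- colMeans(xyz)
  cv <- crossprod(sweep(xyz, 2, ctr)) / nrow(xyz)
  ev <- eigen(cv, symmetric = TRUE)
  axis <- ev$vectors[, 1]
  if (axis[which.max(abs(axis))] < 0) axis <- -axis
  list(axis = axis, center = ctr, coords = xyz, idx = idx)
}

#' Partition the mask into longitudinal segments
#'
#' The bone axis is the principal axis of the masked voxel cloud; masked
#' voxels are partitioned into `nSegments` bins of equal extent along it.
#'
#' @param mask binary [LabelMap-class].
#' @param config a [segmentationConfig()].
#' @return a [LabelMap-class] of kind "segment" with labels 1..S.
#' @export
longitudinalSegments <- function(mask, config = segmentationConfig()) {
  if (!any(mask@labels > 0L)) stop("empty bone mask", call. = FALSE)
  pa <- principalAxis(mask)
  t <- as.vector(sweep(pa$coords, 2, pa$center) %*% pa$axis)
  S <- config$nSegments
  nPositions <- length(unique(round(t / min(mask@spacing) * 2)))
  if (S > nPositions)
    stop("requested ", S, " segments but only ", nPositions,
         " occupied axial positions", call. = FALSE)
  rng <- range(t)
  seg <- if (diff(rng) == 0) rep(1L, length(t)) else
    pmin(pmax(floor((t - rng[1]) / diff(rng) * S) + 1L, 1L), S)
  out <- array(0L, dim(mask@labels))
  out[mask@labels > 0L] <- as.integer(seg)
  labelMap(out, kind = "segment", spacing = mask@spacing,
           origin = mask@origin)
}

## bin a numeric vector into K groups
binDensities <- function(x, K, binning) {
  if (length(unique(x)) == 1L) return(rep(1L, length(x)))
  if (binning == "quantile") {
    n <- length(x)
    as.integer(ceiling(rank(x, ties.method = "first") * K / n))
  } else {
    rng <- range(x)
    pmin(pmax(as.integer(floor((x - rng[1]) / diff(rng) * K)) + 1L, 1L), K)
  }
}

#' Assign density-based material groups
#'
#' Within each (segment x compartment) stratum, voxel densities are binned
#' into `nGroupsPerSegment` groups (equal-width over the stratum's density
#' range by default, quantile optional). Group ids are globally unique; the
#' returned map's `meta$groups` table lists, per group, the segment,
#' compartment, bin, representative (mean) density and voxel count.
#'
#' @param density a [DensityVolume-class].
#' @param compartments compartment [LabelMap-class] (1 cortical,
#'   2 trabecular).
#' @param segments segment [LabelMap-class].
#' @param config a [segmentationConfig()].
#' @return a [LabelMap-class] of kind "group".
#' @export
materialGroups <- function(density, compartments, segments,
                           config = segmentationConfig()) {
  if (!identical(dim(density@values), dim(compartments@labels)) ||
      !identical(dim(density@values), dim(segments@labels)))
    stop("density, compartments and segments must be congruent",
         call. = FALSE)
  K <- config$nGroupsPerSegment
  if (K < 1L) stop("nGroupsPerSegment must be >= 1", call. = FALSE)
  inMask <- compartments@labels > 0L
  seg <- segments@labels[inMask]
  comp <- compartments@labels[inMask]
  rho <- density@values[inMask]
  group <- integer(length(rho))
  rows <- list()
  gid <- 0L
  for (s in sort(unique(seg))) for (cp in sort(unique(comp))) {
    sel <- seg == s & comp == cp
    if (!any(sel)) next
    bins <- binDensities(rho[sel], K, config$binning)
    for (b in sort(unique(bins))) {
      gid <- gid + 1L
      inBin <- sel
      inBin[sel] <- bins == b
      group[inBin] <- gid
      rows[[gid]] <- data.frame(group = gid, segment = s, compartment = cp,
                                bin = b, meanDensity = mean(rho[inBin]),
                                nVoxels = sum(inBin))
    }
  }
  out <- array(0L, dim(density@values))
  out[inMask] <- group
  labelMap(out, kind = "group", spacing = density@spacing,
           origin = density@origin,
           channels = list(segment = segments@labels,
                           compartment = compartments@labels),
           meta = list(groups = do.call(rbind, rows)))
}
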