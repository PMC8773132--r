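#' @import methods
NULL

#' CT volume in Hounsfield units
#'
#' A 3-D scalar field of CT attenuation values in Hounsfield units (HU),
#' together with its voxel geometry. The array axes are fixed to (x, y, z)
#' with z the slice (longitudinal) direction; the physical position of the
#' centre of voxel (0,0,0) is `origin`, and voxel centres sit at
#' `origin + index * spacing` (0-based indices).
#'
#' @slot values 3-D numeric array of HU.
#' @slot spacing numeric(3), per-axis voxel size in mm (all > 0).
#' @slot origin numeric(3), physical position of voxel (0,0,0) in mm.
#' @export
setClass("CTVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 finite positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be 3 finite values (mm)")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "'values' must be finite")
  if (length(msg)) msg else TRUE
})

#' Per-voxel integer label map
#'
#' Integer labels congruent with a [CTVolume]. The primary `labels` array
#' holds one channel (semantics given by `kind`: "mask", "compartment",
#' "segment" or "group"); additional congruent channels (e.g. a segment
#' index alongside a compartment map) can ride along in `channels`.
#' Compartment convention: 0 = background, 1 = cortical, 2 = trabecular.
#'
#' @slot labels 3-D integer array.
#' @slot kind character, semantics of the primary channel.
#' @slot channels named list of congruent 3-D integer arrays.
#' @slot spacing,origin voxel geometry, as in [CTVolume].
#' @slot meta list of per-label metadata (e.g. the material-group table).
#' @export
setClass("LabelMap",
  representation(labels = "array", kind = "character", channels = "list",
                 spacing = "numeric", origin = "numeric", meta = "list"),
  prototype(kind = "mask", channels = list(), spacing = c(1, 1, 1),
            origin = c(0, 0, 0), meta = list()))

setValidity("LabelMap", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "'labels' must be a 3-D array")
  if (!is.integer(object@labels))
    msg <- c(msg, "'labels' must be integer")
  if (any(object@labels < 0L, na.rm = TRUE))
    msg <- c(msg, "labels must be non-negative")
  for (nm in names(object@channels)) {
    ch <- object@channels[[nm]]
    if (!identical(dim(ch), dim(object@labels)))
      msg <- c(msg, sprintf("channel '%s' not congruent with labels", nm))
  }
  if (length(msg)) msg else TRUE
})

#' HU-to-density calibration
#'
#' Linear map from Hounsfield units to apparent density,
#' rho = slope * HU + intercept (g/cm^3).
#'
#' @slot slope g/cm^3 per HU (> 0).
#' @slot intercept g/cm^3.
#' @export
setClass("Calibration",
  representation(slope = "numeric", intercept = "numeric"),
  prototype(slope = 0.0000464, intercept = 1.0))

setValidity("Calibration", function(object) {
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope <= 0)
    return("'slope' must be a single positive number")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    return("'intercept' must be a single finite number")
  TRUE
})

#' Per-voxel apparent density
#'
#' Apparent density rho (g/cm^3) on the voxel grid, zero outside the bone
#' mask, with the calibration used recorded as provenance.
#'
#' @slot values 3-D numeric array of rho (g/cm^3).
#' @slot calibration the [Calibration] applied.
#' @slot spacing,origin voxel geometry.
#' @export
setClass("DensityVolume",
  representation(values = "array", calibration = "Calibration",
                 spacing = "numeric", origin = "numeric"))

setValidity("DensityVolume", function(object) {
  if (length(dim(object@values)) != 3L) return("'values' must be 3-D")
  if (any(!is.finite(object@values))) return("density values must be finite")
  TRUE
})

## ---- material cards -------------------------------------------------------

#' Virtual parent of all material cards
#'
#' Every card carries the representative density it was evaluated at, the
#' compartment it belongs to, and the number of voxels in its group.
#' @slot rho representative apparent density (g/cm^3).
#' @slot compartment "cortical" or "trabecular".
#' @slot nVoxels voxel count of the group (0 for free-standing cards).
#' @export
setClass("MaterialCard", representation("VIRTUAL",
  rho = "numeric", compartment = "character", nVoxels = "integer"),
  prototype(rho = NA_real_, compartment = NA_character_, nVoxels = 0L))

#' Isotropic linear-elastic card
#' @slot E Young's modulus (MPa).
#' @slot nu Poisson's ratio.
#' @export
setClass("IsotropicElasticCard", contains = "MaterialCard",
  representation(E = "numeric", nu = "numeric"), prototype(nu = 0.25))

setValidity("IsotropicElasticCard", function(object) {
  if (!is.finite(object@E) || object@E <= 0) return("E must be > 0")
  if (object@nu <= -1 || object@nu >= 0.5) return("nu must be in (-1, 0.5)")
  TRUE
})

#' Elastic-perfectly-plastic card
#'
#' Elastic branch as [IsotropicElasticCard-class]; yield at the ultimate
#' strength, failure flagged beyond the fracture strain. Hardness is carried
#' as metadata only.
#' @slot E,nu elastic branch.
#' @slot sigmaUltTension,sigmaUltCompression ultimate strengths (MPa).
#' @slot fractureStrain failure strain (fraction, in (0,1)).
#' @slot hardness Vickers hardness, metadata.
#' @export
setClass("PlasticCard", contains = "IsotropicElasticCard",
  representation(sigmaUltTension = "numeric", sigmaUltCompression = "numeric",
                 fractureStrain = "numeric", hardness = "numeric"))

setValidity("PlasticCard", function(object) {
  if (object@sigmaUltTension <= 0 || object@sigmaUltCompression <= 0)
    return("ultimate strengths must be > 0")
  if (object@fractureStrain <= 0 || object@fractureStrain >= 1)
    return("fractureStrain must be in (0, 1)")
  TRUE
})

#' Three-parameter Mooney-Rivlin card
#'
#' Incompressible three-parameter Mooney-Rivlin hyper-elastic card; the
#' volumetric parameter d is stored but unused at the material point.
#' @slot C10,C01,C11 material constants (MPa).
#' @slot d incompressibility parameter (1/MPa).
#' @slot positiveSlope logical, initial stiffness 6*(C10+C01) > 0.
#' @export
setClass("MooneyRivlinCard", contains = "MaterialCard",
  representation(C10 = "numeric", C01 = "numeric", C11 = "numeric",
                 d = "numeric", positiveSlope = "logical"),
  prototype(positiveSlope = TRUE))

#' Transversely isotropic (orthotropic form) card
#'
#' Elastic constants of a transversely isotropic material written in
#' orthotropic form, axis 3 = bone longitudinal axis, E1 = E2.
#' @slot E1,E2,E3 Young's moduli (MPa).
#' @slot G12,G23,G31 shear moduli (MPa).
#' @slot nu12,nu23,nu31 Poisson ratios.
#' @export
setClass("OrthotropicCard", contains = "MaterialCard",
  representation(E1 = "numeric", E2 = "numeric", E3 = "numeric",
                 G12 = "numeric", G23 = "numeric", G31 = "numeric",
                 nu12 = "numeric", nu23 = "numeric", nu31 = "numeric"))

setValidity("OrthotropicCard", function(object) {
  E <- c(object@E1, object@E2, object@E3)
  G <- c(object@G12, object@G23, object@G31)
  if (any(!is.finite(c(E, G))) || any(c(E, G) <= 0))
    return("all moduli must be finite and > 0")
  if (abs(object@E1 - object@E2) > 1e-9 * object@E1)
    return("transverse isotropy requires E1 == E2")
  TRUE
})

#' A set of material cards keyed by group id
#' @slot cards named list of [MaterialCard-class] objects (names = group ids).
#' @slot law one of "elastic", "plastic", "hyperelastic", "anisotropic".
#' @slot groups data.frame with one row per group (segment, compartment, bin,
#'   meanDensity, nVoxels).
#' @export
setClass("MaterialCardSet",
  representation(cards = "list", law = "character", groups = "data.frame"))

## ---- FE objects -----------------------------------------------------------

#' Conforming voxel hexahedral mesh
#'
#' One 8-node hexahedron per masked voxel; nodes shared across faces.
#' @slot nodes m x 3 matrix of node coordinates (mm).
#' @slot elements n x 8 integer matrix of node indices (trilinear hex order).
#' @slot elemGroup integer(n), material-group id per element.
#' @slot elemCompartment integer(n), 1 = cortical, 2 = trabecular.
#' @slot spacing voxel size (mm).
#' @export
setClass("VoxelMesh",
  representation(nodes = "matrix", elements = "matrix",
                 elemGroup = "integer", elemCompartment = "integer",
                 spacing = "numeric"))

setValidity("VoxelMesh", function(object) {
  if (ncol(object@elements) != 8L) return("elements must have 8 nodes")
  if (max(object@elements) > nrow(object@nodes) || min(object@elements) < 1L)
    return("element node index out of range")
  TRUE
})

#' Boundary conditions and load pattern for one analysis
#' @slot fixedDofs integer vector of constrained global DOFs.
#' @slot fixedValues numeric, prescribed values for `fixedDofs` (mm).
#' @slot loadVector numeric(ndof), unit spatial load pattern (N).
#' @slot forceScale numeric, per-time-step scale factors of the pattern.
#' @slot times numeric, time stamps of the steps (s).
#' @export
setClass("LoadCase",
  representation(fixedDofs = "integer", fixedValues = "numeric",
                 loadVector = "numeric", forceScale = "numeric",
                 times = "numeric"))

setValidity("LoadCase", function(object) {
  if (length(object@fixedDofs) == 0L) return("no fixed DOFs: system singular")
  if (length(object@fixedValues) != length(object@fixedDofs))
    return("fixedValues must match fixedDofs")
  if (any(object@times < 0)) return("times must be non-negative")
  TRUE
})

#' Finite-element result
#' @slot displacements m*3-row matrix, one column per time step (mm).
#' @slot stress list (per step) of n x 6 Voigt stress matrices (MPa),
#'   order (11, 22, 33, 23, 31, 12).
#' @slot strain list (per step) of n x 6 Voigt strain matrices (engineering).
#' @slot vonMises n x steps matrix (MPa).
#' @slot maxVonMises numeric per step (MPa).
#' @slot globalMax list(value, element, step).
#' @slot residuals relative residual norm per step.
#' @slot mesh the [VoxelMesh-class] analysed.
#' @export
setClass("FEResult",
  representation(displacements = "matrix", stress = "list", strain = "list",
                 vonMises = "matrix", maxVonMises = "numeric",
                 globalMax = "list", residuals = "numeric", mesh = "VoxelMesh"))

#' Element damage (utilization) field
#'
#' Utilization u = sigma_vM / sigma_ult clamped to [0, 1]; the binary damage
#' indicator is u == 1 ("failed"), latched across load steps.
#' @slot utilization n x steps matrix in [0, 1].
#' @slot failed n x steps logical matrix (latched).
#' @slot failedFraction fraction of failed elements per step.
#' @export
setClass("DamageField",
  representation(utilization = "matrix", failed = "matrix",
                 failedFraction = "numeric"))

setValidity("DamageField", function(object) {
  u <- object@utilization
  if (any(u < 0 | u > 1)) return("utilization must lie in [0, 1]")
  if (!identical(dim(u), dim(object@failed)))
    return("failed must be congruent with utilization")
  TRUE
})

#' Simple bivariate OLS fit
#' @slot slope,intercept coefficients (units of y per x, and y).
#' @slot rSquared coefficient of determination.
#' @slot se named numeric: standard errors of slope and intercept.
#' @slot n number of observations.
#' @slot xName,yName variable names.
#' @export
setClass("BivariateFit",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", se = "numeric", n = "integer",
                 xName = "character", yName = "character"))

setValidity("BivariateFit", function(object) {
  if (object@n < 3L) return("n must be >= 3")
  if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
    return("rSquared must lie in [0, 1]")
  TRUE
})
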