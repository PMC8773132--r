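## HU -> apparent density -> constitutive parameters.
##
## The calibration is the linear map rho = 0.0000464*HU + 1 (g/cm^3).
## Density-modulus power laws (moduli in MPa, rho in g/cm^3):
##   cortical:   E1 = E2 = 2314 rho^1.57,  E3 = 2065 rho^3.09
##   trabecular: E1 = E2 = 1157 rho^1.78,  E3 = 1904 rho^1.64
## Shear moduli scale quadratically with density, G = G_max (rho/rho_max)^2,
## with printed maxima G12/G23/G31 = 5.71/7.11/6.58. Taken literally in MPa
## these give G several orders below E, which is physically implausible for
## bone; a GPa reading is available via `shearScaling(units = "GPa")`.

CORTICAL_LAW <- list(a1 = 2314, b1 = 1.57, a3 = 2065, b3 = 3.09)
TRABECULAR_LAW <- list(a1 = 1157, b1 = 1.78, a3 = 1904, b3 = 1.64)
DEFAULT_NU <- c(nu12 = 0.4, nu23 = 0.25, nu31 = 0.25)
ULT_STRENGTH <- c(cortical = 100, trabecular = 10)    # MPa
FRACTURE_STRAIN <- c(cortical = 0.03, trabecular = 0.07)

#' HU-to-density calibration object
#'
#' @param slope g/cm^3 per HU (default 0.0000464).
#' @param intercept g/cm^3 (default 1).
#' @return a [Calibration-class].
#' @export
calibration <- function(slope = 0.0000464, intercept = 1.0)
  new("Calibration", slope = slope, intercept = intercept)

#' Convert HU to apparent density within the bone mask
#'
#' Applies rho = slope*HU + intercept voxelwise inside the mask; background
#' is left at zero. Errors if the calibration produces a non-positive
#' density at any masked voxel.
#'
#' @param volume a [CTVolume-class].
#' @param mask binary [LabelMap-class].
#' @param cal a [calibration()].
#' @return a [DensityVolume-class].
#' @examples
#' vol <- ctVolume(array(1000, c(2, 2, 2)))
#' msk <- labelMap(array(1L, c(2, 2, 2)))
#' voxelValues(huToDensity(vol, msk))[1]  # 1.0464 g/cm^3
#' @export
huToDensity <- function(volume, mask, cal = calibration()) {
  stopIfNotCongruent(mask, volume)
  m <- mask@labels > 0L
  if (!any(m)) stop("empty bone mask", call. = FALSE)
  rho <- array(0, dim(volume@values))
  rho[m] <- cal@slope * volume@values[m] + cal@intercept
  if (any(rho[m] <= 0))
    stop("calibration yields non-positive density at ", sum(rho[m] <= 0),
         " masked voxel(s); calibration inconsistent with data",
         call. = FALSE)
  new("DensityVolume", values = rho, calibration = cal,
      spacing = volume@spacing, origin = volume@origin)
}

#' Density scaling of the shear moduli
#'
#' G_ij(rho) = G_ij_max * (rho/rho_max)^2. The printed maxima are 5.71,
#' 7.11 and 6.58; `units = "MPa"` (default) takes them at face value, with
#' a warning that the resulting shear moduli are far below the Young's
#' moduli; `units = "GPa"` multiplies by 1000.
#'
#' @param G12max,G23max,G31max shear maxima, in `units`.
#' @param rhoMax reference density at which G reaches its maximum (g/cm^3);
#'   typically the maximum masked density of the model at hand.
#' @param units "MPa" (as printed) or "GPa".
#' @return a list of class "ShearScaling" with maxima converted to MPa.
#' @export
shearScaling <- function(G12max = 5.71, G23max = 7.11, G31max = 6.58,
                         rhoMax = 1.2, units = c("MPa", "GPa")) {
  units <- match.arg(units)
  if (rhoMax <= 0) stop("rhoMax must be > 0", call. = FALSE)
  if (any(c(G12max, G23max, G31max) <= 0))
    stop("shear maxima must be > 0", call. = FALSE)
  mult <- if (units == "GPa") 1000 else 1
  if (units == "MPa")
    warning("shear maxima interpreted in MPa as printed; the resulting ",
            "G << E is physically implausible for bone. Consider ",
            "shearScaling(units = \"GPa\").", call. = FALSE)
  structure(list(G12max = G12max * mult, G23max = G23max * mult,
                 G31max = G31max * mult, rhoMax = rhoMax, units = units),
            class = "ShearScaling")
}

orthoFromLaw <- function(rho, law, scaling, compartment) {
  if (length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("rho must be a single positive density (g/cm^3)", call. = FALSE)
  if (rho > scaling$rhoMax)
    warning("rho = ", signif(rho, 6), " exceeds rhoMax = ",
            signif(scaling$rhoMax, 6), "; shear moduli extrapolated")
  r2 <- (rho / scaling$rhoMax)^2
  new("OrthotropicCard",
      E1 = law$a1 * rho^law$b1, E2 = law$a1 * rho^law$b1,
      E3 = law$a3 * rho^law$b3,
      G12 = scaling$G12max * r2, G23 = scaling$G23max * r2,
      G31 = scaling$G31max * r2,
      nu12 = DEFAULT_NU[["nu12"]], nu23 = DEFAULT_NU[["nu23"]],
      nu31 = DEFAULT_NU[["nu31"]],
      rho = rho, compartment = compartment, nVoxels = 0L)
}

#' Transversely isotropic constants from density
#'
#' `corticalConstants` applies the cortical power laws
#' (E1 = E2 = 2314 rho^1.57, E3 = 2065 rho^3.09); `trabecularConstants`
#' the trabecular ones (E1 = E2 = 1157 rho^1.78, E3 = 1904 rho^1.64), both
#' with nu12 = 0.4, nu23 = nu31 = 0.25 and density-squared shear scaling.
#'
#' @param rho apparent density (g/cm^3, > 0).
#' @param scaling a [shearScaling()].
#' @return an [OrthotropicCard-class].
#' @export
corticalConstants <- function(rho, scaling = shearScaling())
  orthoFromLaw(rho, CORTICAL_LAW, scaling, "cortical")

#' @rdname corticalConstants
#' @export
trabecularConstants <- function(rho, scaling = shearScaling())
  orthoFromLaw(rho, TRABECULAR_LAW, scaling, "trabecular")

compartmentModulus <- function(rho, compartment) {
  law <- switch(compartment, cortical = CORTICAL_LAW,
                trabecular = TRABECULAR_LAW,
                stop("unknown compartment: ", compartment, call. = FALSE))
  law$a1 * rho^law$b1
}

#' Isotropic elastic card from density
#'
#' E from the compartment power law (2314 rho^1.57 cortical,
#' 1157 rho^1.78 trabecular), nu = 0.25.
#'
#' @param rho apparent density (g/cm^3, > 0).
#' @param compartment "cortical" or "trabecular".
#' @return an [IsotropicElasticCard-class].
#' @export
isotropicCard <- function(rho, compartment = c("cortical", "trabecular")) {
  compartment <- match.arg(compartment)
  if (length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("rho must be a single positive density", call. = FALSE)
  new("IsotropicElasticCard", E = compartmentModulus(rho, compartment),
      nu = 0.25, rho = rho, compartment = compartment, nVoxels = 0L)
}

#' Elastic-perfectly-plastic card from density
#'
#' Elastic branch as [isotropicCard()]; ultimate strengths 100 MPa
#' (cortical) / 10 MPa (trabecular) in both tension and compression,
#' fracture strain 3% / 7%, Vickers hardness 100 recorded as metadata.
#'
#' @param rho apparent density (g/cm^3, > 0).
#' @param compartment "cortical" or "trabecular".
#' @param fractureStrain optional override of the compartment default.
#' @return a [PlasticCard-class].
#' @export
plasticCard <- function(rho, compartment = c("cortical", "trabecular"),
                        fractureStrain = NULL) {
  compartment <- match.arg(compartment)
  base <- isotropicCard(rho, compartment)
  new("PlasticCard", E = base@E, nu = base@nu,
      sigmaUltTension = ULT_STRENGTH[[compartment]],
      sigmaUltCompression = ULT_STRENGTH[[compartment]],
      fractureStrain = fractureStrain %||% FRACTURE_STRAIN[[compartment]],
      hardness = 100,
      rho = rho, compartment = compartment, nVoxels = 0L)
}

## incompressible uniaxial Mooney-Rivlin regressors: P(lambda) is linear in
## (C10, C01, C11) with these three basis functions
mrBasis <- function(lambda) {
  I1 <- lambda^2 + 2 / lambda
  I2 <- 2 * lambda + 1 / lambda^2
  common <- 2 * (lambda - lambda^-2)
  cbind(c10 = common,
        c01 = common / lambda,
        c11 = common * ((I2 - 3) + (I1 - 3) / lambda))
}

#' Fit a three-parameter Mooney-Rivlin card to uniaxial test data
#'
#' Least-squares fit of (C10, C01, C11) in the incompressible uniaxial
#' nominal-stress model
#' P(lambda) = 2(lambda - lambda^-2) * (C10 + C01/lambda +
#'   C11((I2-3) + (I1-3)/lambda)),
#' which is linear in the constants, so the fit is the closed-form
#' least-squares solution. The volumetric parameter is set for
#' near-incompressibility, d = 2/K with K = 1000 * 6(C10+C01).
#'
#' @param testData data.frame with columns `stretch` (lambda) and
#'   `nominal_stress_MPa`.
#' @param rho,compartment optional provenance recorded on the card.
#' @return a [MooneyRivlinCard-class].
#' @export
fitMooneyRivlin <- function(testData, rho = NA_real_,
                            compartment = NA_character_) {
  if (!all(c("stretch", "nominal_stress_MPa") %in% names(testData)))
    stop("testData needs columns 'stretch' and 'nominal_stress_MPa'",
         call. = FALSE)
  lam <- testData$stretch
  P <- testData$nominal_stress_MPa
  if (sum(abs(lam - 1) > 1e-12) < 3L)
    stop("need at least 3 distinct data points with stretch != 1",
         call. = FALSE)
  X <- mrBasis(lam)
  qrX <- qr(X)
  if (qrX$rank < 3L)
    stop("Mooney-Rivlin fit underdetermined (design rank ", qrX$rank, ")",
         call. = FALSE)
  beta <- qr.coef(qrX, P)
  slope0 <- 6 * (beta[["c10"]] + beta[["c01"]])
  if (slope0 <= 0)
    warning("fitted Mooney-Rivlin card has non-positive initial stiffness")
  K <- 1000 * abs(slope0)
  new("MooneyRivlinCard", C10 = beta[["c10"]], C01 = beta[["c01"]],
      C11 = beta[["c11"]], d = 2 / K, positiveSlope = slope0 > 0,
      rho = rho, compartment = compartment, nVoxels = 0L)
}

#' Read uniaxial stress-strain test data
#'
#' @param path CSV with header columns `stretch`, `nominal_stress_MPa`.
#' @return a data.frame.
#' @export
readUniaxialData <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("stretch", "nominal_stress_MPa") %in% names(df)))
    stop("uniaxial CSV must have columns stretch, nominal_stress_MPa",
         call. = FALSE)
  df
}

scaleMooneyRivlin <- function(card, factor) {
  new("MooneyRivlinCard", C10 = card@C10 * factor, C01 = card@C01 * factor,
      C11 = card@C11 * factor, d = card@d / factor,
      positiveSlope = card@positiveSlope,
      rho = card@rho, compartment = card@compartment, nVoxels = card@nVoxels)
}

#' Build one material card per density group
#'
#' Evaluates the chosen constitutive law at each group's representative
#' (mean) density. Anisotropic groups get [OrthotropicCard-class]s from the
#' compartment power laws; elastic/plastic groups get compartment cards;
#' hyper-elastic groups share the card fitted to the compartment's test data,
#' with constants scaled by (rho_group/rho_fit)^b, b the compartment's
#' density-modulus exponent (1.57 cortical, 1.78 trabecular), which keeps
#' initial stiffness consistent with the elastic power laws.
#'
#' @param density a [DensityVolume-class].
#' @param groups group [LabelMap-class] from [materialGroups()].
#' @param law "elastic", "plastic", "hyperelastic" or "anisotropic".
#' @param scaling a [shearScaling()] (anisotropic law only). Defaults to the
#'   printed maxima with rhoMax = the model's maximum masked density.
#' @param testData for "hyperelastic": a list with elements `cortical` and
#'   `trabecular`, each a data.frame(stretch, nominal_stress_MPa), plus
#'   optional `rhoFit` named numeric giving the test densities (defaults
#'   to the compartment mean densities of the model).
#' @return a [MaterialCardSet-class].
#' @export
buildMaterialCards <- function(density, groups,
                               law = c("elastic", "plastic", "hyperelastic",
                                       "anisotropic"),
                               scaling = NULL, testData = NULL) {
  law <- match.arg(law)
  tab <- groups@meta$groups
  if (is.null(tab))
    stop("groups label map carries no group table; use materialGroups()",
         call. = FALSE)
  compName <- c("cortical", "trabecular")
  if (law == "anisotropic" && is.null(scaling)) {
    rhoMax <- max(density@values)
    scaling <- shearScaling(rhoMax = rhoMax)
  }
  fitted <- NULL
  if (law == "hyperelastic") {
    if (is.null(testData))
      stop("hyperelastic law requires uniaxial testData per compartment",
         call. = FALSE)
    rhoFit <- testData$rhoFit %||% c(
      cortical = mean(tab$meanDensity[tab$compartment == 1L]),
      trabecular = mean(tab$meanDensity[tab$compartment == 2L]))
    fitted <- list()
    for (cp in intersect(compName, names(testData)))
      fitted[[cp]] <- fitMooneyRivlin(testData[[cp]], rho = rhoFit[[cp]],
                                      compartment = cp)
  }
  cards <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cp <- compName[tab$compartment[i]]
    rho <- tab$meanDensity[i]
    card <- switch(law,
      elastic = isotropicCard(rho, cp),
      plastic = plasticCard(rho, cp),
      anisotropic = if (cp == "cortical") corticalConstants(rho, scaling)
                    else trabecularConstants(rho, scaling),
      hyperelastic = {
        base <- fitted[[cp]]
        if (is.null(base))
          stop("missing test data for compartment ", cp, call. = FALSE)
        expo <- if (cp == "cortical") CORTICAL_LAW$b1 else TRABECULAR_LAW$b1
        scaleMooneyRivlin(base, (rho / base@rho)^expo)
      })
    card@rho <- rho
    card@compartment <- cp
    card@nVoxels <- as.integer(tab$nVoxels[i])
    cards[[i]] <- card
  }
  names(cards) <- as.character(tab$group)
  new("MaterialCardSet", cards = cards, law = law, groups = tab)
}

#' Export a card set as a JSON document
#'
#' One record per group: law, parameters, representative density and voxel
#' count.
#'
#' @param cardset a [MaterialCardSet-class].
#' @param path output JSON file.
#' @return invisibly, `path`.
#' @export
exportCards <- function(cardset, path) {
  recs <- lapply(cardset@cards, function(card) {
    slots <- setdiff(slotNames(class(card)),
                     c("rho", "compartment", "nVoxels"))
    params <- lapply(slots, function(s) slot(card, s))
    names(params) <- slots
    list(law = cardset@law, compartment = card@compartment,
         representative_density = card@rho, n_voxels = card@nVoxels,
         parameters = params)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
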