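## Material-point mechanics: stiffness assembly, von Mises stress, and the
## uniaxial response of each of the four laws.
##
## Voigt convention throughout: components (11, 22, 33, 23, 31, 12) with
## engineering shear strains; axis 3 is the bone longitudinal axis.

#' Assemble a 6x6 Voigt stiffness matrix from a material card
#'
#' For an [OrthotropicCard-class], the compliance is built as
#' S11 = 1/E1, S12 = -nu12/E1, S23 = -nu23/E2, S31 = -nu31/E3 (symmetrized
#' via nu_ij/E_i = nu_ji/E_j), shear diagonal 1/G23, 1/G31, 1/G12, and the
#' stiffness is its inverse. For an [IsotropicElasticCard-class] the Lame
#' form is used. Positive definiteness is verified by an eigenvalue check.
#'
#' @param card an [OrthotropicCard-class] or [IsotropicElasticCard-class].
#' @return 6x6 symmetric positive-definite matrix (MPa).
#' @export
assembleStiffness <- function(card) {
  if (is(card, "OrthotropicCard")) {
    S <- matrix(0, 6, 6)
    S[1, 1] <- 1 / card@E1
    S[2, 2] <- 1 / card@E2
    S[3, 3] <- 1 / card@E3
    S[1, 2] <- S[2, 1] <- -card@nu12 / card@E1
    S[2, 3] <- S[3, 2] <- -card@nu23 / card@E2
    S[3, 1] <- S[1, 3] <- -card@nu31 / card@E3
    S[4, 4] <- 1 / card@G23
    S[5, 5] <- 1 / card@G31
    S[6, 6] <- 1 / card@G12
    C <- tryCatch(solve(S), error = function(e)
      stop("compliance not invertible for card with E = (",
           paste(signif(c(card@E1, card@E2, card@E3), 5), collapse = ", "),
           ") MPa", call. = FALSE))
    C <- (C + t(C)) / 2
  } else if (is(card, "IsotropicElasticCard")) {
    E <- card@E; nu <- card@nu
    lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
    mu <- E / (2 * (1 + nu))
    C <- matrix(0, 6, 6)
    C[1:3, 1:3] <- lam
    diag(C)[1:3] <- lam + 2 * mu
    diag(C)[4:6] <- mu
  } else stop("unsupported card class: ", class(card), call. = FALSE)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("assembled stiffness not positive definite (min eigenvalue ",
         signif(min(ev), 4), "); check the nu/G combination of the card",
         call. = FALSE)
  C
}

#' Von Mises equivalent stress
#'
#' sigma_vM = sqrt(0.5[(s11-s22)^2 + (s22-s33)^2 + (s33-s11)^2] +
#'                 3(s23^2 + s31^2 + s12^2)).
#'
#' @param stress numeric(6) Voigt vector (11, 22, 33, 23, 31, 12) in MPa,
#'   or an n x 6 matrix of such rows.
#' @return scalar or numeric(n), MPa.
#' @examples
#' vonMisesStress(c(5, 0, 0, 0, 0, 0))  # uniaxial: 5
#' vonMisesStress(c(3, 3, 3, 0, 0, 0))  # hydrostatic: 0
#' @export
vonMisesStress <- function(stress) {
  if (is.null(dim(stress))) stress <- matrix(stress, nrow = 1)
  s <- stress
  sqrt(pmax(0,
    0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 + (s[, 3] - s[, 1])^2) +
    3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2)))
}

#' Uniaxial linear-elastic response
#'
#' @param card an [IsotropicElasticCard-class].
#' @param strain axial strain (|strain| < 0.2).
#' @return stress in MPa.
#' @export
elasticUniaxial <- function(card, strain) {
  if (any(abs(strain) >= 0.2))
    stop("small-strain model: |strain| must be < 0.2", call. = FALSE)
  card@E * strain
}

#' 1-D elastic-perfectly-plastic strain path
#'
#' Rate-independent return mapping with yield at the ultimate compressive
#' strength and no hardening; unloading is elastic with slope E. The failure
#' flag latches once |total strain| exceeds the fracture strain.
#'
#' @param card a [PlasticCard-class].
#' @param strainPath numeric sequence of total strains visited in order.
#' @return data.frame(strain, stress_MPa, plastic_strain, failed).
#' @export
plasticUniaxialPath <- function(card, strainPath) {
  E <- card@E
  sy <- card@sigmaUltCompression
  epsP <- 0
  failed <- FALSE
  out <- data.frame(strain = strainPath, stress_MPa = NA_real_,
                    plastic_strain = NA_real_, failed = NA)
  for (i in seq_along(strainPath)) {
    eps <- strainPath[i]
    trial <- E * (eps - epsP)
    if (abs(trial) > sy) {
      sig <- sy * sign(trial)
      epsP <- eps - sig / E
    } else sig <- trial
    failed <- failed || abs(eps) > card@fractureStrain
    out$stress_MPa[i] <- sig
    out$plastic_strain[i] <- epsP
    out$failed[i] <- failed
  }
  out
}

#' Incompressible uniaxial Mooney-Rivlin response
#'
#' Nominal (first Piola-Kirchhoff) stress
#' P(lambda) = 2(lambda - lambda^-2) * (C10 + C01/lambda +
#'   C11((I2-3) + (I1-3)/lambda)),
#' I1 = lambda^2 + 2/lambda, I2 = 2 lambda + 1/lambda^2.
#'
#' @param card a [MooneyRivlinCard-class].
#' @param lambda stretch ratio (> 0); vectorized.
#' @return nominal stress in MPa.
#' @export
mooneyRivlinUniaxial <- function(card, lambda) {
  if (any(lambda <= 0)) stop("stretch must be > 0", call. = FALSE)
  drop(mrBasis(lambda) %*% c(card@C10, card@C01, card@C11))
}

## small-strain tangent modulus of a Mooney-Rivlin card at lambda = 1
mooneyRivlinTangent <- function(card)
  6 * (card@C10 + card@C01) + 0 * card@C11  # C11 term vanishes at lambda = 1

#' Uniaxial stress-strain curve for any of the four laws
#'
#' Samples the law's uniaxial response on a monotone strain grid. The
#' hyper-elastic law uses lambda = 1 + strain; the anisotropic law loads
#' along the bone axis (axis 3), slope E3; the plastic law traverses the
#' grid as a strain path.
#'
#' @param law "elastic", "plastic", "hyperelastic" or "anisotropic".
#' @param card the matching material card.
#' @param strainGrid monotone numeric vector of strains.
#' @return data.frame(strain, stress_MPa).
#' @export
stressStrainCurve <- function(law = c("elastic", "plastic", "hyperelastic",
                                      "anisotropic"),
                              card, strainGrid) {
  law <- match.arg(law)
  if (is.unsorted(strainGrid) && is.unsorted(rev(strainGrid)))
    stop("strainGrid must be monotone", call. = FALSE)
  stress <- switch(law,
    elastic = elasticUniaxial(card, strainGrid),
    plastic = plasticUniaxialPath(card, strainGrid)$stress_MPa,
    hyperelastic = mooneyRivlinUniaxial(card, 1 + strainGrid),
    anisotropic = card@E3 * strainGrid)
  data.frame(strain = strainGrid, stress_MPa = stress)
}
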