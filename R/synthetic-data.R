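## Synthetic inputs: femur-like tube phantoms, demographic cohorts with the
## published bivariate structure, parametric gait load curves, and uniaxial
## test data. Everything is deterministic for a fixed seed, so the whole
## pipeline runs without external data.

## printed generating relations (density in g/cm^3)
COHORT_RELATIONS <- list(
  age = c(intercept = 1.5404122, slope = -0.010025),
  bmi = c(intercept = 0.6791666, slope = 0.0060304),
  weight = c(intercept = 0.5729131, slope = 0.0015183),
  height = c(intercept = -0.040764, slope = 0.1609694),
  stress = c(intercept = 4.352e-11, slope = 0.0097057))

GENDER_DENSITY <- list(
  female = c(mean = 0.6653613, sd = 0.187628),
  male = c(mean = 0.9693199, sd = 0.1268695))

AGE_RANGE <- list(female = c(23, 95), male = c(26, 92))

## race mean densities chosen so the Black-vs-other contrasts reproduce the
## published ordering Black > Mixed > Caucasian > Asian (47.91 / 53.27 /
## 57.41 % higher than Mixed / Caucasian / Asian)
RACE_DENSITY <- c(Black = 1.0, Mixed = 1 / 1.4791,
                  Caucasian = 1 / 1.5327, Asian = 1 / 1.5741)

#' Phantom specification
#'
#' A straight (optionally tilted) tube: cortical shell around a trabecular
#' core in a uniform background, with Gaussian HU noise per region. The
#' default cortical thickness is 45% of the outer radius, a typical adult
#' mid-diaphysis proportion.
#'
#' @param size "test" (16 x 16 x 48 voxels) or "demo" (40 x 40 x 120).
#' @param voxelMM isotropic voxel size in mm (default 0.5).
#' @param outerRadiusMM,corticalThicknessMM,lengthMM tube geometry (mm).
#' @param corticalHU,trabecularHU,backgroundHU region HU means.
#' @param corticalSD,trabecularSD,backgroundSD region HU noise SDs.
#' @param tiltDeg tilt of the tube axis away from z, about y (degrees).
#' @param volDim integer(3) grid size; derived from the preset by default.
#' @param seed noise seed.
#' @return a list of class "PhantomSpec".
#' @export
phantomSpec <- function(size = c("test", "demo"), voxelMM = 0.5,
                        outerRadiusMM = NULL, corticalThicknessMM = NULL,
                        lengthMM = NULL, corticalHU = 1500,
                        trabecularHU = 300, backgroundHU = -1000,
                        corticalSD = 0, trabecularSD = 0, backgroundSD = 0,
                        tiltDeg = 0, volDim = NULL, seed = 1L) {
  size <- match.arg(size)
  if (is.null(volDim))
    volDim <- if (size == "test") c(16L, 16L, 48L) else c(40L, 40L, 120L)
  if (is.null(outerRadiusMM))
    outerRadiusMM <- 0.4 * min(volDim[1:2]) * voxelMM
  if (is.null(corticalThicknessMM))
    corticalThicknessMM <- 0.45 * outerRadiusMM
  if (is.null(lengthMM)) lengthMM <- volDim[3] * voxelMM
  if (corticalThicknessMM >= outerRadiusMM)
    stop("cortical thickness must be smaller than the outer radius",
         call. = FALSE)
  if (voxelMM <= 0) stop("voxel size must be > 0", call. = FALSE)
  if (2 * outerRadiusMM > min(volDim[1:2]) * voxelMM + 1e-9)
    stop("tube does not fit in the volume cross-section", call. = FALSE)
  structure(list(voxelMM = voxelMM, outerRadiusMM = outerRadiusMM,
                 corticalThicknessMM = corticalThicknessMM,
                 lengthMM = lengthMM, corticalHU = corticalHU,
                 trabecularHU = trabecularHU, backgroundHU = backgroundHU,
                 corticalSD = corticalSD, trabecularSD = trabecularSD,
                 backgroundSD = backgroundSD, tiltDeg = tiltDeg,
                 volDim = as.integer(volDim), seed = seed),
            class = "PhantomSpec")
}

#' Generate a femur-like CT phantom
#'
#' @param spec a [phantomSpec()].
#' @return a [CTVolume-class]; bit-reproducible for a fixed seed.
#' @export
makePhantom <- function(spec = phantomSpec()) {
  d <- spec$volDim
  sp <- rep(spec$voxelMM, 3)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  ctr <- (d - 1) / 2 * sp
  xyz <- sweep(voxelCenters(idx, sp, c(0, 0, 0)), 2, ctr)
  th <- spec$tiltDeg * pi / 180
  axis <- c(sin(th), 0, cos(th))
  t <- xyz %*% axis
  radial2 <- rowSums(xyz^2) - t^2
  rOut <- spec$outerRadiusMM
  rIn <- rOut - spec$corticalThicknessMM
  inLength <- abs(t) <= spec$lengthMM / 2 + 1e-9
  shell <- inLength & radial2 <= rOut^2 & radial2 > rIn^2
  core <- inLength & radial2 <= rIn^2
  hu <- rep(spec$backgroundHU, nrow(xyz))
  hu[shell] <- spec$corticalHU
  hu[core] <- spec$trabecularHU
  withSeed(spec$seed, {
    if (spec$backgroundSD > 0) {
      bg <- !(shell | core)
      hu[bg] <- hu[bg] + stats::rnorm(sum(bg), 0, spec$backgroundSD)
    }
    if (spec$corticalSD > 0)
      hu[shell] <- hu[shell] + stats::rnorm(sum(shell), 0, spec$corticalSD)
    if (spec$trabecularSD > 0)
      hu[core] <- hu[core] + stats::rnorm(sum(core), 0, spec$trabecularSD)
  })
  ctVolume(array(hu, d), spacing = sp, origin = c(0, 0, 0))
}

#' Cohort specification
#'
#' The generating relation for density is selected by `mode`:
#' "age", "bmi", "weight", "height" and "stress" use the published bivariate
#' fits plus Gaussian noise; "gender-means" draws each gender's density from
#' its published mean and SD; "race-means" uses race mean offsets that
#' reproduce the published ordering. Ages are uniform on 23-95 (female) /
#' 26-92 (male).
#'
#' @param n number of subjects (default 313).
#' @param mode generating relation for density.
#' @param noiseSD Gaussian noise SD on density (g/cm^3); mode-specific
#'   default (0.05, except 0.02 for "stress" and the published per-gender
#'   SDs for "gender-means").
#' @param stressNoiseSD noise SD (MPa) on the statistical max-stress column
#'   when it is derived from density rather than an FE run.
#' @param raceProportions named proportions over Caucasian, Black, Asian,
#'   Mixed (must sum to 1).
#' @param seed RNG seed.
#' @return a list of class "CohortSpec".
#' @export
cohortSpec <- function(n = 313L,
                       mode = c("age", "gender-means", "bmi", "weight",
                                "height", "stress", "race-means"),
                       noiseSD = NULL, stressNoiseSD = 2,
                       raceProportions = c(Caucasian = 0.6, Black = 0.2,
                                           Asian = 0.1, Mixed = 0.1),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (abs(sum(raceProportions) - 1) > 1e-9)
    stop("race proportions must sum to 1", call. = FALSE)
  if (is.null(noiseSD))
    noiseSD <- switch(mode, stress = 0.02, `gender-means` = NA_real_, 0.05)
  structure(list(n = as.integer(n), mode = mode, noiseSD = noiseSD,
                 stressNoiseSD = stressNoiseSD,
                 raceProportions = raceProportions, seed = seed),
            class = "CohortSpec")
}

#' Generate a synthetic demographic cohort
#'
#' @param spec a [cohortSpec()].
#' @return a validated cohort data.frame (see [validateCohort()]) with
#'   columns id, age, gender, race, bmi, weight_lbs, height_ft, height_m,
#'   density, maxVonMises, damage; deterministic per seed.
#' @export
makeCohort <- function(spec = cohortSpec()) {
  n <- spec$n
  withSeed(spec$seed, {
    gender <- sample(c("female", "male"), n, replace = TRUE)
    age <- vapply(gender, function(g)
      stats::runif(1, AGE_RANGE[[g]][1], AGE_RANGE[[g]][2]), numeric(1))
    race <- sample(names(spec$raceProportions), n, replace = TRUE,
                   prob = spec$raceProportions)
    bmi <- stats::runif(n, 18, 45)
    weight <- stats::runif(n, 100, 300)
    heightFt <- stats::runif(n, 4.8, 6.6)
    rel <- COHORT_RELATIONS
    density <- switch(spec$mode,
      age = rel$age[["intercept"]] + rel$age[["slope"]] * age +
        stats::rnorm(n, 0, spec$noiseSD),
      bmi = rel$bmi[["intercept"]] + rel$bmi[["slope"]] * bmi +
        stats::rnorm(n, 0, spec$noiseSD),
      weight = rel$weight[["intercept"]] + rel$weight[["slope"]] * weight +
        stats::rnorm(n, 0, spec$noiseSD),
      height = rel$height[["intercept"]] + rel$height[["slope"]] * heightFt +
        stats::rnorm(n, 0, spec$noiseSD),
      `gender-means` = {
        m <- vapply(gender, function(g) GENDER_DENSITY[[g]][["mean"]],
                    numeric(1))
        s <- if (is.na(spec$noiseSD))
          vapply(gender, function(g) GENDER_DENSITY[[g]][["sd"]],
                 numeric(1)) else spec$noiseSD
        m + if (all(s == 0)) 0 else stats::rnorm(n, 0, s)
      },
      `race-means` = RACE_DENSITY[race] + stats::rnorm(n, 0, spec$noiseSD),
      stress = NA_real_)
    if (spec$mode == "stress") {
      maxStress <- stats::runif(n, 40, 110)
      density <- rel$stress[["intercept"]] +
        rel$stress[["slope"]] * maxStress + stats::rnorm(n, 0, spec$noiseSD)
    } else {
      maxStress <- (density - rel$stress[["intercept"]]) /
        rel$stress[["slope"]] +
        if (spec$stressNoiseSD > 0) stats::rnorm(n, 0, spec$stressNoiseSD)
        else 0
    }
    density <- pmax(density, 1e-3)
    tab <- data.frame(id = seq_len(n), age = age, gender = gender,
                      race = race, bmi = bmi, weight_lbs = weight,
                      height_ft = heightFt, height_m = heightFt * 0.3048,
                      density = unname(density),
                      maxVonMises = pmax(unname(maxStress), 0))
    tab$damage <- pmin(tab$maxVonMises / ULT_STRENGTH[["cortical"]], 1)
    rownames(tab) <- NULL
    validateCohort(tab)
    tab
  })
}

#' Parametric double-peak gait load curve
#'
#' Hip contact force over one gait cycle as two raised-cosine bumps in
#' body-weight multiples (defaults 2.38 and 2.20 x body weight at 15% and
#' 48% of the cycle, zero through the swing tail). With the default 101
#' samples the grid hits both peak times exactly.
#'
#' @param bodyWeightN body weight in N (> 0).
#' @param nSteps number of samples over the cycle (>= 2).
#' @param peaks peak force multiples of body weight.
#' @param peakTimes peak locations as cycle fractions.
#' @param width full support of each bump (cycle fraction).
#' @param cycleDuration cycle length in seconds.
#' @return data.frame(time_s, force_N).
#' @export
makeGaitCurve <- function(bodyWeightN, nSteps = 101L, peaks = c(2.38, 2.20),
                          peakTimes = c(0.15, 0.48), width = 0.25,
                          cycleDuration = 1) {
  if (bodyWeightN <= 0) stop("body weight must be > 0", call. = FALSE)
  if (nSteps < 2L) stop("need >= 2 steps", call. = FALSE)
  if (length(peaks) != length(peakTimes))
    stop("peaks and peakTimes must have equal length", call. = FALSE)
  frac <- seq(0, 1, length.out = nSteps)
  force <- numeric(nSteps)
  for (i in seq_along(peaks)) {
    u <- (frac - peakTimes[i]) / width
    bump <- ifelse(abs(u) <= 0.5, cos(pi * u)^2, 0)
    force <- force + peaks[i] * bodyWeightN * bump
  }
  data.frame(time_s = frac * cycleDuration, force_N = force)
}

#' Generate synthetic uniaxial compression/tension test data
#'
#' Samples the incompressible uniaxial Mooney-Rivlin response of a card and
#' adds Gaussian noise; feeding the zero-noise output to
#' [fitMooneyRivlin()] recovers the card's constants.
#'
#' @param card a [MooneyRivlinCard-class].
#' @param lambdas stretch ratios (nonempty).
#' @param noiseSD Gaussian noise on the nominal stress (MPa).
#' @param seed RNG seed.
#' @return data.frame(stretch, nominal_stress_MPa).
#' @export
makeUniaxialTestData <- function(card, lambdas = seq(0.8, 1.3, by = 0.05),
                                 noiseSD = 0, seed = NULL) {
  if (!length(lambdas)) stop("lambdas must be nonempty", call. = FALSE)
  P <- mooneyRivlinUniaxial(card, lambdas)
  if (noiseSD > 0)
    P <- withSeed(seed, P + stats::rnorm(length(P), 0, noiseSD))
  data.frame(stretch = lambdas, nominal_stress_MPa = P)
}

#' Reference Mooney-Rivlin card for a compartment
#'
#' A synthetic stand-in for compression test data: constants chosen so the
#' small-strain tangent 6(C10 + C01) matches the compartment's elastic
#' power-law modulus at the given density, split 3:1 between C10 and C01
#' with a small C11 coupling term.
#'
#' @param compartment "cortical" or "trabecular".
#' @param rho density at which the tangent matches (g/cm^3).
#' @return a [MooneyRivlinCard-class].
#' @export
mooneyRivlinReferenceCard <- function(compartment = c("cortical",
                                                      "trabecular"),
                                      rho = NULL) {
  compartment <- match.arg(compartment)
  if (is.null(rho))
    rho <- if (compartment == "cortical") 1.15802 else 0.93508
  E <- compartmentModulus(rho, compartment)
  C10 <- E / 8
  C01 <- E / 24           # 6*(C10 + C01) = E
  new("MooneyRivlinCard", C10 = C10, C01 = C01, C11 = 0.05 * C10,
      d = 2 / (1000 * E), positiveSlope = TRUE, rho = rho,
      compartment = compartment, nVoxels = 0L)
}
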