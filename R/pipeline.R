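## Pipeline orchestration: a single flat configuration, staged execution
## with a run manifest, and the four-law comparison.

#' Pipeline configuration with the published parameters as defaults
#'
#' Flat, human-editable configuration covering every stage. Unknown keys
#' are rejected. Defaults embody the published parameters: calibration
#' slope 0.0000464 g/cm^3 per HU, eight segments, ten groups per segment,
#' nu 0.4/0.25/0.25, strengths 100/10 MPa.
#'
#' @param ... overrides of the defaults listed below.
#' @return a list of class "PipelineConfig".
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    calibration_slope = 0.0000464,    # g/cm^3 per HU
    calibration_intercept = 1.0,      # g/cm^3
    bone_hu_threshold = 200,          # HU
    cortical_hu_threshold = 700,      # HU
    n_segments = 8L,
    n_groups_per_segment = 10L,
    binning = "equal-width",
    law = "anisotropic",
    shear_units = "GPa",              # "MPa" reproduces the printed values
    solver_tol = 1e-8,
    solver_dof_threshold = 150000L,
    body_weight_N = 700,
    gait_peaks = c(2.38, 2.20),
    gait_peak_times = c(0.15, 0.48),
    gait_steps = 101L,
    damage_summary = "max-utilization",
    phantom_size = "test",
    cohort_n = 313L,
    cohort_mode = "age",
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults[names(over)] <- over
  structure(defaults, class = "PipelineConfig")
}

configSegmentation <- function(cfg)
  segmentationConfig(cfg$bone_hu_threshold, cfg$cortical_hu_threshold,
                     cfg$n_segments, cfg$n_groups_per_segment, cfg$binning)

## phantom -> labels -> density -> groups, shared by several stages
segmentPhantom <- function(vol, cfg) {
  sc <- configSegmentation(cfg)
  mask <- boneMask(vol, sc)
  comp <- splitCompartments(vol, mask, sc)
  seg <- longitudinalSegments(mask, sc)
  rho <- huToDensity(vol, mask,
                     calibration(cfg$calibration_slope,
                                 cfg$calibration_intercept))
  groups <- materialGroups(rho, comp, seg, sc)
  list(mask = mask, compartments = comp, segments = seg, density = rho,
       groups = groups)
}

cardsForLaw <- function(seg, law, cfg) {
  if (law == "anisotropic") {
    scaling <- withCallingHandlers(
      shearScaling(rhoMax = max(seg$density@values),
                   units = cfg$shear_units),
      warning = function(w) invokeRestart("muffleWarning"))
    buildMaterialCards(seg$density, seg$groups, "anisotropic",
                       scaling = scaling)
  } else if (law == "hyperelastic") {
    tab <- seg$groups@meta$groups
    rhoFit <- c(
      cortical = mean(tab$meanDensity[tab$compartment == 1L]),
      trabecular = mean(tab$meanDensity[tab$compartment == 2L]))
    testData <- list(rhoFit = rhoFit)
    for (cp in c("cortical", "trabecular"))
      if (is.finite(rhoFit[[cp]]))
        testData[[cp]] <- makeUniaxialTestData(
          mooneyRivlinReferenceCard(cp, rhoFit[[cp]]))
    buildMaterialCards(seg$density, seg$groups, "hyperelastic",
                       testData = testData)
  } else buildMaterialCards(seg$density, seg$groups, law)
}

## replace material-point-only cards by their small-strain tangent
## isotropic equivalents so a linear solve is possible
linearizeCards <- function(cardset) {
  if (cardset@law %in% c("elastic", "anisotropic")) return(cardset)
  cards <- lapply(cardset@cards, function(card) {
    E <- if (is(card, "MooneyRivlinCard")) mooneyRivlinTangent(card)
         else card@E
    new("IsotropicElasticCard", E = E, nu = 0.25, rho = card@rho,
        compartment = card@compartment, nVoxels = card@nVoxels)
  })
  new("MaterialCardSet", cards = cards, law = "elastic",
      groups = cardset@groups)
}

#' Compare the four material representations on one phantom
#'
#' Runs the full pipeline on a phantom under the gait load for each of the
#' four constitutive representations and reports the maximum von Mises
#' stress of each. The elastic and anisotropic laws are solved directly;
#' the elastic-plastic law reuses the elastic field with stresses capped at
#' the compartment yield strength; the hyper-elastic law is linearized to
#' its small-strain tangent.
#'
#' @param phantom a [CTVolume-class] (default: the test-size phantom).
#' @param cfg a [pipelineConfig()].
#' @return list with `maxVonMises` (named numeric: elastic, plastic,
#'   hyperelastic, anisotropic), the per-law [FEResult-class]s for the two
#'   linear laws, and the segmentation.
#' @export
fourLawComparison <- function(phantom = NULL, cfg = pipelineConfig()) {
  vol <- phantom %||% makePhantom(phantomSpec(cfg$phantom_size,
                                              seed = cfg$seed))
  seg <- segmentPhantom(vol, cfg)
  mesh <- buildMesh(seg$mask, seg$groups, vol)
  gait <- makeGaitCurve(cfg$body_weight_N, cfg$gait_steps, cfg$gait_peaks,
                        cfg$gait_peak_times)
  lcase <- loadCase(mesh, totalForce = -max(gait$force_N))
  solveLaw <- function(cards) {
    sys <- assembleSystem(mesh, linearizeCards(cards))
    gaitSweep(sys, gait, lcase, tol = cfg$solver_tol,
              dofThreshold = cfg$solver_dof_threshold)
  }
  cardsE <- cardsForLaw(seg, "elastic", cfg)
  cardsP <- cardsForLaw(seg, "plastic", cfg)
  cardsH <- cardsForLaw(seg, "hyperelastic", cfg)
  cardsA <- cardsForLaw(seg, "anisotropic", cfg)
  resE <- solveLaw(cardsE)
  resH <- solveLaw(cardsH)
  resA <- solveLaw(cardsA)
  ## plastic: elastic field with the stress capped at yield per element
  sigmaUlt <- vapply(as.character(mesh@elemGroup), function(g)
    cardsP@cards[[g]]@sigmaUltCompression, numeric(1))
  vmPlastic <- pmin(resE@vonMises, sigmaUlt)
  list(maxVonMises = c(elastic = max(resE@vonMises),
                       plastic = max(vmPlastic),
                       hyperelastic = max(resH@vonMises),
                       anisotropic = max(resA@vonMises)),
       results = list(elastic = resE, hyperelastic = resH,
                      anisotropic = resA),
       cards = list(elastic = cardsE, plastic = cardsP,
                    hyperelastic = cardsH, anisotropic = cardsA),
       segmentation = seg, mesh = mesh, gait = gait)
}

writeManifest <- function(outDir, stage, cfg, outputs) {
  manifest <- list(
    stage = stage,
    config = unclass(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("voxbone")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  path <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run a pipeline stage
#'
#' Staged execution writing artifacts and a run manifest (config echo,
#' seed, versions, timestamps, output checksums) to `outDir`.
#'
#' Stages: "phantom" (NIfTI phantom), "cohort" (cohort CSV), "map"
#' (material cards JSON), "solve" (FE summary + element CSV + VTK mesh),
#' "damage" (element damage CSV), "stats" (bivariate fits JSON, gender
#' comparison, damage CDF CSV), "all" (everything).
#'
#' @param stage one of phantom, cohort, map, solve, damage, stats, all.
#' @param cfg a [pipelineConfig()].
#' @param outDir output directory (created).
#' @return invisibly, the manifest path.
#' @export
runPipeline <- function(stage = c("all", "phantom", "cohort", "map",
                                  "solve", "damage", "stats"),
                        cfg = pipelineConfig(), outDir = "voxbone-out") {
  stage <- match.arg(stage)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  wants <- function(s) stage %in% c("all", s)
  vol <- NULL; seg <- NULL; cards <- NULL; fe <- NULL
  needPhantom <- stage %in% c("all", "phantom", "map", "solve", "damage")
  if (needPhantom) {
    vol <- makePhantom(phantomSpec(cfg$phantom_size, seed = cfg$seed))
    if (wants("phantom")) {
      p <- file.path(outDir, "phantom.nii.gz")
      writeVolume(vol, p)
      outputs <- c(outputs, p)
    }
  }
  if (stage %in% c("all", "map", "solve", "damage")) {
    seg <- segmentPhantom(vol, cfg)
    cards <- cardsForLaw(seg, cfg$law, cfg)
    if (wants("map")) {
      p <- file.path(outDir, "material_cards.json")
      exportCards(cards, p)
      outputs <- c(outputs, p)
    }
  }
  if (stage %in% c("all", "solve", "damage")) {
    mesh <- buildMesh(seg$mask, seg$groups, vol)
    sys <- assembleSystem(mesh, linearizeCards(cards))
    gait <- makeGaitCurve(cfg$body_weight_N, cfg$gait_steps,
                          cfg$gait_peaks, cfg$gait_peak_times)
    lcase <- loadCase(mesh, totalForce = -max(gait$force_N))
    fe <- gaitSweep(sys, gait, lcase, tol = cfg$solver_tol,
                    dofThreshold = cfg$solver_dof_threshold)
    if (wants("solve"))
      outputs <- c(outputs, exportResults(fe, outDir))
    if (wants("damage")) {
      dmg <- computeDamage(fe, cardsForLaw(seg, "plastic", cfg))
      p <- file.path(outDir, "damage.csv")
      ns <- ncol(dmg@utilization)
      utils::write.csv(data.frame(
        element = seq_len(nrow(dmg@utilization)),
        utilization = dmg@utilization[, ns],
        failed = dmg@failed[, ns]), p, row.names = FALSE)
      outputs <- c(outputs, p)
    }
  }
  if (stage %in% c("all", "cohort", "stats")) {
    cohort <- makeCohort(cohortSpec(cfg$cohort_n, cfg$cohort_mode,
                                    seed = cfg$seed))
    if (wants("cohort")) {
      p <- file.path(outDir, "cohort.csv")
      utils::write.csv(cohort, p, row.names = FALSE)
      outputs <- c(outputs, p)
    }
    if (wants("stats")) {
      fits <- list(
        density_age = bivariateFit(cohort, "age", "density"),
        density_bmi = bivariateFit(cohort, "bmi", "density"),
        density_stress = bivariateFit(cohort, "maxVonMises", "density"))
      gender <- twoSampleT(cohort, "gender", "density")
      p <- file.path(outDir, "cohort_stats.json")
      jsonlite::write_json(list(
        fits = lapply(fits, function(f) list(
          x = f@xName, y = f@yName, slope = f@slope,
          intercept = f@intercept, r_squared = f@rSquared,
          se = as.list(f@se), n = f@n)),
        gender_welch = gender), p, auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      outputs <- c(outputs, p)
      cdf <- damageCDF(cohort, "gender", "damage")
      p2 <- file.path(outDir, "damage_cdf.csv")
      utils::write.csv(cdf, p2, row.names = FALSE)
      outputs <- c(outputs, p2)
    }
  }
  invisible(writeManifest(outDir, stage, cfg, outputs))
}
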