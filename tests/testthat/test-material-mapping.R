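# Calibration, density-modulus power laws, shear scaling, card building,
# Mooney-Rivlin fitting. Reference values frozen from high-precision
# evaluation of the closed forms.

E1_CORT_1158 <- 2913.38291438122     # 2314 * 1.15802^1.57
E3_CORT_1158 <- 3249.39630052855     # 2065 * 1.15802^3.09
E1_TRAB_0935 <- 1026.70142853550     # 1157 * 0.93508^1.78
E3_TRAB_0935 <- 1705.52827546013     # 1904 * 0.93508^1.64

densityVolumeOf <- function(hu, maskOn = TRUE) {
  d <- c(2, 2, 2)
  vol <- ctVolume(array(hu, d))
  msk <- labelMap(array(as.integer(maskOn), d))
  huToDensity(vol, msk)
}

test_that("HU-to-density calibration is the printed linear map", {
  expect_equal(voxelValues(densityVolumeOf(0))[1], 1.0)
  expect_equal(voxelValues(densityVolumeOf(1000))[1], 1.0464)
  # the printed cortical density back-solves to HU 3405.6034...
  expect_equal(voxelValues(densityVolumeOf(0.15802 / 0.0000464))[1],
               1.15802, tolerance = 1e-9)
  # strictly increasing in HU
  hu <- seq(-500, 3000, by = 250)
  rho <- vapply(hu, function(h) voxelValues(densityVolumeOf(h))[1],
                numeric(1))
  expect_true(all(diff(rho) > 0))
  # a calibration that produces non-positive density is rejected
  vol <- ctVolume(array(0, c(2, 2, 2)))
  msk <- labelMap(array(1L, c(2, 2, 2)))
  expect_error(huToDensity(vol, msk, calibration(intercept = -1)),
               "non-positive")
  # background stays zero
  d <- c(3, 3, 3)
  msk2 <- labelMap(array(c(1L, rep(0L, 26)), d))
  rhoV <- huToDensity(ctVolume(array(100, d)), msk2)
  expect_equal(sum(voxelValues(rhoV) > 0), 1L)
})

test_that("cortical and trabecular power laws match the closed forms", {
  sc <- quietShearScaling(rhoMax = 1)
  c1 <- corticalConstants(1, sc)
  expect_equal(c1@E1, 2314); expect_equal(c1@E2, 2314)
  expect_equal(c1@E3, 2065)
  expect_equal(c1@G12, 5.71); expect_equal(c1@G23, 7.11)
  expect_equal(c1@G31, 6.58)
  expect_equal(c(c1@nu12, c1@nu23, c1@nu31), c(0.4, 0.25, 0.25))

  sc2 <- quietShearScaling(rhoMax = 1.2)
  expect_warning(c2 <- corticalConstants(1.15802, sc2), NA)
  expect_equal(c2@E1, E1_CORT_1158, tolerance = 1e-9)
  expect_equal(c2@E3, E3_CORT_1158, tolerance = 1e-9)

  t1 <- trabecularConstants(1, quietShearScaling(rhoMax = 1))
  expect_equal(t1@E1, 1157); expect_equal(t1@E3, 1904)
  expect_equal(t1@G23, 7.11)
  t2 <- trabecularConstants(0.93508, sc2)
  expect_equal(t2@E1, E1_TRAB_0935, tolerance = 1e-9)
  expect_equal(t2@E3, E3_TRAB_0935, tolerance = 1e-9)

  expect_error(corticalConstants(0, sc), "positive")
  expect_warning(corticalConstants(1.3, sc2), "exceeds rhoMax")

  # all moduli strictly increasing over a density grid
  grid <- seq(0.2, 1.2, by = 0.05)
  for (f in list(corticalConstants, trabecularConstants)) {
    cards <- lapply(grid, f, scaling = sc2)
    for (s in c("E1", "E3", "G12", "G23", "G31"))
      expect_true(all(diff(vapply(cards, slot, numeric(1), s)) > 0))
  }
  # shear scaling: G(rhoMax) = Gmax exactly, quadratic ratio elsewhere
  cMax <- corticalConstants(1.2, sc2)
  expect_identical(cMax@G12, 5.71)
  cHalf <- corticalConstants(0.6, sc2)
  expect_equal(cHalf@G12 / 5.71, 0.25, tolerance = 1e-12)
  # GPa reading scales by 1000
  scG <- shearScaling(rhoMax = 1, units = "GPa")
  expect_equal(corticalConstants(1, scG)@G12, 5710)
  # the MPa-as-printed reading warns loudly
  expect_warning(shearScaling(rhoMax = 1), "implausible")
})

test_that("isotropic and plastic cards carry the tabulated properties", {
  expect_equal(isotropicCard(1, "cortical")@E, 2314)
  expect_equal(isotropicCard(1.15802, "cortical")@E, E1_CORT_1158,
               tolerance = 1e-9)
  expect_equal(isotropicCard(0.93508, "trabecular")@E, E1_TRAB_0935,
               tolerance = 1e-9)
  expect_equal(isotropicCard(1, "cortical")@nu, 0.25)
  expect_error(isotropicCard(1, "femur"))

  pc <- plasticCard(1.1, "cortical")
  expect_equal(pc@sigmaUltCompression, 100)
  expect_equal(pc@sigmaUltTension, 100)
  expect_equal(pc@fractureStrain, 0.03)
  pt <- plasticCard(0.9, "trabecular")
  expect_equal(pt@sigmaUltCompression, 10)
  expect_equal(pt@fractureStrain, 0.07)
  # tabulated fracture-strain range allows an override
  expect_equal(plasticCard(1.1, "cortical",
                           fractureStrain = 0.01)@fractureStrain, 0.01)
  expect_equal(pc@hardness, 100)
})

test_that("Mooney-Rivlin fitting is exact on exact data", {
  card <- mrTestCard(1, 0.5, 0.2)
  td <- makeUniaxialTestData(card, c(0.8, 0.9, 1.1, 1.2, 1.3))
  fit <- fitMooneyRivlin(td)
  expect_equal(c(fit@C10, fit@C01, fit@C11), c(1, 0.5, 0.2),
               tolerance = 1e-10)
  # lambda = 1 contributes zero stress and zero information
  expect_equal(mooneyRivlinUniaxial(card, 1), 0)
  td1 <- rbind(td, data.frame(stretch = 1, nominal_stress_MPa = 0))
  fit1 <- fitMooneyRivlin(td1)
  expect_equal(c(fit1@C10, fit1@C01, fit1@C11), c(1, 0.5, 0.2),
               tolerance = 1e-10)
  # two informative points are rank deficient
  expect_error(fitMooneyRivlin(td[1:2, ]), "at least 3")
  expect_error(
    fitMooneyRivlin(data.frame(stretch = c(0.9, 1.1, 1, 1),
                               nominal_stress_MPa = c(-1, 1, 0, 0))),
    "at least 3")
  # CSV reader round-trips the fit input
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(td, f, row.names = FALSE)
  expect_equal(fitMooneyRivlin(readUniaxialData(f))@C10, 1,
               tolerance = 1e-10)
})

test_that("card sets evaluate each law at the group mean density", {
  fx <- tubeFixture(seed = 5L)
  rho <- huToDensity(fx$vol, fx$mask)
  cfgSmall <- segmentationConfig(nSegments = 2L, nGroupsPerSegment = 2L)
  segs <- longitudinalSegments(fx$mask, cfgSmall)
  groups <- materialGroups(rho, fx$comp, segs, cfgSmall)
  sc <- quietShearScaling(rhoMax = max(rho@values))
  aniso <- buildMaterialCards(rho, groups, "anisotropic", scaling = sc)
  tab <- groups@meta$groups
  # zero-noise tube: each stratum has constant density, so 2 seg x 2 comp
  expect_equal(length(aniso@cards), nrow(tab))
  for (i in seq_len(nrow(tab))) {
    card <- aniso@cards[[as.character(tab$group[i])]]
    ref <- if (tab$compartment[i] == 1L)
      corticalConstants(tab$meanDensity[i], sc)
    else trabecularConstants(tab$meanDensity[i], sc)
    expect_equal(card@E1, ref@E1, tolerance = 1e-12)
    expect_equal(card@E3, ref@E3, tolerance = 1e-12)
    expect_equal(card@G12, ref@G12, tolerance = 1e-12)
  }
  # elastic cards differ only in E; nu is 0.25 throughout
  el <- buildMaterialCards(rho, groups, "elastic")
  expect_true(all(vapply(el@cards, function(c) c@nu, numeric(1)) == 0.25))
  # plastic cards carry the tabulated strengths
  pl <- buildMaterialCards(rho, groups, "plastic")
  stren <- vapply(pl@cards, function(c) c@sigmaUltCompression, numeric(1))
  comp <- vapply(pl@cards, function(c) c@compartment, character(1))
  expect_true(all(stren[comp == "cortical"] == 100))
  expect_true(all(stren[comp == "trabecular"] == 10))
  # hyperelastic needs test data
  expect_error(buildMaterialCards(rho, groups, "hyperelastic"),
               "testData")
  # card export is valid JSON keyed by group
  f <- withr::local_tempfile(fileext = ".json")
  exportCards(aniso, f)
  doc <- jsonlite::read_json(f)
  expect_equal(length(doc), length(aniso@cards))
  expect_equal(doc[[1]]$law, "anisotropic")
})
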