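# Stiffness assembly, von Mises, and the four uniaxial responses.

test_that("stiffness assembly reproduces closed forms and stays PD", {
  # isotropic, E = 1, nu = 0: diagonal (1,1,1,.5,.5,.5) with eng. shear
  C0 <- assembleStiffness(new("IsotropicElasticCard", E = 1, nu = 0,
                              rho = 1, compartment = "cortical",
                              nVoxels = 0L))
  expect_equal(C0, diag(c(1, 1, 1, 0.5, 0.5, 0.5)), tolerance = 1e-12)
  # isotropic limit of the orthotropic path
  iso <- assembleStiffness(new("IsotropicElasticCard", E = 1000, nu = 0.25,
                               rho = 1, compartment = "cortical",
                               nVoxels = 0L))
  ortho <- assembleStiffness(isotropicMatchedOrthoCard(1000, 0.25))
  expect_equal(ortho, iso, tolerance = 1e-10)
  # stiffness is the inverse of the built compliance and symmetric
  card <- corticalConstants(1.15802, quietShearScaling(rhoMax = 1.2))
  C <- assembleStiffness(card)
  expect_equal(C, t(C), tolerance = 1e-10)
  S <- matrix(0, 6, 6)
  S[1, 1] <- 1 / card@E1; S[2, 2] <- 1 / card@E2; S[3, 3] <- 1 / card@E3
  S[1, 2] <- S[2, 1] <- -card@nu12 / card@E1
  S[2, 3] <- S[3, 2] <- -card@nu23 / card@E2
  S[3, 1] <- S[1, 3] <- -card@nu31 / card@E3
  diag(S)[4:6] <- 1 / c(card@G23, card@G31, card@G12)
  expect_equal(C %*% S, diag(6), tolerance = 1e-8)
  # both unit readings of the printed shear maxima assemble PD here
  for (units in c("MPa", "GPa")) {
    cardU <- corticalConstants(1.15802,
                               quietShearScaling(rhoMax = 1.2,
                                                 units = units))
    ev <- eigen(assembleStiffness(cardU), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
  # a non-PD combination is refused
  bad <- isotropicMatchedOrthoCard(1000, 0.25)
  bad@nu23 <- 0.95; bad@nu12 <- 0.95
  expect_error(assembleStiffness(bad), "positive definite")
})

test_that("von Mises stress has its closed-form values and invariances", {
  expect_equal(vonMisesStress(c(3, 3, 3, 0, 0, 0)), 0)
  expect_equal(vonMisesStress(c(5, 0, 0, 0, 0, 0)), 5)
  expect_equal(vonMisesStress(c(-7, 0, 0, 0, 0, 0)), 7)
  expect_equal(vonMisesStress(c(0, 0, 0, 0, 0, 2)), 2 * sqrt(3),
               tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    s <- rnorm(6, 0, 10)
    p <- rnorm(1, 0, 50)
    cc <- rnorm(1, 0, 3)
    expect_equal(vonMisesStress(s + c(p, p, p, 0, 0, 0)),
                 vonMisesStress(s), tolerance = 1e-9)
    expect_equal(vonMisesStress(cc * s), abs(cc) * vonMisesStress(s),
                 tolerance = 1e-9)
  }
  # matrix form
  expect_equal(vonMisesStress(rbind(c(5, 0, 0, 0, 0, 0),
                                    c(1, 1, 1, 0, 0, 0))), c(5, 0))
})

test_that("elastic uniaxial response is linear and odd", {
  card <- isotropicCard(1, "cortical")  # E = 2314
  expect_equal(elasticUniaxial(card, 0), 0)
  expect_equal(elasticUniaxial(card, 0.001), 2.314)
  expect_equal(elasticUniaxial(card, -0.003),
               -elasticUniaxial(card, 0.003))
  expect_error(elasticUniaxial(card, 0.3), "0.2")
})

test_that("plastic path caps at yield, unloads elastically, dissipates", {
  card <- new("PlasticCard", E = 1000, nu = 0.25, sigmaUltTension = 100,
              sigmaUltCompression = 100, fractureStrain = 0.03,
              hardness = 100, rho = 1, compartment = "cortical",
              nVoxels = 0L)
  expect_equal(plasticUniaxialPath(card, 0.05)$stress_MPa, 50)
  expect_equal(plasticUniaxialPath(card, 0.2)$stress_MPa, 100)
  # hand-computed elastic unloading: 100 - 1000 * 0.05 = 50
  p <- plasticUniaxialPath(card, c(0.2, 0.15))
  expect_equal(p$stress_MPa, c(100, 50))
  expect_true(p$failed[1])       # 0.2 > fracture strain 0.03
  expect_false(plasticUniaxialPath(card, 0.02)$failed)
  # never exceeds yield on random paths; closed loops dissipate >= 0
  set.seed(2)
  for (i in 1:10) {
    path <- cumsum(rnorm(40, 0, 0.03))
    loop <- c(path, rev(path)[-1], 0)
    # upsample so the trapezoid work integral resolves the yield kinks
    fine <- unlist(lapply(seq_along(loop), function(k) {
      from <- if (k == 1) 0 else loop[k - 1]
      seq(from, loop[k], length.out = 50)[-1]
    }))
    out <- plasticUniaxialPath(card, fine)
    expect_true(all(abs(out$stress_MPa) <= 100 + 1e-12))
    work <- sum(diff(c(0, fine)) *
                  (out$stress_MPa + c(0, head(out$stress_MPa, -1))) / 2)
    expect_gte(work, -1e-6)
  }
})

test_that("Mooney-Rivlin uniaxial response matches the closed form", {
  card <- mrTestCard(1, 0.5, 0)
  expect_equal(mooneyRivlinUniaxial(card, 1), 0)
  expect_equal(mooneyRivlinUniaxial(card, 1.1), 0.795792637114951,
               tolerance = 1e-12)
  expect_equal(mooneyRivlinUniaxial(card, 0.9), -1.04087791495199,
               tolerance = 1e-12)
  expect_error(mooneyRivlinUniaxial(card, -0.5), "stretch")
})

test_that("stress-strain curves have the per-law shapes", {
  el <- isotropicCard(1.1, "cortical")
  grid <- seq(-0.01, 0.01, by = 0.001)
  tabE <- stressStrainCurve("elastic", el, grid)
  expect_equal(tabE$stress_MPa, el@E * grid)
  pl <- plasticCard(1.1, "cortical")
  up <- seq(0, 0.06, by = 0.001)   # far enough to reach the plateau
  tabP <- stressStrainCurve("plastic", pl, up)
  expect_true(all(tabP$stress_MPa <= 100 + 1e-12))
  expect_equal(max(tabP$stress_MPa), 100)
  # bilinear: slope E then plateau
  expect_equal(tabP$stress_MPa[2] / up[2], pl@E, tolerance = 1e-9)
  # anisotropic curve loads along the bone axis with slope E3
  an <- corticalConstants(1.1, quietShearScaling(rhoMax = 1.2))
  tabA <- stressStrainCurve("anisotropic", an, grid)
  expect_equal(tabA$stress_MPa, an@E3 * grid)
  # hyper-elastic small-strain slope is 6 (C10 + C01)
  mr <- mrTestCard(1, 0.5, 0)
  h <- 1e-5
  fd <- (mooneyRivlinUniaxial(mr, 1 + h) -
           mooneyRivlinUniaxial(mr, 1 - h)) / (2 * h)
  expect_equal(fd, 6 * (mr@C10 + mr@C01), tolerance = 1e-3)
  expect_error(stressStrainCurve("magic", el, grid))
  expect_error(stressStrainCurve("elastic", el, c(0, 0.2, 0.1)),
               "monotone")
})
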