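# Voxel mesh construction, assembly, analytic solutions, gait sweep.

barSetup <- function(d = c(10, 10, 10), E = 1000, nu = 0.25,
                     cards = singleElasticCardSet(E, nu)) {
  mesh <- buildMesh(cuboidMask(d))
  sys <- assembleSystem(mesh, cards)
  lc <- loadCase(mesh, fixity = "rollers", totalForce = -100)
  list(mesh = mesh, sys = sys, lc = lc)
}

test_that("mesh nodes are deduplicated across shared faces", {
  m2 <- buildMesh(cuboidMask(c(2, 2, 2)))
  expect_equal(nrow(m2@elements), 8L)
  expect_equal(nrow(m2@nodes), 27L)
  m1 <- buildMesh(cuboidMask(c(1, 1, 1)))
  expect_equal(nrow(m1@elements), 1L)
  expect_equal(nrow(m1@nodes), 8L)
  twoVox <- labelMap(array(1L, c(2, 1, 1)))
  mt <- buildMesh(twoVox)
  expect_equal(nrow(mt@nodes), 12L)
  expect_error(buildMesh(labelMap(array(1L, c(2, 2, 2)),
                                  spacing = c(1, 1, 2))),
               "resample")
  expect_error(buildMesh(labelMap(array(0L, c(2, 2, 2)))), "empty")
})

test_that("single-element stiffness matches an independent quadrature", {
  card <- singleElasticCardSet(1500, 0.3)@cards[[1]]
  C <- assembleStiffness(card)
  mesh <- buildMesh(labelMap(array(1L, c(1, 1, 1)),
                             spacing = c(0.5, 0.5, 0.5)))
  sys <- assembleSystem(mesh, singleElasticCardSet(1500, 0.3))
  Ke <- as.matrix(sys$K)
  # oracle wants nodes and DOFs in element-local (hex) order
  e1 <- mesh@elements[1, ]
  dofs <- as.vector(t(cbind(3 * e1 - 2, 3 * e1 - 1, 3 * e1)))
  KeOracle <- denseHexStiffness(C, mesh@nodes[e1, ])
  expect_equal(Ke[dofs, dofs], KeOracle, tolerance = 1e-10,
               ignore_attr = TRUE)
  # free element: exactly 6 rigid-body zero-energy modes
  ev <- eigen(Ke, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6L)
  # global matrix symmetric
  expect_lt(max(abs(Ke - t(Ke))), 1e-9 * max(abs(Ke)))
  # an anisotropic card runs through the same quadrature
  cardA <- corticalConstants(1.1, quietShearScaling(rhoMax = 1.2,
                                                    units = "GPa"))
  CA <- assembleStiffness(cardA)
  setA <- singleElasticCardSet()
  setA@cards[[1]] <- cardA
  setA@law <- "anisotropic"
  sysA <- assembleSystem(mesh, setA)
  expect_equal(as.matrix(sysA$K)[dofs, dofs],
               denseHexStiffness(CA, mesh@nodes[e1, ]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("axial bar on rollers reproduces sigma = F/A exactly", {
  bs <- barSetup()
  res <- solveSystem(bs$sys, bs$lc)
  sig <- res@stress[[1]]
  # total axial force -100 N over 100 mm^2: sigma_33 = -1 MPa everywhere
  expect_equal(sig[, 3], rep(-1, nrow(sig)), tolerance = 1e-6)
  expect_equal(max(abs(sig[, c(1, 2, 4, 5, 6)])), 0, tolerance = 1e-6)
  expect_equal(res@vonMises[, 1], rep(1, nrow(sig)), tolerance = 1e-6)
  expect_lt(res@residuals, 1e-8)
  # equilibrium: reactions balance the applied load
  r <- reactionForces(bs$sys, res, bs$lc)
  expect_equal(sum(r), 100, tolerance = 1e-6)
  # refinement invariance: halved voxels, same uniform stress
  fine <- buildMesh(labelMap(array(1L, c(20, 20, 20)),
                             spacing = c(0.5, 0.5, 0.5)))
  sysF <- assembleSystem(fine, singleElasticCardSet())
  resF <- solveSystem(sysF, loadCase(fine, fixity = "rollers",
                                     totalForce = -100))
  expect_equal(resF@stress[[1]][, 3], rep(-1, nrow(fine@elements)),
               tolerance = 1e-6)
})

test_that("orthotropic assembly with matched constants equals isotropic", {
  bs <- barSetup()
  resIso <- solveSystem(bs$sys, bs$lc)
  setO <- singleElasticCardSet()
  setO@cards[[1]] <- isotropicMatchedOrthoCard(1000, 0.25)
  setO@law <- "anisotropic"
  sysO <- assembleSystem(bs$mesh, setO)
  resO <- solveSystem(sysO, bs$lc)
  expect_equal(resO@displacements, resIso@displacements, tolerance = 1e-8)
})

test_that("patch test: affine boundary displacement gives uniform strain", {
  mesh <- buildMesh(cuboidMask(c(3, 3, 3)))
  sys <- assembleSystem(mesh, singleElasticCardSet())
  A <- matrix(c(1e-3, 2e-4, -1e-4,
                3e-4, -5e-4, 2e-4,
                -2e-4, 1e-4, 8e-4), 3, 3, byrow = TRUE)
  onBoundary <- apply(mesh@nodes, 1, function(p)
    any(abs(p - (-0.5)) < 1e-9 | abs(p - 2.5) < 1e-9))
  bnodes <- which(onBoundary)
  uB <- mesh@nodes[bnodes, ] %*% t(A)
  fixedDofs <- as.integer(t(outer(3L * bnodes, c(-2L, -1L, 0L), "+")))
  ord <- order(fixedDofs)
  lc <- new("LoadCase", fixedDofs = fixedDofs[ord],
            fixedValues = as.vector(t(uB))[ord],
            loadVector = numeric(sys$ndof), forceScale = 1, times = 0)
  res <- solveSystem(sys, lc)
  eps <- res@strain[[1]]
  sym <- (A + t(A)) / 2
  expected <- c(sym[1, 1], sym[2, 2], sym[3, 3],
                2 * sym[2, 3], 2 * sym[3, 1], 2 * sym[1, 2])
  for (k in 1:6)
    expect_equal(eps[, k], rep(expected[k], nrow(eps)), tolerance = 1e-8)
})

test_that("direct and iterative solvers agree", {
  bs <- barSetup(d = c(6, 6, 6))
  resD <- solveSystem(bs$sys, bs$lc, method = "direct")
  resC <- solveSystem(bs$sys, bs$lc, method = "cg", tol = 1e-10)
  expect_equal(resC@displacements, resD@displacements, tolerance = 1e-6)
})

test_that("insufficient constraints are reported as singular", {
  mesh <- buildMesh(cuboidMask(c(2, 2, 2)))
  sys <- assembleSystem(mesh, singleElasticCardSet())
  lc <- new("LoadCase", fixedDofs = 1L, fixedValues = 0,
            loadVector = numeric(sys$ndof), forceScale = 1, times = 0)
  expect_error(suppressWarnings(solveSystem(sys, lc)),
               "singular|factorization")
})

test_that("material-point-only laws are refused at assembly", {
  mesh <- buildMesh(cuboidMask(c(2, 2, 2)))
  set <- singleElasticCardSet()
  set@law <- "plastic"
  expect_error(assembleSystem(mesh, set), "material-point only")
})

test_that("gait sweep scales one factorization linearly", {
  bs <- barSetup(d = c(6, 6, 6))
  const <- data.frame(time_s = seq(0, 1, length.out = 5),
                      force_N = rep(100, 5))
  resConst <- gaitSweep(bs$sys, const, bs$lc)
  expect_equal(resConst@maxVonMises, rep(resConst@maxVonMises[1], 5))
  double <- const; double$force_N <- 200
  resDouble <- gaitSweep(bs$sys, double, bs$lc)
  expect_equal(resDouble@stress[[1]], 2 * resConst@stress[[1]],
               tolerance = 1e-12)
  gait <- makeGaitCurve(700)
  resGait <- gaitSweep(bs$sys, gait, bs$lc)
  # max-von-Mises trace proportional to the force trace, argmax at peak 1
  expect_equal(which.max(resGait@maxVonMises), which.max(gait$force_N))
  nz <- gait$force_N > 0
  ratio <- resGait@maxVonMises[nz] / gait$force_N[nz]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
  expect_error(gaitSweep(bs$sys, data.frame(time_s = c(-1, 0),
                                            force_N = c(1, 1)), bs$lc),
               "negative")
  expect_error(gaitSweep(bs$sys, const[1, ], bs$lc), ">= 2")
})

test_that("results export as summary JSON, element CSV and VTK", {
  bs <- barSetup(d = c(4, 4, 4))
  res <- solveSystem(bs$sys, bs$lc)
  dir <- withr::local_tempdir()
  paths <- exportResults(res, dir)
  expect_true(all(file.exists(paths)))
  summ <- jsonlite::read_json(file.path(dir, "fe_summary.json"))
  expect_equal(summ$global_max$value, max(res@vonMises), tolerance = 1e-9)
  el <- read.csv(file.path(dir, "elements.csv"))
  expect_equal(nrow(el), nrow(bs$mesh@elements))
  expect_equal(el$von_mises, res@vonMises[, 1], tolerance = 1e-9)
  vtk <- readLines(file.path(dir, "mesh.vtk"), n = 5)
  expect_match(vtk[4], "UNSTRUCTURED_GRID")
})
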