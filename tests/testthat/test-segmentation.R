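# Threshold masks, compartments, longitudinal segments, material groups.

test_that("bone mask is the HU threshold minus detached specks", {
  fx <- tubeFixture()
  hu <- voxelValues(fx$vol)
  expect_identical(voxelValues(fx$mask) > 0L, hu >= 200)

  expect_error(boneMask(ctVolume(array(-1000, c(6, 6, 6)))), "no bone")

  # a detached 2-voxel speck must be excluded; flood-fill BFS as oracle
  hu2 <- hu
  hu2[1, 1, 1] <- 1500; hu2[2, 1, 1] <- 1500
  vol2 <- ctVolume(hu2, spacing = voxelSpacing(fx$vol))
  m2 <- boneMask(vol2)
  comp <- floodFill6(hu2 >= 200)
  sizes <- table(comp[comp > 0])
  keep <- as.integer(names(sizes)[which.max(sizes)])
  expect_identical(voxelValues(m2) > 0L, comp == keep)
  expect_equal(voxelValues(m2)[1, 1, 1], 0L)
})

test_that("compartment split follows the cortical cutoff and is monotone", {
  fx <- tubeFixture()
  comp <- voxelValues(fx$comp)
  hu <- voxelValues(fx$vol)
  m <- voxelValues(fx$mask) > 0L
  expect_true(all(comp[m & hu >= 700] == 1L))
  expect_true(all(comp[m & hu < 700] == 2L))
  expect_true(all(comp[!m] == 0L))

  allCort <- ctVolume(array(1500, c(4, 4, 4)))
  mc <- boneMask(allCort)
  expect_warning(sc <- splitCompartments(allCort, mc), "no trabecular")
  expect_true(all(voxelValues(sc)[voxelValues(mc) > 0L] == 1L))

  # brute-force count per cutoff: cortical count non-increasing in cutoff
  counts <- vapply(seq(300, 1400, by = 100), function(cut) {
    cfg <- segmentationConfig(corticalHuThreshold = cut)
    sum(voxelValues(suppressWarnings(
      splitCompartments(fx$vol, fx$mask, cfg))) == 1L)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("longitudinal segments partition equally along the bone axis", {
  fx <- tubeFixture()
  seg <- voxelValues(fx$seg)
  m <- voxelValues(fx$mask) > 0L
  expect_setequal(unique(seg[m]), 1:8)
  expect_true(all(seg[!m] == 0L))
  # straight tube along z: segment boundaries at equal z-eighths
  zs <- which(m, arr.ind = TRUE)[, 3]
  segOfZ <- tapply(seg[m], zs, function(v) unique(v))
  expect_true(all(lengths(segOfZ) == 1L))  # whole slices share a segment
  # 48 slices spread evenly over 8 segments
  expect_true(all(table(unlist(segOfZ)) == 6L))

  one <- longitudinalSegments(fx$mask, segmentationConfig(nSegments = 1L))
  expect_true(all(voxelValues(one)[m] == 1L))

  expect_error(
    longitudinalSegments(labelMap(array(c(1L, rep(0L, 26)), c(3, 3, 3))),
                         segmentationConfig(nSegments = 8L)),
    "segments")
})

test_that("tilted tube segments balance along the known tilt axis", {
  # a tilted tube short enough to fit the volume untouched by the borders
  vol <- makePhantom(phantomSpec("test", tiltDeg = 30, lengthMM = 10,
                                 outerRadiusMM = 1.5,
                                 corticalThicknessMM = 0.7))
  mask <- boneMask(vol)
  m <- voxelValues(mask) > 0L
  cfg4 <- segmentationConfig(nSegments = 4L)
  seg4 <- voxelValues(longitudinalSegments(mask, cfg4))
  frac <- as.vector(table(seg4[m])) / sum(m)
  expect_equal(frac, rep(0.25, 4), tolerance = 0.08)
  # brute-force oracle: project onto the generating tilt axis
  idx <- which(m, arr.ind = TRUE)
  sp <- voxelSpacing(mask)
  xyz <- sweep(sweep(idx - 1, 2, sp, "*"), 2,
               colMeans(sweep(idx - 1, 2, sp, "*")))
  axis <- c(sin(pi / 6), 0, cos(pi / 6))
  t <- xyz %*% axis
  rng <- range(t)
  oracle <- pmin(floor((t - rng[1]) / diff(rng) * 4) + 1, 4)
  expect_gt(mean(oracle == seg4[m]), 0.95)
})

test_that("material groups bin densities per stratum as specified", {
  # equal-width: uniform densities on [1, 2], K = 10 -> edges at 1.0,1.1,...
  d <- c(10, 10, 1)
  rhoVals <- array(seq(1, 2, length.out = 100), d)
  rho <- new("DensityVolume", values = rhoVals, calibration = calibration(),
             spacing = c(1, 1, 1), origin = c(0, 0, 0))
  comp <- labelMap(array(1L, d), kind = "compartment")
  seg <- labelMap(array(1L, d), kind = "segment")
  g <- materialGroups(rho, comp, seg,
                      segmentationConfig(nSegments = 1L))
  bins <- voxelValues(g)[voxelValues(comp) > 0L]
  oracle <- pmin(floor((as.vector(rhoVals) - 1) / 1 * 10) + 1, 10)
  expect_identical(as.integer(bins), as.integer(oracle))

  # constant-density stratum collapses to a single group
  rhoC <- new("DensityVolume", values = array(1.5, d),
              calibration = calibration(), spacing = c(1, 1, 1),
              origin = c(0, 0, 0))
  gC <- materialGroups(rhoC, comp, seg, segmentationConfig(nSegments = 1L))
  expect_true(all(voxelValues(gC)[voxelValues(comp) > 0L] == 1L))
  expect_equal(nrow(gC@meta$groups), 1L)

  # quantile binning splits 1000 random densities into 100 +- 1 per group
  d2 <- c(10, 10, 10)
  set.seed(3)
  rv <- array(runif(1000, 0.5, 1.5), d2)
  rho2 <- new("DensityVolume", values = rv, calibration = calibration(),
              spacing = c(1, 1, 1), origin = c(0, 0, 0))
  g2 <- materialGroups(rho2, labelMap(array(1L, d2), kind = "compartment"),
                       labelMap(array(1L, d2), kind = "segment"),
                       segmentationConfig(nSegments = 1L,
                                          binning = "quantile"))
  counts <- g2@meta$groups$nVoxels
  expect_equal(length(counts), 10L)
  expect_true(all(abs(counts - 100) <= 1))
  # sort-and-split oracle
  expect_identical(as.integer(ceiling(rank(as.vector(rv),
                                           ties.method = "first") / 100)),
                   as.integer(voxelValues(g2)))
})

test_that("labels partition the mask and thresholds act monotonically", {
  fx <- tubeFixture()
  m <- voxelValues(fx$mask) > 0L
  rho <- huToDensity(fx$vol, fx$mask)
  g <- materialGroups(rho, fx$comp, fx$seg)
  for (lm in list(fx$comp, fx$seg, g)) {
    lab <- voxelValues(lm)
    expect_true(all(lab[m] > 0L))
    expect_true(all(lab[!m] == 0L))
  }
  # group table accounts for every masked voxel exactly once
  expect_equal(sum(g@meta$groups$nVoxels), sum(m))
  # group mean densities match a direct recomputation
  for (r in sample(nrow(g@meta$groups), 5)) {
    row <- g@meta$groups[r, ]
    expect_equal(mean(rho@values[voxelValues(g) == row$group]),
                 row$meanDensity, tolerance = 1e-12)
  }
  # raising the bone threshold never grows the mask
  sizes <- vapply(c(200, 400, 800, 1200), function(th)
    sum(voxelValues(boneMask(fx$vol,
                             segmentationConfig(boneHuThreshold = th,
                                                corticalHuThreshold = th + 1)))),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
})
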