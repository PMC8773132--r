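# Independent oracles and small fixtures shared across the test files.
# Each oracle is deliberately implemented differently from the package path
# it checks.

# breadth-first flood fill, 6-connectivity: returns component id per voxel
floodFill6 <- function(mask) {
  d <- dim(mask)
  comp <- array(0L, d)
  nextId <- 0L
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  todo <- which(mask)
  for (start in todo) {
    if (comp[start] != 0L) next
    nextId <- nextId + 1L
    queue <- start
    comp[start] <- nextId
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      k <- (cur - 1) %/% (d[1] * d[2])
      rem <- (cur - 1) %% (d[1] * d[2])
      j <- rem %/% d[1]; i <- rem %% d[1]
      for (o in seq_len(nrow(offsets))) {
        ni <- i + offsets[o, 1]; nj <- j + offsets[o, 2]
        nk <- k + offsets[o, 3]
        if (ni < 0 || ni >= d[1] || nj < 0 || nj >= d[2] ||
            nk < 0 || nk >= d[3]) next
        lin <- 1 + ni + d[1] * nj + d[1] * d[2] * nk
        if (mask[lin] && comp[lin] == 0L) {
          comp[lin] <- nextId
          queue <- c(queue, lin)
        }
      }
    }
  }
  comp
}

# independent hexahedral element stiffness: full isoparametric formulation
# with finite-difference shape gradients, numeric Jacobian, 3x3x3 Gauss
denseHexStiffness <- function(C, nodeCoords) {
  shape <- function(p) {
    s <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
               c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
    sapply(1:8, function(i)
      prod(1 + s[i, ] * p) / 8)
  }
  dshape <- function(p) {
    s <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
               c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
    t(sapply(1:8, function(i) {
      full <- 1 + s[i, ] * p
      s[i, ] * c(full[2] * full[3], full[1] * full[3],
                 full[1] * full[2]) / 8
    }))  # 8 x 3 in local coords
  }
  g1 <- sqrt(3 / 5)
  pts <- c(-g1, 0, g1)
  wts <- c(5, 8, 5) / 9
  Ke <- matrix(0, 24, 24)
  for (a in 1:3) for (b in 1:3) for (cdx in 1:3) {
    p <- c(pts[a], pts[b], pts[cdx])
    w <- wts[a] * wts[b] * wts[cdx]
    dN <- dshape(p)                       # 8 x 3 (d/dxi)
    J <- t(dN) %*% nodeCoords             # 3 x 3
    dNx <- dN %*% solve(J)                # 8 x 3 (d/dx)
    B <- matrix(0, 6, 24)
    for (i in 1:8) {
      c0 <- 3 * (i - 1)
      B[1, c0 + 1] <- dNx[i, 1]
      B[2, c0 + 2] <- dNx[i, 2]
      B[3, c0 + 3] <- dNx[i, 3]
      B[4, c0 + 2] <- dNx[i, 3]; B[4, c0 + 3] <- dNx[i, 2]
      B[5, c0 + 1] <- dNx[i, 3]; B[5, c0 + 3] <- dNx[i, 1]
      B[6, c0 + 1] <- dNx[i, 2]; B[6, c0 + 2] <- dNx[i, 1]
    }
    Ke <- Ke + w * t(B) %*% C %*% B * det(J)
  }
  Ke
}

# full-cuboid mask of given voxel dimensions
cuboidMask <- function(d, spacing = c(1, 1, 1)) {
  labelMap(array(1L, d), spacing = spacing)
}

# one-card elastic set for homogeneous meshes
singleElasticCardSet <- function(E = 1000, nu = 0.25) {
  new("MaterialCardSet",
      cards = list(`1` = new("IsotropicElasticCard", E = E, nu = nu,
                             rho = 1, compartment = "cortical",
                             nVoxels = 0L)),
      law = "elastic",
      groups = data.frame(group = 1L, segment = 1L, compartment = 1L,
                          bin = 1L, meanDensity = 1, nVoxels = 0L))
}

# orthotropic card numerically identical to an isotropic (E, nu) material
isotropicMatchedOrthoCard <- function(E = 1000, nu = 0.25) {
  G <- E / (2 * (1 + nu))
  new("OrthotropicCard", E1 = E, E2 = E, E3 = E, G12 = G, G23 = G, G31 = G,
      nu12 = nu, nu23 = nu, nu31 = nu, rho = 1, compartment = "cortical",
      nVoxels = 0L)
}

mrTestCard <- function(C10 = 1, C01 = 0.5, C11 = 0.2) {
  new("MooneyRivlinCard", C10 = C10, C01 = C01, C11 = C11, d = 1e-3,
      positiveSlope = TRUE, rho = 1, compartment = "cortical", nVoxels = 0L)
}

quietShearScaling <- function(...) suppressWarnings(shearScaling(...))

# straight-tube segmentation fixture shared by several files
tubeFixture <- function(tiltDeg = 0, seed = 7L) {
  vol <- makePhantom(phantomSpec("test", tiltDeg = tiltDeg, seed = seed))
  cfg <- segmentationConfig()
  mask <- boneMask(vol, cfg)
  list(vol = vol, cfg = cfg, mask = mask,
       comp = splitCompartments(vol, mask, cfg),
       seg = longitudinalSegments(mask, cfg))
}
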