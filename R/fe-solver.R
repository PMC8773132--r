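## Voxel hexahedral linear finite-element solver.
##
## One trilinear 8-node hexahedron per masked voxel, 3 displacement DOF per
## node, 2x2x2 Gauss quadrature, consistent mm-N-MPa units. The gait sweep
## is quasi-static: one spatial load pattern factorized once and scaled by
## the force at each time step.

## local corner signs in element order 1..8 (xi, eta, zeta)
HEX_SIGNS <- matrix(c(-1, -1, -1,   1, -1, -1,   1, 1, -1,  -1, 1, -1,
                      -1, -1,  1,   1, -1,  1,   1, 1,  1,  -1, 1,  1),
                    ncol = 3, byrow = TRUE)

## strain-displacement matrix (6 x 24) at local point (xi, eta, zeta) for a
## rectangular hex with edge lengths h (Voigt 11,22,33,23,31,12, eng. shear)
hexBMatrix <- function(xi, eta, zeta, h) {
  B <- matrix(0, 6, 24)
  for (i in 1:8) {
    s <- HEX_SIGNS[i, ]
    dNdx <- s[1] * (1 + s[2] * eta) * (1 + s[3] * zeta) / 8 * 2 / h[1]
    dNdy <- s[2] * (1 + s[1] * xi) * (1 + s[3] * zeta) / 8 * 2 / h[2]
    dNdz <- s[3] * (1 + s[1] * xi) * (1 + s[2] * eta) / 8 * 2 / h[3]
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- dNdx
    B[2, c0 + 2] <- dNdy
    B[3, c0 + 3] <- dNdz
    B[4, c0 + 2] <- dNdz; B[4, c0 + 3] <- dNdy
    B[5, c0 + 1] <- dNdz; B[5, c0 + 3] <- dNdx
    B[6, c0 + 1] <- dNdy; B[6, c0 + 2] <- dNdx
  }
  B
}

gaussPoints2 <- function() {
  g <- 1 / sqrt(3)
  as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
}

## 24x24 element stiffness for stiffness matrix C and edge lengths h
hexElementStiffness <- function(C, h) {
  gp <- gaussPoints2()
  detJ <- prod(h) / 8
  Ke <- matrix(0, 24, 24)
  Bsum <- matrix(0, 6, 24)
  for (q in seq_len(nrow(gp))) {
    B <- hexBMatrix(gp[q, 1], gp[q, 2], gp[q, 3], h)
    Ke <- Ke + t(B) %*% C %*% B * detJ
    Bsum <- Bsum + B
  }
  list(Ke = (Ke + t(Ke)) / 2, Bbar = Bsum / nrow(gp))
}

#' Build a conforming voxel hexahedral mesh
#'
#' One 8-node hexahedron per masked voxel; nodes deduplicated across shared
#' corners. Requires near-isotropic spacing (max/min ratio <= 1.5);
#' resample first otherwise (see [resampleVolume()]).
#'
#' @param mask binary [LabelMap-class].
#' @param groups group [LabelMap-class] from [materialGroups()] (or NULL for
#'   a homogeneous mesh, group 1 everywhere).
#' @param volume the [CTVolume-class] supplying geometry (or NULL to take
#'   geometry from `mask`).
#' @return a [VoxelMesh-class].
#' @export
buildMesh <- function(mask, groups = NULL, volume = NULL) {
  sp <- if (is.null(volume)) mask@spacing else volume@spacing
  or <- if (is.null(volume)) mask@origin else volume@origin
  if (max(sp) / min(sp) > 1.5)
    stop("voxel spacing ratio ", signif(max(sp) / min(sp), 3),
         " > 1.5; resample to near-isotropic spacing first", call. = FALSE)
  vox <- which(mask@labels > 0L, arr.ind = TRUE)
  if (nrow(vox) == 0L) stop("empty mask: nothing to mesh", call. = FALSE)
  d <- dim(mask@labels)
  nx1 <- d[1] + 1L; ny1 <- d[2] + 1L
  cornerId <- function(cx, cy, cz) cx + nx1 * (cy + ny1 * cz) + 1
  elems <- matrix(0, nrow(vox), 8)
  for (i in 1:8) {
    off <- (HEX_SIGNS[i, ] + 1) / 2          # 0 or 1
    elems[, i] <- cornerId(vox[, 1] - 1L + off[1], vox[, 2] - 1L + off[2],
                           vox[, 3] - 1L + off[3])
  }
  usedIds <- sort(unique(as.vector(elems)))
  remap <- integer(max(usedIds))
  remap[usedIds] <- seq_along(usedIds)
  elements <- matrix(remap[as.vector(elems)], nrow(vox), 8)
  storage.mode(elements) <- "integer"
  g0 <- usedIds - 1
  cz <- g0 %/% (nx1 * ny1)
  cy <- (g0 %% (nx1 * ny1)) %/% nx1
  cx <- g0 %% nx1
  nodes <- cbind(or[1] + (cx - 0.5) * sp[1],
                 or[2] + (cy - 0.5) * sp[2],
                 or[3] + (cz - 0.5) * sp[3])
  lin <- vox[, 1] + d[1] * (vox[, 2] - 1L) + d[1] * d[2] * (vox[, 3] - 1L)
  elemGroup <- if (is.null(groups)) rep(1L, nrow(vox)) else
    as.integer(groups@labels[lin])
  elemComp <- if (!is.null(groups) && !is.null(groups@channels$compartment))
    as.integer(groups@channels$compartment[lin]) else rep(1L, nrow(vox))
  new("VoxelMesh", nodes = nodes, elements = elements,
      elemGroup = elemGroup, elemCompartment = elemComp, spacing = sp)
}

elementDofMatrix <- function(elements) {
  n <- nrow(elements)
  dofm <- matrix(0L, n, 24)
  for (i in 1:8) {
    dofm[, 3 * i - 2] <- 3L * elements[, i] - 2L
    dofm[, 3 * i - 1] <- 3L * elements[, i] - 1L
    dofm[, 3 * i] <- 3L * elements[, i]
  }
  dofm
}

#' Assemble the global sparse stiffness system
#'
#' Element stiffness by 2x2x2 Gauss quadrature of B'CB over each hexahedron
#' (one stiffness per material group, since all voxels share the element
#' geometry), summed into a global sparse symmetric matrix with 3 DOF per
#' node. Only linear laws assemble; plastic and hyper-elastic cards are
#' material-point models here and must be linearized first.
#'
#' @param mesh a [VoxelMesh-class].
#' @param cards a [MaterialCardSet-class] with law "elastic" or
#'   "anisotropic" (every element group must have a card).
#' @return a list (class "FESystem") with the sparse stiffness `K`, the
#'   mesh, per-group 6x6 stiffnesses and centroid strain-displacement
#'   operator.
#' @export
assembleSystem <- function(mesh, cards) {
  if (!cards@law %in% c("elastic", "anisotropic"))
    stop("law '", cards@law,
         "' is material-point only; linearize first", call. = FALSE)
  ugr <- sort(unique(mesh@elemGroup))
  missing <- setdiff(as.character(ugr), names(cards@cards))
  if (length(missing))
    stop("no material card for group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ndof <- 3L * nrow(mesh@nodes)
  dofm <- elementDofMatrix(mesh@elements)
  iPat <- rep(1:24, times = 24)
  jPat <- rep(1:24, each = 24)
  Cmats <- list()
  Bbar <- NULL
  iAll <- vector("list", length(ugr))
  jAll <- vector("list", length(ugr))
  xAll <- vector("list", length(ugr))
  for (gi in seq_along(ugr)) {
    g <- ugr[gi]
    card <- cards@cards[[as.character(g)]]
    C <- assembleStiffness(card)
    ek <- hexElementStiffness(C, mesh@spacing)
    Cmats[[as.character(g)]] <- C
    Bbar <- ek$Bbar
    sel <- mesh@elemGroup == g
    dsel <- dofm[sel, , drop = FALSE]
    iAll[[gi]] <- as.vector(t(dsel[, iPat, drop = FALSE]))
    jAll[[gi]] <- as.vector(t(dsel[, jPat, drop = FALSE]))
    xAll[[gi]] <- rep(as.vector(ek$Ke), sum(sel))
  }
  K <- Matrix::sparseMatrix(i = unlist(iAll), j = unlist(jAll),
                            x = unlist(xAll), dims = c(ndof, ndof))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  structure(list(K = K, mesh = mesh, Cmats = Cmats, Bbar = Bbar,
                 cards = cards, ndof = ndof),
            class = "FESystem")
}

## face nodes of the mesh at the min/max extreme along `axis`
faceNodes <- function(mesh, axis, end = c("min", "max")) {
  end <- match.arg(end)
  coord <- mesh@nodes[, axis]
  target <- if (end == "min") min(coord) else max(coord)
  which(abs(coord - target) < 1e-9 + 1e-9 * abs(target))
}

## tributary weights on the extreme face: each element whose face lies on
## the plane contributes 1/4 to each of its 4 face corner nodes
tributaryWeights <- function(mesh, axis, end = "max") {
  fnodes <- faceNodes(mesh, axis, end)
  onFace <- logical(nrow(mesh@nodes))
  onFace[fnodes] <- TRUE
  w <- numeric(nrow(mesh@nodes))
  faceCorner <- onFace[mesh@elements]           # n x 8
  dim(faceCorner) <- dim(mesh@elements)
  hasFace <- rowSums(faceCorner) == 4L
  for (i in 1:8) {
    sel <- hasFace & faceCorner[, i]
    nd <- mesh@elements[sel, i]
    w[nd] <- w[nd] + 0.25
  }
  w
}

#' Define boundary conditions and a load pattern
#'
#' The distal end (minimum along the bone axis) is constrained; the proximal
#' face carries the axial load. `fixity = "fixed"` clamps all displacement
#' components of the distal face (the default, mirroring fixed femoral
#' condyles); `"rollers"` constrains only the axial component plus a minimal
#' lateral pinning, which admits the textbook uniform-stress state.
#' The load is distributed over the proximal face nodes either by tributary
#' area (equivalent to a uniform surface traction; default) or equally per
#' node.
#'
#' @param mesh a [VoxelMesh-class].
#' @param axis bone axis (1, 2 or 3; default 3 = z).
#' @param fixity "fixed" or "rollers".
#' @param totalForce signed total axial force in N (negative = compression
#'   along -axis); becomes the single entry of `forceScale`.
#' @param times time stamps for the steps (s).
#' @param distribution "tributary" or "uniform".
#' @return a [LoadCase-class]; its `loadVector` is the unit pattern (total
#'   axial force 1 N) and `forceScale` carries the newtons.
#' @export
loadCase <- function(mesh, axis = 3L, fixity = c("fixed", "rollers"),
                     totalForce = -100, times = 0,
                     distribution = c("tributary", "uniform")) {
  fixity <- match.arg(fixity)
  distribution <- match.arg(distribution)
  distal <- faceNodes(mesh, axis, "min")
  proximal <- faceNodes(mesh, axis, "max")
  if (length(intersect(distal, proximal)))
    stop("distal and proximal faces overlap: mesh too thin along the axis",
         call. = FALSE)
  if (fixity == "fixed") {
    fixedDofs <- as.integer(outer(c(-2L, -1L, 0L), 3L * distal, "+"))
  } else {
    lateral <- setdiff(1:3, axis)
    fixedDofs <- 3L * distal - (3L - axis)
    ctr <- colMeans(mesh@nodes[distal, , drop = FALSE])
    dist2 <- rowSums(sweep(mesh@nodes[distal, lateral, drop = FALSE], 2,
                           ctr[lateral])^2)
    pinA <- distal[which.min(dist2)]
    fixedDofs <- c(fixedDofs, 3L * pinA - (3L - lateral))
    dAlong1 <- abs(mesh@nodes[distal, lateral[1]] -
                   mesh@nodes[pinA, lateral[1]])
    pinB <- distal[which.max(dAlong1)]
    fixedDofs <- c(fixedDofs, 3L * pinB - (3L - lateral[2]))
    fixedDofs <- sort(unique(as.integer(fixedDofs)))
  }
  w <- if (distribution == "tributary") tributaryWeights(mesh, axis, "max")
       else { v <- numeric(nrow(mesh@nodes)); v[proximal] <- 1; v }
  w <- w / sum(w)
  f <- numeric(3L * nrow(mesh@nodes))
  f[3L * seq_len(nrow(mesh@nodes)) - (3L - axis)] <- w
  new("LoadCase", fixedDofs = sort(unique(fixedDofs)),
      fixedValues = numeric(length(unique(fixedDofs))),
      loadVector = f, forceScale = as.numeric(totalForce),
      times = as.numeric(times))
}

## Jacobi-preconditioned conjugate gradient
pcgSolve <- function(K, b, tol = 1e-8, maxit = 20000L) {
  Dinv <- 1 / Matrix::diag(K)
  x <- numeric(length(b))
  r <- b
  z <- Dinv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, iters = 0L, relres = 0))
  hist <- numeric(0)
  for (it in seq_len(maxit)) {
    Kp <- as.vector(K %*% p)
    alpha <- rz / sum(p * Kp)
    x <- x + alpha * p
    r <- r - alpha * Kp
    relres <- sqrt(sum(r^2)) / bnorm
    hist <- c(hist, relres)
    if (relres <= tol) return(list(x = x, iters = it, relres = relres))
    z <- Dinv * r
    rzNew <- sum(r * z)
    p <- z + (rzNew / rz) * p
    rz <- rzNew
  }
  stop("conjugate gradient did not converge in ", maxit,
       " iterations (last residuals: ",
       paste(signif(utils::tail(hist, 5), 3), collapse = ", "), ")",
       call. = FALSE)
}

#' Solve the assembled system for a load case
#'
#' Quasi-static solve: the unit spatial load pattern is solved once (direct
#' sparse Cholesky below `dofThreshold` free DOFs, Jacobi-preconditioned
#' conjugate gradient above, relative residual <= `tol`), then scaled by
#' each step's force. Element stresses are recovered at the centroid as
#' C B u averaged over the Gauss points.
#'
#' @param system an "FESystem" from [assembleSystem()].
#' @param loadcase a [LoadCase-class].
#' @param method "auto", "direct" or "cg".
#' @param tol relative residual tolerance for the iterative path.
#' @param dofThreshold free-DOF count above which "auto" switches to CG.
#' @return an [FEResult-class].
#' @export
solveSystem <- function(system, loadcase, method = c("auto", "direct", "cg"),
                        tol = 1e-8, dofThreshold = 150000L) {
  method <- match.arg(method)
  K <- system$K
  ndof <- system$ndof
  fixed <- loadcase@fixedDofs
  if (any(fixed < 1L) || any(fixed > ndof))
    stop("fixed DOF out of range", call. = FALSE)
  free <- setdiff(seq_len(ndof), fixed)
  Kff <- K[free, free, drop = FALSE]
  uFix <- loadcase@fixedValues
  rhsFix <- if (any(uFix != 0))
    as.vector(K[free, fixed, drop = FALSE] %*% uFix) else numeric(length(free))
  if (method == "auto")
    method <- if (length(free) <= dofThreshold) "direct" else "cg"
  solveFree <- if (method == "direct") {
    ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff),
                                    super = TRUE),
      error = function(e)
        stop("stiffness factorization failed (singular system? ",
             "insufficient constraints): ", conditionMessage(e),
             call. = FALSE))
    function(b) as.vector(Matrix::solve(ch, b))
  } else function(b) pcgSolve(Kff, b, tol = tol)$x
  fUnit <- loadcase@loadVector
  uUnit <- numeric(ndof)
  uUnit[free] <- solveFree(fUnit[free])
  u0 <- numeric(ndof)
  if (any(uFix != 0)) {
    u0[fixed] <- uFix
    u0[free] <- solveFree(-rhsFix)
  }
  nsteps <- length(loadcase@forceScale)
  mesh <- system$mesh
  nElem <- nrow(mesh@elements)
  dofm <- elementDofMatrix(mesh@elements)
  ugr <- sort(unique(mesh@elemGroup))
  ## element strain/stress for one displacement field
  recover <- function(u) {
    eps <- matrix(0, nElem, 6)
    sig <- matrix(0, nElem, 6)
    for (g in ugr) {
      sel <- mesh@elemGroup == g
      Ue <- matrix(u[t(dofm[sel, , drop = FALSE])], nrow = 24)
      epsG <- system$Bbar %*% Ue                   # 6 x n
      sigG <- system$Cmats[[as.character(g)]] %*% epsG
      eps[sel, ] <- t(epsG)
      sig[sel, ] <- t(sigG)
    }
    list(eps = eps, sig = sig)
  }
  ## linearity: every step is u0 + scale * uUnit, so recover both fields
  ## once and combine per step
  recUnit <- recover(uUnit)
  rec0 <- if (any(uFix != 0)) recover(u0) else NULL
  residUnit <- as.vector(K %*% uUnit) - fUnit
  resid0 <- if (!is.null(rec0)) as.vector(K %*% u0) else numeric(ndof)
  disp <- matrix(0, ndof, nsteps)
  stress <- vector("list", nsteps)
  strain <- vector("list", nsteps)
  vm <- matrix(0, nElem, nsteps)
  residuals <- numeric(nsteps)
  for (s in seq_len(nsteps)) {
    scale <- loadcase@forceScale[s]
    disp[, s] <- u0 + scale * uUnit
    resid <- scale * residUnit + resid0
    fn <- abs(scale) * sqrt(sum(fUnit[free]^2))
    residuals[s] <- if (fn > 0) sqrt(sum(resid[free]^2)) / fn else
      sqrt(sum(resid[free]^2))
    eps <- scale * recUnit$eps
    sig <- scale * recUnit$sig
    if (!is.null(rec0)) { eps <- eps + rec0$eps; sig <- sig + rec0$sig }
    strain[[s]] <- eps
    stress[[s]] <- sig
    vm[, s] <- vonMisesStress(sig)
  }
  maxVM <- apply(vm, 2, max)
  gStep <- which.max(maxVM)
  gElem <- which.max(vm[, gStep])
  new("FEResult", displacements = disp, stress = stress, strain = strain,
      vonMises = vm, maxVonMises = maxVM,
      globalMax = list(value = vm[gElem, gStep], element = gElem,
                       step = gStep),
      residuals = residuals, mesh = mesh)
}

#' Reaction forces at the fixed DOFs
#'
#' @param system an "FESystem".
#' @param result an [FEResult-class] from [solveSystem()].
#' @param loadcase the [LoadCase-class] solved.
#' @param step time step (default 1).
#' @return numeric vector of reactions (N) indexed like
#'   `loadcase@fixedDofs`.
#' @export
reactionForces <- function(system, result, loadcase, step = 1L) {
  u <- result@displacements[, step]
  f <- loadcase@forceScale[step] * loadcase@loadVector
  as.vector(system$K %*% u - f)[loadcase@fixedDofs]
}

#' Sweep a gait load curve through the factorized system
#'
#' Linear scaling of the unit-load solution by the force at each time step
#' of the gait curve (single factorization reused). Forces are applied
#' compressively along the negative bone axis.
#'
#' @param system an "FESystem".
#' @param gait data.frame with columns `time_s` and `force_N` (>= 2 rows).
#' @param loadcase the [LoadCase-class] defining faces and constraints.
#' @param ... passed to [solveSystem()].
#' @return an [FEResult-class] with one step per gait sample.
#' @export
gaitSweep <- function(system, gait, loadcase, ...) {
  if (!all(c("time_s", "force_N") %in% names(gait)))
    stop("gait curve needs columns time_s, force_N", call. = FALSE)
  if (nrow(gait) < 2L) stop("gait curve needs >= 2 steps", call. = FALSE)
  if (any(gait$time_s < 0)) stop("negative time steps", call. = FALSE)
  lc <- loadcase
  lc@forceScale <- -abs(gait$force_N)
  lc@times <- gait$time_s
  solveSystem(system, lc, ...)
}

#' Export FE results
#'
#' Writes a summary JSON (per-step and global max von Mises), a per-element
#' CSV (element id, centroid, group, Voigt stress, von Mises) for the
#' requested step, and a legacy-format VTK unstructured grid with the von
#' Mises field for visualization.
#'
#' @param result an [FEResult-class].
#' @param dir output directory.
#' @param step which step the element CSV/VTK reports (default: global max).
#' @return invisibly, the paths written.
#' @export
exportResults <- function(result, dir, step = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  step <- step %||% result@globalMax$step
  summaryPath <- file.path(dir, "fe_summary.json")
  jsonlite::write_json(list(
    max_von_mises_per_step = result@maxVonMises,
    times = seq_along(result@maxVonMises),
    global_max = result@globalMax,
    residuals = result@residuals), summaryPath,
    auto_unbox = TRUE, digits = NA)
  mesh <- result@mesh
  cent <- matrix(0, nrow(mesh@elements), 3)
  for (a in 1:3)
    cent[, a] <- rowMeans(matrix(mesh@nodes[mesh@elements, a],
                                 nrow(mesh@elements), 8))
  sig <- result@stress[[step]]
  csvPath <- file.path(dir, "elements.csv")
  utils::write.csv(data.frame(
    element = seq_len(nrow(sig)), x = cent[, 1], y = cent[, 2],
    z = cent[, 3], group = mesh@elemGroup,
    s11 = sig[, 1], s22 = sig[, 2], s33 = sig[, 3],
    s23 = sig[, 4], s31 = sig[, 5], s12 = sig[, 6],
    von_mises = result@vonMises[, step]), csvPath, row.names = FALSE)
  vtkPath <- file.path(dir, "mesh.vtk")
  writeVtkMesh(mesh, result@vonMises[, step], vtkPath)
  invisible(c(summaryPath, csvPath, vtkPath))
}

## legacy ASCII VTK unstructured grid (hexahedra, cell type 12)
writeVtkMesh <- function(mesh, cellField, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "voxbone mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(mesh@nodes))), con)
  utils::write.table(mesh@nodes, con, row.names = FALSE, col.names = FALSE)
  nE <- nrow(mesh@elements)
  ## VTK hexahedron ordering matches the element corner order used here
  writeLines(sprintf("CELLS %d %d", nE, 9 * nE), con)
  utils::write.table(cbind(8L, mesh@elements - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nE), con)
  writeLines(as.character(rep(12L, nE)), con)
  writeLines(c(sprintf("CELL_DATA %d", nE), "SCALARS von_mises double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format(cellField, digits = 10), con)
  invisible(path)
}
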