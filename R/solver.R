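# Displacement-controlled nonlinear voxel FE solver.
#
# Trilinear 8-node hexahedra with full 2x2x2 Gauss integration and one
# material point per element (the voxel). Nonlinearity is handled by
# deformation-theory secant iteration: each element's von Mises
# effective strain is mapped through the uniaxial four-region curve and
# the element modulus replaced by the secant value sigma(eps)/eps,
# floored to avoid singularity once elements soften fully. Monotone
# loading only; no unloading path is modelled.

# Gauss-point strain-displacement matrices and unit-modulus stiffness for
# a box element with edge lengths `h` (mm) and Poisson ratio `nu`.
.hexElement <- function(h, nu) {
  sg <- c(-1, 1, 1, -1, -1, 1, 1, -1)   # node xi signs (trilinear order)
  tg <- c(-1, -1, 1, 1, -1, -1, 1, 1)   # eta
  zg <- c(-1, -1, -1, -1, 1, 1, 1, 1)   # zeta

  Bat <- function(xi, eta, zeta) {
    dNdx <- sg * (1 + eta * tg) * (1 + zeta * zg) / 8 * (2 / h[1])
    dNdy <- tg * (1 + xi * sg) * (1 + zeta * zg) / 8 * (2 / h[2])
    dNdz <- zg * (1 + xi * sg) * (1 + eta * tg) / 8 * (2 / h[3])
    B <- matrix(0, 6, 24)
    ix <- seq(1, 24, by = 3)
    B[1, ix] <- dNdx
    B[2, ix + 1] <- dNdy
    B[3, ix + 2] <- dNdz
    B[4, ix] <- dNdy; B[4, ix + 1] <- dNdx
    B[5, ix + 1] <- dNdz; B[5, ix + 2] <- dNdy
    B[6, ix] <- dNdz; B[6, ix + 2] <- dNdx
    B
  }

  f <- 1 / ((1 + nu) * (1 - 2 * nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- nu * f
  diag(D)[1:3] <- (1 - nu) * f
  diag(D)[4:6] <- 1 / (2 * (1 + nu))

  g <- 1 / sqrt(3)
  detJ <- prod(h) / 8
  ke <- matrix(0, 24, 24)
  for (xi in c(-g, g)) for (eta in c(-g, g)) for (zeta in c(-g, g)) {
    B <- Bat(xi, eta, zeta)
    ke <- ke + t(B) %*% D %*% B * detJ
  }
  list(ke = ke, B0 = Bat(0, 0, 0), D = D)
}

# per-mesh precomputation: element dof table, assembly index vectors,
# unit stiffness
.femPrecompute <- function(mesh, nu) {
  el <- .hexElement(mesh@spacing, nu)
  elems <- mesh@elements
  m <- nrow(elems)
  edof <- matrix(0L, m, 24)
  for (a in 1:8) {
    edof[, 3 * a - 2] <- 3L * elems[, a] - 2L
    edof[, 3 * a - 1] <- 3L * elems[, a] - 1L
    edof[, 3 * a] <- 3L * elems[, a]
  }
  rowIdx <- rep(1:24, times = 24)
  colIdx <- rep(1:24, each = 24)
  list(ke = el$ke, keVec = as.vector(el$ke), B0 = el$B0, D = el$D,
       edof = edof, ii = edof[, rowIdx, drop = FALSE],
       jj = edof[, colIdx, drop = FALSE],
       ndof = 3L * nrow(mesh@nodes), elemVolume = prod(mesh@spacing))
}

.assembleK <- function(pre, Eelem) {
  vals <- Eelem * matrix(pre$keVec, nrow = length(Eelem), ncol = 576,
                         byrow = TRUE)
  Matrix::sparseMatrix(i = as.vector(pre$ii), j = as.vector(pre$jj),
                       x = as.vector(vals),
                       dims = c(pre$ndof, pre$ndof))
}

.nodeDofs <- function(nodes) as.vector(rbind(3L * nodes - 2L,
                                             3L * nodes - 1L,
                                             3L * nodes))

#' Linear elastic solve under prescribed displacements
#'
#' Solves K u = 0 on the free degrees of freedom with the given fixed
#' dofs held at the given values, and returns the displacement and
#' reaction vectors. Exposed for solver validation (patch tests, energy
#' checks).
#'
#' @param mesh A [HexMesh-class].
#' @param Eelem Elastic modulus per element, MPa.
#' @param nu Poisson ratio.
#' @param fixedDofs Integer dof indices (dofs are node-major x,y,z).
#' @param fixedValues Prescribed displacements, mm, aligned with
#'   `fixedDofs`.
#' @return List with `u` (ndof displacements), `reactions` (K u, N),
#'   and `strainEnergy` (N mm) from element centroid strains.
#' @export
elasticSolve <- function(mesh, Eelem, nu = 0.3, fixedDofs, fixedValues) {
  pre <- .femPrecompute(mesh, nu)
  Eelem <- rep_len(Eelem, nrow(mesh@elements))
  K <- .assembleK(pre, Eelem)
  u <- numeric(pre$ndof)
  u[fixedDofs] <- fixedValues
  free <- setdiff(seq_len(pre$ndof), fixedDofs)
  if (length(free)) {
    b <- -K[free, fixedDofs, drop = FALSE] %*% fixedValues
    Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
    ch <- tryCatch(suppressWarnings(Matrix::Cholesky(Kff)),
                   error = function(e) stop(
                     "singular system: check that the constrained node sets ",
                     "connect all components", call. = FALSE))
    u[free] <- as.numeric(Matrix::solve(ch, b))
  }
  eps <- elementStrains(mesh, u, pre = pre)
  sig <- eps %*% pre$D                    # unit-modulus stress
  en <- 0.5 * sum(Eelem * rowSums(eps * sig)) * pre$elemVolume
  list(u = u, reactions = as.numeric(K %*% u), strainEnergy = en)
}

#' Element centroid strains from a displacement vector
#'
#' @param mesh A [HexMesh-class].
#' @param u Displacement vector (3 dofs per node, node-major).
#' @param pre Internal precomputation (optional).
#' @return m x 6 matrix of engineering strains
#'   (exx, eyy, ezz, gxy, gyz, gzx).
#' @export
elementStrains <- function(mesh, u, pre = NULL) {
  if (is.null(pre)) pre <- .femPrecompute(mesh, 0.3)
  Ue <- matrix(u[pre$edof], nrow = nrow(pre$edof))
  Ue %*% t(pre$B0)
}

#' Construct solver settings
#'
#' @param displacementIncrement mm of additional head displacement per
#'   load step.
#' @param maxSteps Maximum number of increments.
#' @param secantTol Relative reaction-force change below which the
#'   secant loop is converged.
#' @param maxSecantIters Secant iteration cap per step.
#' @param dropFraction Terminate once the reaction force falls below
#'   (1 - dropFraction) of the running maximum ("began to decrease",
#'   made robust to float noise).
#' @param minModulusRatio Secant-modulus floor as a fraction of the
#'   initial elastic modulus.
#' @return A [SolveConfig-class].
#' @export
solveConfig <- function(displacementIncrement = 0.25, maxSteps = 30,
                        secantTol = 1e-3, maxSecantIters = 80,
                        dropFraction = 0.02, minModulusRatio = 1e-4) {
  new("SolveConfig", displacementIncrement = displacementIncrement,
      maxSteps = maxSteps, secantTol = secantTol,
      maxSecantIters = maxSecantIters, dropFraction = dropFraction,
      minModulusRatio = minModulusRatio)
}

#' Solve for hip load capacity under incremental head displacement
#'
#' Prescribes rigid displacement increments of the head-cap node set
#' along the mesh's load direction with the distal face fully fixed,
#' iterating the element secant moduli to convergence at each step. The
#' reaction force is the total constraint force on the head cap resolved
#' along the load direction; loading stops when the force has dropped by
#' the configured fraction from its running maximum (or at the step
#' cap), and the load capacity is the maximum reaction force.
#'
#' @param mesh A [HexMesh-class].
#' @param material A [MaterialModel-class].
#' @param cfg A [SolveConfig-class].
#' @param label Configuration label stored in the result.
#' @return An [FEResult-class].
#' @export
#' @examples
#' mesh <- blockMesh(c(1, 1, 1), density = 0.5)
#' res <- solveLoadCapacity(mesh,
#'   materialModel(residualFraction = 1, poisson = 0),
#'   solveConfig(displacementIncrement = 0.002, maxSteps = 8))
#' loadCapacity(res)
solveLoadCapacity <- function(mesh, material, cfg = solveConfig(),
                              label = "custom") {
  stopifnot(is(mesh, "HexMesh"), is(material, "MaterialModel"),
            is(cfg, "SolveConfig"))
  pre <- .femPrecompute(mesh, material@poisson)
  rho <- mesh@elementDensity
  cv <- materialCurveAt(material, rho)
  E0 <- pmax(cv$E, 1e-9)
  Efloor <- cfg@minModulusRatio * E0

  head <- mesh@nodeSets$headSurface
  distal <- mesh@nodeSets$distalFace
  fixedDofs <- c(.nodeDofs(head), .nodeDofs(distal))
  free <- setdiff(seq_len(pre$ndof), fixedDofs)
  dirv <- mesh@loadDirection

  Esec <- E0
  u <- numeric(pre$ndof)
  disp <- numeric(0); forces <- numeric(0)
  maxF <- -Inf; reason <- "max_steps"; nonconv <- FALSE
  ch <- NULL

  for (step in seq_len(cfg@maxSteps)) {
    d <- step * cfg@displacementIncrement
    fixedVals <- c(rep(dirv * d, length(head)), numeric(3 * length(distal)))
    Fprev <- NA_real_; F <- NA_real_; converged <- FALSE
    for (it in seq_len(cfg@maxSecantIters)) {
      K <- .assembleK(pre, Esec)
      u[fixedDofs] <- fixedVals
      if (length(free)) {
        b <- -K[free, fixedDofs, drop = FALSE] %*% fixedVals
        Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
        ch <- tryCatch(suppressWarnings({
          if (is.null(ch)) Matrix::Cholesky(Kff) else Matrix::update(ch, Kff)
        }), error = function(e) tryCatch(suppressWarnings(Matrix::Cholesky(Kff)),
          error = function(e2) stop(
            "singular system: check that headSurface/distalFace constrain ",
            "all rigid modes", call. = FALSE)))
        u[free] <- as.numeric(Matrix::solve(ch, b))
      }
      r <- matrix(as.numeric(K %*% u), nrow = 3)
      F <- sum(dirv * r[, head, drop = FALSE])
      eps <- matrix(u[pre$edof], nrow = nrow(pre$edof)) %*% t(pre$B0)
      eff <- vonMisesStrain(eps, material@poisson)
      sig <- uniaxialStress(material, rho, eff)
      Enew <- ifelse(eff > 1e-12, pmax(sig / eff, Efloor), E0)
      # under-relax late iterations: softening elements can otherwise
      # oscillate between two states; the fixed point is unchanged
      Esec <- if (it > 6) 0.7 * Enew + 0.3 * Esec else Enew
      if (is.finite(Fprev) &&
          abs(F - Fprev) <= cfg@secantTol * max(abs(F), 1e-9)) {
        converged <- TRUE
        break
      }
      Fprev <- F
    }
    if (!converged) nonconv <- TRUE
    disp <- c(disp, d); forces <- c(forces, F)
    if (F > maxF) maxF <- F
    if (F < (1 - cfg@dropFraction) * maxF) {
      reason <- "force_drop"
      break
    }
  }
  if (nonconv) {
    warning("secant iteration did not converge at one or more steps")
    reason <- "non_convergent"
  }
  new("FEResult", displacements = disp, reactionForces = forces,
      loadCapacity = max(forces), stoppedReason = reason,
      configuration = label)
}

#' Run a full loading configuration on a calibrated volume
#'
#' Convenience composition of [buildMesh()] and [solveLoadCapacity()]
#' with the configuration-specific load direction: nonlinear single-limb
#' stance (NLS) or nonlinear posterolateral fall (NLF).
#'
#' @param volume Calibrated [QCTVolume-class].
#' @param configuration "NLS" or "NLF".
#' @param material A [MaterialModel-class].
#' @param cfg A [SolveConfig-class].
#' @param ... Passed to [buildMesh()] (threshold, angles).
#' @return An [FEResult-class] labelled with the configuration.
#' @export
runConfiguration <- function(volume, configuration = c("NLS", "NLF"),
                             material = materialModel(),
                             cfg = solveConfig(), ...) {
  configuration <- match.arg(configuration)
  mesh <- buildMesh(volume, configuration = configuration, ...)
  solveLoadCapacity(mesh, material, cfg, label = configuration)
}
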