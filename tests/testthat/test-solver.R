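test_that("single-element bar follows the elastic line then the plastic plateau", {
  mat <- materialModel(residualFraction = 1, poisson = 0)  # elastic-plastic
  rho <- 0.5
  cv <- materialCurveAt(mat, rho)
  A <- 4; h <- 1                                  # 2x2x1 mm element
  mesh <- blockMesh(c(1, 1, 1), spacing = c(2, 2, 1), density = rho)
  cfg <- solveConfig(displacementIncrement = 0.001, maxSteps = 12,
                     dropFraction = 0.5)
  res <- solveLoadCapacity(mesh, mat, cfg)
  fd <- forceDisplacement(res)
  elastic <- fd$displacement_mm / h < cv$epsYield
  expect_equal(fd$force_N[elastic],
               cv$E * A * fd$displacement_mm[elastic] / h, tolerance = 1e-9)
  expect_equal(loadCapacity(res), cv$sy * A, tolerance = 1e-6)
  expect_equal(fd$force_N[!elastic], rep(cv$sy * A, sum(!elastic)),
               tolerance = 1e-6)
})

test_that("softening drops the force and triggers the stop rule at peak", {
  mat <- materialModel(residualFraction = 0.3, poisson = 0)
  rho <- 0.5
  cv <- materialCurveAt(mat, rho)
  mesh <- blockMesh(c(1, 1, 1), spacing = c(2, 2, 1), density = rho)
  res <- solveLoadCapacity(mesh, mat,
                           solveConfig(displacementIncrement = 0.001,
                                       maxSteps = 25, dropFraction = 0.02))
  expect_identical(res@stoppedReason, "force_drop")
  expect_equal(loadCapacity(res), cv$sy * 4, tolerance = 1e-6)
  fd <- forceDisplacement(res)
  expect_lt(fd$force_N[nrow(fd)], loadCapacity(res))
})

test_that("two elements in series match one element and halve the strain", {
  mat <- materialModel(residualFraction = 0.3, poisson = 0)
  rho <- 0.5
  cv <- materialCurveAt(mat, rho)
  mesh2 <- blockMesh(c(1, 1, 2), spacing = c(2, 2, 1), density = rho)
  res2 <- solveLoadCapacity(mesh2, mat,
                            solveConfig(displacementIncrement = 0.002,
                                        maxSteps = 25, dropFraction = 0.02))
  expect_equal(loadCapacity(res2), cv$sy * 4, tolerance = 1e-6)
  # elastic strain check: total displacement splits equally over the bar
  d <- 0.002
  sol <- elasticSolve(mesh2, Eelem = cv$E, nu = 0,
                      fixedDofs = c(hipFE:::.nodeDofs(mesh2@nodeSets$headSurface),
                                    hipFE:::.nodeDofs(mesh2@nodeSets$distalFace)),
                      fixedValues = c(rep(c(0, 0, -d),
                                          length(mesh2@nodeSets$headSurface)),
                                      numeric(3 * length(mesh2@nodeSets$distalFace))))
  eps <- elementStrains(mesh2, sol$u)
  expect_equal(eps[, 3], rep(-d / 2, 2), tolerance = 1e-10)
})

test_that("patch test: linear boundary displacement gives uniform strain and energy balance", {
  mesh <- blockMesh(c(3, 3, 3), spacing = c(1, 1, 1), density = 1)
  E <- 12000; nu <- 0.3
  a <- -2e-3; b <- 1e-3; c3 <- -1e-3     # target strains exx, eyy, ezz
  nd <- mesh@nodes
  onBoundary <- which(
    nd[, 1] %in% range(nd[, 1]) | nd[, 2] %in% range(nd[, 2]) |
      nd[, 3] %in% range(nd[, 3]))
  fixedDofs <- hipFE:::.nodeDofs(onBoundary)
  uB <- t(vapply(onBoundary, function(i)
    c(a * nd[i, 1], b * nd[i, 2], c3 * nd[i, 3]), numeric(3)))
  sol <- elasticSolve(mesh, E, nu, fixedDofs, as.vector(t(uB)))
  eps <- elementStrains(mesh, sol$u)
  target <- c(a, b, c3, 0, 0, 0)
  for (k in 1:6)
    expect_equal(unname(eps[, k]), rep(target[k], nrow(eps)),
                 tolerance = 1e-10)
  # reaction on the top face equals the analytic uniform stress * area
  f <- 1 / ((1 + nu) * (1 - 2 * nu))
  sigZ <- E * f * ((1 - nu) * c3 + nu * (a + b))
  topDofsZ <- 3 * which(nd[, 3] == max(nd[, 3]))
  expect_equal(sum(sol$reactions[topDofsZ]), sigZ * 9, tolerance = 1e-8)
  # external work on constrained dofs equals stored strain energy
  W <- 0.5 * sum(sol$reactions[fixedDofs] * as.vector(t(uB)))
  expect_equal(W, sol$strainEnergy, tolerance = 1e-9)
})

test_that("capacity is invariant to rigid translation and solver reruns", {
  mat <- materialModel(poisson = 0.3)
  mesh <- blockMesh(c(2, 2, 3), spacing = c(1, 1, 1), density = 0.4)
  cfg <- solveConfig(displacementIncrement = 0.005, maxSteps = 20,
                     dropFraction = 0.02)
  r1 <- solveLoadCapacity(mesh, mat, cfg)
  shifted <- mesh
  shifted@nodes <- sweep(mesh@nodes, 2, c(13.5, -7.25, 101), `+`)
  r2 <- solveLoadCapacity(shifted, mat, cfg)
  r3 <- solveLoadCapacity(mesh, mat, cfg)
  expect_equal(loadCapacity(r1), loadCapacity(r2), tolerance = 1e-12)
  expect_identical(forceDisplacement(r1), forceDisplacement(r3))
})

test_that("mesh refinement leaves the bar capacity essentially unchanged", {
  mat <- materialModel(residualFraction = 1, poisson = 0)
  rho <- 0.5
  coarse <- blockMesh(c(1, 1, 2), spacing = c(2, 2, 1), density = rho)
  fine <- blockMesh(c(2, 2, 4), spacing = c(1, 1, 0.5), density = rho)
  cfg <- solveConfig(displacementIncrement = 0.002, maxSteps = 15,
                     dropFraction = 0.5)
  cCoarse <- loadCapacity(solveLoadCapacity(coarse, mat, cfg))
  cFine <- loadCapacity(solveLoadCapacity(fine, mat, cfg))
  expect_lt(abs(cFine - cCoarse) / cCoarse, 0.02)
})

test_that("a stiffness-free system raises a singular-system error", {
  mesh <- blockMesh(c(2, 2, 2), spacing = c(1, 1, 1), density = 0.5)
  bottom <- mesh@nodeSets$distalFace
  fd <- hipFE:::.nodeDofs(bottom)
  expect_error(
    elasticSolve(mesh, 0, 0.3, fixedDofs = fd,
                 fixedValues = numeric(length(fd))),
    "singular")
})
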