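test_that("phantom rods reproduce the scanner forward model exactly when noiseless", {
  v <- noiselessVolume()   # huSlope 1.5, huIntercept -20, noiseSD 0
  expect_length(phantomROIs(v), 3L)
  noms <- vapply(phantomROIs(v), `[[`, numeric(1), "nominal")
  expect_equal(noms, c(0, 75, 150))
  for (roi in phantomROIs(v)) {
    expect_equal(mean(voxelGrid(v)[roi$indices]),
                 1.5 * roi$nominal - 20, tolerance = 1e-12)
  }
})

test_that("volume generation is deterministic and noise is seed-controlled", {
  sc <- scannerModel(huSlope = 1.2, huIntercept = -15, noiseSD = 5)
  a <- generateVolume(subjectParams(), sc, voxelMM = 5, seed = 42)
  b <- generateVolume(subjectParams(), sc, voxelMM = 5, seed = 42)
  c <- generateVolume(subjectParams(), sc, voxelMM = 5, seed = 43)
  expect_identical(voxelGrid(a), voxelGrid(b))
  expect_false(identical(voxelGrid(a), voxelGrid(c)))
})

test_that("zero-density subject is indistinguishable from background", {
  p <- subjectParams(corticalDensity = 0, trabecularDensity = 0)
  v <- generateVolume(p, scannerModel(huSlope = 2, huIntercept = 30),
                      voxelMM = 5, seed = 1)
  bone <- landmarks(v)$boneMask
  expect_true(all(voxelGrid(v)[bone] == 30))   # intercept only
})

test_that("too-coarse voxels raise a degenerate-geometry error", {
  expect_error(generateVolume(subjectParams(), scannerModel(), voxelMM = 8),
               "degenerate geometry")
})

test_that("cohort sampling recovers the configured truncated-normal moments", {
  n <- 2000
  coh <- generateCohort("AGES_fractured", n = n, seed = 5)
  expect_length(coh, n)
  age <- vapply(coh, function(p) p@age, numeric(1))
  # analytic mean of N(80.3, 5.7) truncated to [71, 93]
  a <- (71 - 80.3) / 5.7; b <- (93 - 80.3) / 5.7
  z <- pnorm(b) - pnorm(a)
  truncMean <- 80.3 + 5.7 * (dnorm(a) - dnorm(b)) / z
  expect_lt(abs(mean(age) - truncMean), 3 * 5.7 / sqrt(n))
  expect_lt(abs(sd(age) - 5.7) / 5.7, 0.15)
  expect_true(all(age >= 71 & age <= 93))
  # fractured spec shifts density means down relative to non-fractured
  cohNF <- generateCohort("AGES_nonfractured", n = n, seed = 5)
  trabF <- vapply(coh, function(p) p@trabecularDensity, numeric(1))
  trabNF <- vapply(cohNF, function(p) p@trabecularDensity, numeric(1))
  expect_lt(mean(trabF), mean(trabNF))
})

test_that("different seeds give different draws with matching distributions", {
  n <- 2000
  a <- vapply(generateCohort("Mayo_male", n = n, seed = 1),
              function(p) p@age, numeric(1))
  b <- vapply(generateCohort("Mayo_male", n = n, seed = 2),
              function(p) p@age, numeric(1))
  expect_false(identical(a, b))
  expect_gt(t.test(a, b)$p.value, 1e-4)
})

test_that("cohort edge cases: n = 0 and invalid n", {
  expect_identical(generateCohort("astronaut", n = 0), list())
  expect_error(generateCohort("astronaut", n = -1), "non-negative")
  expect_error(generateCohort("nope", n = 3), "unknown cohort")
})

test_that("flight effect: identity at zero duration, compartment ordering, log-linearity", {
  p <- subjectParams()
  expect_identical(applyFlightEffect(p, duration = 0), p)

  post <- applyFlightEffect(p, duration = 154, seed = 3)
  relTrab <- 1 - post@trabecularDensity / p@trabecularDensity
  relCort <- 1 - post@corticalDensity / p@corticalDensity
  expect_gt(relTrab, relCort)   # trabecular loss outpaces cortical

  # doubling duration doubles log-scale loss at zero noise
  p1 <- applyFlightEffect(p, duration = 100, noiseSD = 0)
  p2 <- applyFlightEffect(p, duration = 200, noiseSD = 0)
  expect_equal(log(p2@trabecularDensity / p@trabecularDensity),
               2 * log(p1@trabecularDensity / p@trabecularDensity),
               tolerance = 1e-12)
  expect_error(applyFlightEffect(p, lossModel = list(trabecular = -1,
                                                     cortical = 1),
                                 duration = 10), "allowGain")
})

test_that("DXA projection has the closed-form value on a uniform box", {
  # 500 mg/cc over 4 voxels of 2 mm along axis 2 -> aBMD = 0.5 * 0.8 g/cm^2
  v <- boxVolume(dims = c(10, 4, 10), spacing = c(2, 2, 2), density = 500)
  d <- projectDXA(v, axis = 2, refMean = 0.40, refSD = 0.1,
                  mask = array(TRUE, dim(voxelGrid(v))))
  expect_equal(aBMD(d), 0.5 * 0.8, tolerance = 1e-12)
  expect_equal(tScore(d), 0)   # aBMD equals the reference mean
})

test_that("DXA projection is linear in density for a fixed mask", {
  v <- calibratedFemur()
  mask <- landmarks(v)$boneMask
  d1 <- projectDXA(v, refMean = 1, refSD = 0.2, mask = mask)
  v2 <- v; v2@grid <- 2 * v@grid
  d2 <- projectDXA(v2, refMean = 1, refSD = 0.2, mask = mask)
  expect_equal(aBMD(d2), 2 * aBMD(d1), tolerance = 1e-12)
  expect_equal(tScore(d2) - tScore(d1), aBMD(d1) / 0.2, tolerance = 1e-9)
  expect_error(projectDXA(v, mask = integer(0)), "empty")
  expect_error(projectDXA(noiselessVolume()), "calibrated")
})

test_that("record cohorts reproduce anchored marginals and correlations", {
  n <- 4000
  r <- generateRecordCohort("Mayo_male", n = n, seed = 9)
  expect_lt(abs(mean(r$f_nls) - 11416), 3 * 2816 / sqrt(n) + 150)
  expect_gt(cor(r$t_score, r$f_nls)^2, 0.6)   # configured R^2 ~ 0.77
  ast <- generateRecordCohort("astronaut", seed = 2)
  expect_identical(nrow(ast), 8L)
  expect_true(all(c("f_nls_post", "t_score_post", "flight_days")
                  %in% names(ast)))
  expect_true(all(ast$f_nls >= 10030 & ast$f_nls <= 22072))
})
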