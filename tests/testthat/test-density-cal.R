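# helper: calibrated volume with chosen ROI mean values
volWithROIMeans <- function(meansHU, nominal, calibrated = FALSE,
                            scanner = "A") {
  g <- array(0, dim = c(6, 6, length(meansHU)))
  rois <- lapply(seq_along(meansHU), function(k) {
    idx <- which(slice.index(g, 3) == k)
    g[idx] <<- meansHU[k]
    list(indices = idx, nominal = nominal[k])
  })
  new("QCTVolume", grid = g, spacing = c(1, 1, 1), calibrated = calibrated,
      phantomROIs = rois, scannerID = scanner, landmarks = list())
}

test_that("noiseless phantom fit inverts the scanner map exactly", {
  v <- noiselessVolume()   # HU = 1.5 * density - 20
  fit <- fitPhantomCalibration(v)
  expect_equal(fit@slope, 1 / 1.5, tolerance = 1e-12)
  expect_equal(fit@intercept, 20 / 1.5, tolerance = 1e-9)
  expect_equal(fit@rSquared, 1, tolerance = 1e-12)
})

test_that("fit matches hand-computed OLS on three collinear rods", {
  v <- volWithROIMeans(c(10, 85, 160), c(0, 75, 150))
  fit <- fitPhantomCalibration(v)
  expect_equal(fit@slope, 1.0, tolerance = 1e-12)
  expect_equal(fit@intercept, -10.0, tolerance = 1e-12)
})

test_that("degenerate phantoms are rejected", {
  expect_error(fitPhantomCalibration(
    volWithROIMeans(c(10, 85), c(75, 75))), "insufficient phantom")
  expect_error(fitPhantomCalibration(
    volWithROIMeans(c(50, 50), c(0, 75))), "degenerate fit")
})

test_that("applying a calibration maps voxels affinely and flags the volume", {
  v <- noiselessVolume()
  idFit <- new("CalibrationFit", slope = 1, intercept = 0, rSquared = 1,
               rodTable = data.frame(nominal = c(0, 75), meanHU = c(0, 75)))
  expect_equal(voxelGrid(applyCalibration(v, idFit)), voxelGrid(v))

  cal <- applyCalibration(v, fitPhantomCalibration(v))
  expect_true(isCalibrated(cal))
  for (roi in phantomROIs(cal))
    expect_equal(mean(voxelGrid(cal)[roi$indices]), roi$nominal,
                 tolerance = 1e-9)
  expect_error(applyCalibration(cal, idFit), "already calibrated")
})

test_that("calibration composes with an affine rescan of the same scene", {
  v <- noiselessVolume()
  v2 <- v; v2@grid <- 0.5 * v@grid + 100   # same scene, different scanner map
  f1 <- fitPhantomCalibration(v)
  f2 <- fitPhantomCalibration(v2)
  expect_equal(voxelGrid(applyCalibration(v, f1)),
               voxelGrid(applyCalibration(v2, f2)), tolerance = 1e-8)
})

test_that("cross-calibration recovers an affine scanner discrepancy", {
  v <- noiselessVolume()
  calA <- applyCalibration(v, fitPhantomCalibration(v))
  calB <- calA
  calB@grid <- 1.1 * calA@grid + 5     # scanner B reports 1.1*rho + 5
  calB@scannerID <- "B"
  # B's rod ROI means no longer equal nominals: B mis-calibrates by the
  # affine discrepancy; regressing region means recovers the inverse map
  xc <- fitCrossCalibration(calA, calB)
  expect_equal(xc@slope, 1 / 1.1, tolerance = 0.01)
  expect_equal(xc@intercept, -5 / 1.1, tolerance = 0.05)
  back <- applyCrossCalibration(calB, xc)
  expect_identical(scannerID(back), scannerID(calA))
  rms <- sqrt(mean((voxelGrid(back) - voxelGrid(calA))^2))
  expect_lt(rms, 1e-8)
  # identity pair
  xcId <- fitCrossCalibration(calA, calA)
  expect_equal(xcId@slope, 1, tolerance = 1e-9)
  expect_equal(xcId@intercept, 0, tolerance = 1e-6)
  expect_error(applyCrossCalibration(calA, xc), "scanner mismatch")
})

test_that("cross-calibration error shrinks as regions are added (OLS consistency)", {
  # already-calibrated synthetic pair: scanner B reports 1.1*rho + 5 with
  # independent voxel noise on both scanners; region means then scatter
  # independently about the affine map, so more regions = smaller error
  trueRho <- seq(50, 1000, length.out = 12)
  nvox <- 8                          # small regions keep mean-noise visible
  regionIdx <- split(seq_len(12 * nvox), rep(1:12, each = nvox))
  mkVol <- function(vals, id) {
    rois <- lapply(1:3, function(k)
      list(indices = regionIdx[[k]], nominal = trueRho[k]))
    new("QCTVolume", grid = array(vals, c(12 * nvox, 1, 1)),
        spacing = c(1, 1, 1), calibrated = TRUE, phantomROIs = rois,
        scannerID = id, landmarks = list())
  }
  set.seed(55)
  errs <- replicate(30, {
    base <- rep(trueRho, each = nvox)
    vA <- mkVol(base + rnorm(length(base), 0, 60), "A")
    vB <- mkVol(1.1 * (base + rnorm(length(base), 0, 60)) + 5, "B")
    few <- fitCrossCalibration(vA, vB)
    many <- fitCrossCalibration(vA, vB,
                                extraRegions = regionIdx[4:12])
    c(abs(few@slope - 1 / 1.1), abs(many@slope - 1 / 1.1))
  })
  expect_lt(mean(errs[2, ]), mean(errs[1, ]))
})

test_that("DXA manufacturer cross-calibration is affine and monotone", {
  cal <- dxaCrossCal(slope = 0.91, intercept = 0.02)
  expect_equal(dxaCrossCalibrate(1.00, cal), 0.93, tolerance = 1e-12)
  expect_equal(dxaCrossCalibrate(0.8, dxaCrossCal()), 0.8)
  expect_lt(dxaCrossCalibrate(0.9, cal), dxaCrossCalibrate(1.1, cal))
  expect_error(dxaCrossCalibrate(-0.1, cal), "non-negative")
})
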