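# Phantom-based HU -> equivalent-density calibration and scanner /
# DXA cross-calibration. All maps are affine; regression direction is
# nominal density on observed HU because the rod densities are exact.

#' Fit the in-field phantom calibration
#'
#' Ordinary least squares of the nominal rod densities (mg/cc) on the
#' observed rod-ROI mean HU values. The fitted affine map converts HU to
#' equivalent mineral density.
#'
#' @param volume Uncalibrated [QCTVolume-class] with at least two phantom
#'   ROIs of distinct nominal density.
#' @return A [CalibrationFit-class].
#' @export
#' @examples
#' vol <- generateVolume(subjectParams(), scannerModel(huSlope = 1.5,
#'   huIntercept = -20), voxelMM = 5, seed = 1)
#' fitPhantomCalibration(vol)
fitPhantomCalibration <- function(volume) {
  stopifnot(is(volume, "QCTVolume"))
  rois <- volume@phantomROIs
  nominal <- vapply(rois, `[[`, numeric(1), "nominal")
  if (length(unique(nominal)) < 2L)
    stop("insufficient phantom: need >= 2 distinct rod densities",
         call. = FALSE)
  meanHU <- vapply(rois, function(r) mean(volume@grid[r$indices]), numeric(1))
  if (max(meanHU) - min(meanHU) < 1e-12)
    stop("degenerate fit: zero HU variance across rods", call. = FALSE)
  fit <- stats::lm(nominal ~ meanHU)
  ssTot <- sum((nominal - mean(nominal))^2)
  r2 <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot else 1
  new("CalibrationFit",
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      rSquared = min(max(r2, 0), 1),
      rodTable = data.frame(nominal = nominal, meanHU = meanHU))
}

#' Apply a phantom calibration to a volume
#'
#' Maps every voxel affinely from HU to equivalent density (mg/cc) and
#' sets the calibrated flag.
#'
#' @param volume Uncalibrated [QCTVolume-class].
#' @param fit A [CalibrationFit-class].
#' @return Calibrated [QCTVolume-class].
#' @export
applyCalibration <- function(volume, fit) {
  stopifnot(is(volume, "QCTVolume"), is(fit, "CalibrationFit"))
  if (volume@calibrated)
    stop("volume is already calibrated", call. = FALSE)
  out <- volume
  out@grid <- fit@slope * volume@grid + fit@intercept
  out@calibrated <- TRUE
  out
}

#' Fit a scanner-to-scanner density cross-calibration
#'
#' Both volumes must be calibrated on their own scanners and image the
#' same physical phantom regions. Region-mean calibrated densities on the
#' reference scanner A are regressed on those of scanner B, yielding the
#' affine map that carries B's density scale onto A's. Region means are
#' used rather than raw voxels to suppress noise.
#'
#' @param phantomOnA,phantomOnB Calibrated [QCTVolume-class] objects of
#'   the same phantom on the reference (A) and source (B) scanners.
#' @param extraRegions Optional list of further same-grid region index
#'   vectors (for example femur compartments of a designated synthetic
#'   subject) appended to the phantom rods.
#' @return A [CrossCalibration-class] mapping B onto A's scale.
#' @export
fitCrossCalibration <- function(phantomOnA, phantomOnB,
                                extraRegions = NULL) {
  stopifnot(is(phantomOnA, "QCTVolume"), is(phantomOnB, "QCTVolume"))
  if (!phantomOnA@calibrated || !phantomOnB@calibrated)
    stop("both volumes must be calibrated on their own scanners",
         call. = FALSE)
  nomA <- vapply(phantomOnA@phantomROIs, `[[`, numeric(1), "nominal")
  nomB <- vapply(phantomOnB@phantomROIs, `[[`, numeric(1), "nominal")
  shared <- intersect(nomA, nomB)
  if (length(shared) < 2L)
    stop("non-overlapping phantom region sets", call. = FALSE)
  mA <- vapply(shared, function(d) {
    i <- which(nomA == d)[1]
    mean(phantomOnA@grid[phantomOnA@phantomROIs[[i]]$indices])
  }, numeric(1))
  mB <- vapply(shared, function(d) {
    i <- which(nomB == d)[1]
    mean(phantomOnB@grid[phantomOnB@phantomROIs[[i]]$indices])
  }, numeric(1))
  if (!is.null(extraRegions)) {
    mA <- c(mA, vapply(extraRegions, function(ix)
      mean(phantomOnA@grid[ix]), numeric(1)))
    mB <- c(mB, vapply(extraRegions, function(ix)
      mean(phantomOnB@grid[ix]), numeric(1)))
  }
  fit <- stats::lm(mA ~ mB)
  new("CrossCalibration",
      sourceScannerID = phantomOnB@scannerID,
      targetScannerID = phantomOnA@scannerID,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]))
}

#' Apply a cross-calibration at the voxel level
#'
#' @param volume Calibrated [QCTVolume-class] from the cross-calibration's
#'   source scanner.
#' @param xcal A [CrossCalibration-class].
#' @return Volume on the target scanner's density scale, with the
#'   scanner ID rewritten.
#' @export
applyCrossCalibration <- function(volume, xcal) {
  stopifnot(is(volume, "QCTVolume"), is(xcal, "CrossCalibration"))
  if (volume@scannerID != xcal@sourceScannerID)
    stop("scanner mismatch: volume is from '", volume@scannerID,
         "' but cross-calibration expects '", xcal@sourceScannerID, "'",
         call. = FALSE)
  out <- volume
  out@grid <- xcal@slope * volume@grid + xcal@intercept
  out@scannerID <- xcal@targetScannerID
  out
}

#' Construct a DXA manufacturer cross-calibration
#'
#' The published conversion equations between densitometer manufacturers
#' are configuration here (they are not re-derived); the default is the
#' identity.
#'
#' @param sourceModel,targetModel character labels.
#' @param slope Dimensionless (> 0); \code{intercept} g/cm^2.
#' @return A [DXACrossCal-class].
#' @export
dxaCrossCal <- function(sourceModel = "Lunar", targetModel = "Hologic",
                        slope = 1, intercept = 0) {
  new("DXACrossCal", sourceModel = sourceModel, targetModel = targetModel,
      slope = slope, intercept = intercept)
}

#' Cross-calibrate an aBMD value between DXA manufacturers
#'
#' @param abmd aBMD in g/cm^2 (>= 0), vectorised.
#' @param cal A [DXACrossCal-class].
#' @return Converted aBMD, g/cm^2.
#' @export
#' @examples
#' dxaCrossCalibrate(1.00, dxaCrossCal(slope = 0.91, intercept = 0.02))
dxaCrossCalibrate <- function(abmd, cal) {
  stopifnot(is(cal, "DXACrossCal"))
  if (any(abmd < 0)) stop("aBMD must be non-negative", call. = FALSE)
  cal@slope * abmd + cal@intercept
}
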