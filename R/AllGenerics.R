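# Accessor generics. Slot access from user code goes through these.

#' @rdname QCTVolume-class
#' @param object,x An object of the documented class.
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' @rdname QCTVolume-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname QCTVolume-class
#' @export
setGeneric("isCalibrated", function(x) standardGeneric("isCalibrated"))

#' @rdname QCTVolume-class
#' @export
setGeneric("phantomROIs", function(x) standardGeneric("phantomROIs"))

#' @rdname QCTVolume-class
#' @export
setGeneric("scannerID", function(x) standardGeneric("scannerID"))

#' @rdname QCTVolume-class
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))

#' @rdname FEResult-class
#' @export
setGeneric("loadCapacity", function(x) standardGeneric("loadCapacity"))

#' @rdname FEResult-class
#' @export
setGeneric("forceDisplacement", function(x) standardGeneric("forceDisplacement"))

#' @rdname DXAMeasure-class
#' @export
setGeneric("aBMD", function(x) standardGeneric("aBMD"))

#' @rdname DXAMeasure-class
#' @export
setGeneric("tScore", function(x) standardGeneric("tScore"))

#' @rdname OverloadResult-class
#' @export
setGeneric("overloadProb", function(x) standardGeneric("overloadProb"))

#' @rdname QCTVolume-class
#' @export
setMethod("voxelGrid", "QCTVolume", function(x) x@grid)

#' @rdname QCTVolume-class
#' @export
setMethod("voxelSpacing", "QCTVolume", function(x) x@spacing)

#' @rdname QCTVolume-class
#' @export
setMethod("isCalibrated", "QCTVolume", function(x) x@calibrated)

#' @rdname QCTVolume-class
#' @export
setMethod("phantomROIs", "QCTVolume", function(x) x@phantomROIs)

#' @rdname QCTVolume-class
#' @export
setMethod("scannerID", "QCTVolume", function(x) x@scannerID)

#' @rdname QCTVolume-class
#' @export
setMethod("landmarks", "QCTVolume", function(x) x@landmarks)

#' @rdname FEResult-class
#' @export
setMethod("loadCapacity", "FEResult", function(x) x@loadCapacity)

#' @describeIn FEResult-class force-displacement history as a data.frame
#'   with columns `displacement_mm` and `force_N`.
#' @export
setMethod("forceDisplacement", "FEResult", function(x)
  data.frame(displacement_mm = x@displacements, force_N = x@reactionForces))

#' @rdname DXAMeasure-class
#' @export
setMethod("aBMD", "DXAMeasure", function(x) x@aBMD)

#' @rdname DXAMeasure-class
#' @export
setMethod("tScore", "DXAMeasure", function(x) x@tScore)

#' @rdname OverloadResult-class
#' @export
setMethod("overloadProb", "OverloadResult", function(x) x@probability)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "QCTVolume", function(object) {
  d <- dim(object@grid)
  cat(sprintf("QCTVolume %dx%dx%d voxels, spacing %s mm [%s]\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = "x"),
              if (object@calibrated) "calibrated, mg/cc" else "uncalibrated, HU"))
  cat(sprintf("  scanner: %s; phantom rods: %d\n", object@scannerID,
              length(object@phantomROIs)))
})

setMethod("show", "FEResult", function(object) {
  cat(sprintf("FEResult [%s]: load capacity %.1f N over %d steps (%s)\n",
              object@configuration, object@loadCapacity,
              length(object@reactionForces), object@stoppedReason))
})

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf("CalibrationFit: density = %.4g * HU + %.4g mg/cc (R^2 = %.4f)\n",
              object@slope, object@intercept, object@rSquared))
})

setMethod("show", "CrossCalibration", function(object) {
  cat(sprintf("CrossCalibration %s -> %s: rho' = %.4g * rho + %.4g mg/cc\n",
              object@sourceScannerID, object@targetScannerID,
              object@slope, object@intercept))
})

setMethod("show", "MaterialModel", function(object) {
  cat(sprintf(paste0(
    "MaterialModel: E = %g * rho^%g MPa; sy = %g * rho^%g MPa\n",
    "  plateau %g strain, softening slope %g*E, residual %g*sy, nu = %g\n"),
    object@modulusCoef, object@modulusExp, object@yieldCoef, object@yieldExp,
    object@plateauStrain, object@softeningRatio, object@residualFraction,
    object@poisson))
})

setMethod("show", "HexMesh", function(object) {
  cat(sprintf("HexMesh: %d nodes, %d elements; head cap %d nodes, distal face %d nodes\n",
              nrow(object@nodes), nrow(object@elements),
              length(object@nodeSets$headSurface),
              length(object@nodeSets$distalFace)))
})

setMethod("show", "Classification", function(object) {
  cat(sprintf("Classification: quadrant=%s, preflight=%s\n",
              object@quadrant, object@preflightDecision))
  fl <- object@postflightFlags
  if (length(fl))
    cat("  flags:", paste(names(fl)[fl], collapse = ", "),
        if (!any(fl)) "(none)" else "", "\n")
})

setMethod("show", "OverloadResult", function(object) {
  cat(sprintf("OverloadResult: P(load > %.0f N) = %.4f [%s]\n",
              object@capacityUsed, object@probability, object@method))
})

setMethod("show", "LoadDistribution", function(object) {
  cat(sprintf("LoadDistribution %s/%s: %s(location=%.4g, scale=%.4g) x g=%.3g\n",
              object@scenario, object@eventClass, object@family,
              object@location, object@scale, object@gravityScale))
})
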