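#' @import methods
NULL

# ---------------------------------------------------------------------------
# Imaging / subject classes
# ---------------------------------------------------------------------------

#' FemurGeometry: parametric proximal femur
#'
#' A simplified proximal femur built from a spherical head, an angled
#' cylindrical neck, and a vertical cylindrical shaft with a flared
#' trochanteric region, wrapped in a uniform cortical shell. All lengths
#' are millimetres; the neck-shaft angle is degrees between the neck axis
#' and the distal shaft axis.
#'
#' @slot headRadius,neckRadius,neckLength,shaftRadius,shaftLength numeric, mm.
#' @slot neckShaftAngle numeric, degrees in (90, 160).
#' @slot corticalThickness numeric, mm; must be less than the neck radius.
#' @exportClass FemurGeometry
setClass("FemurGeometry", representation(
  headRadius = "numeric", neckRadius = "numeric", neckLength = "numeric",
  neckShaftAngle = "numeric", shaftRadius = "numeric", shaftLength = "numeric",
  corticalThickness = "numeric"
))

setValidity("FemurGeometry", function(object) {
  msg <- character()
  lens <- c(object@headRadius, object@neckRadius, object@neckLength,
            object@shaftRadius, object@shaftLength, object@corticalThickness)
  if (any(!is.finite(lens)) || any(lens <= 0))
    msg <- c(msg, "all lengths must be positive and finite")
  if (!(object@neckShaftAngle > 90 && object@neckShaftAngle < 160))
    msg <- c(msg, "neckShaftAngle must be in (90, 160) degrees")
  if (object@corticalThickness >= object@neckRadius)
    msg <- c(msg, "corticalThickness must be smaller than neckRadius")
  if (length(msg)) msg else TRUE
})

#' SubjectParams: demographics and bone parameters for one subject
#'
#' @slot subjectID character identifier.
#' @slot age years; \code{sex} "male" or "female"; \code{height} cm;
#'   \code{weight} kg.
#' @slot geometry a [FemurGeometry-class].
#' @slot corticalDensity,trabecularDensity g/cm^3 equivalent mineral
#'   density; trabecular must be below cortical.
#' @slot scannerID character.
#' @slot flightDuration days, or NA for never-flown subjects.
#' @exportClass SubjectParams
setClass("SubjectParams", representation(
  subjectID = "character", age = "numeric", sex = "character",
  height = "numeric", weight = "numeric", geometry = "FemurGeometry",
  corticalDensity = "numeric", trabecularDensity = "numeric",
  scannerID = "character", flightDuration = "numeric"
))

setValidity("SubjectParams", function(object) {
  msg <- character()
  if (!object@sex %in% c("male", "female"))
    msg <- c(msg, "sex must be 'male' or 'female'")
  if (object@trabecularDensity < 0 ||
      object@trabecularDensity > object@corticalDensity)
    msg <- c(msg, "need 0 <= trabecularDensity <= corticalDensity")
  if (length(msg)) msg else TRUE
})

#' ScannerModel: forward HU model for a CT scanner
#'
#' Maps equivalent mineral density (mg/cc) to Hounsfield units as
#' HU = huSlope * density + huIntercept + N(0, noiseSD). The forward
#' model is what phantom calibration must invert.
#'
#' @slot scannerID character.
#' @slot huSlope HU per (mg/cc), positive.
#' @slot huIntercept HU.
#' @slot noiseSD HU, non-negative.
#' @exportClass ScannerModel
setClass("ScannerModel", representation(
  scannerID = "character", huSlope = "numeric", huIntercept = "numeric",
  noiseSD = "numeric"
))

setValidity("ScannerModel", function(object) {
  msg <- character()
  if (object@huSlope <= 0) msg <- c(msg, "huSlope must be positive")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be non-negative")
  if (length(msg)) msg else TRUE
})

#' QCTVolume: a 3D QCT voxel volume with phantom metadata
#'
#' Holds the voxel grid (HU before calibration, mg/cc equivalent mineral
#' density after), the voxel spacing, the in-field calibration phantom
#' rod regions, and anatomical landmarks recorded by the generator.
#'
#' @slot grid 3D numeric array.
#' @slot spacing numeric length-3, mm per axis, all positive.
#' @slot calibrated logical; TRUE once values are equivalent density.
#' @slot phantomROIs list of `list(indices=<linear voxel indices>,
#'   nominal=<mg/cc>)`, one per rod.
#' @slot scannerID character.
#' @slot landmarks list; may carry `headCenter` (mm), `headRadius` (mm),
#'   `distalZ` (mm) and a `boneMask` index vector.
#' @exportClass QCTVolume
setClass("QCTVolume", representation(
  grid = "array", spacing = "numeric", calibrated = "logical",
  phantomROIs = "list", scannerID = "character", landmarks = "list"
))

setValidity("QCTVolume", function(object) {
  msg <- character()
  if (length(dim(object@grid)) != 3L)
    msg <- c(msg, "grid must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  for (roi in object@phantomROIs) {
    if (!all(c("indices", "nominal") %in% names(roi)))
      msg <- c(msg, "each phantom ROI needs 'indices' and 'nominal'")
  }
  if (length(msg)) msg else TRUE
})

#' DXAMeasure: simulated DXA measurement
#'
#' @slot aBMD areal bone mineral density, g/cm^2, non-negative.
#' @slot tScore standardised aBMD against a young reference.
#' @slot scanDay days relative to launch (negative) or return (positive).
#' @exportClass DXAMeasure
setClass("DXAMeasure", representation(
  aBMD = "numeric", tScore = "numeric", scanDay = "numeric"
))

setValidity("DXAMeasure", function(object) {
  if (object@aBMD < 0) "aBMD must be non-negative" else TRUE
})

# ---------------------------------------------------------------------------
# Calibration classes
# ---------------------------------------------------------------------------

#' CalibrationFit: phantom HU-to-density calibration
#'
#' Ordinary least squares of nominal rod density (mg/cc) on observed
#' rod-ROI mean HU. Applying the fit maps HU affinely to equivalent
#' density: density = slope * HU + intercept.
#'
#' @slot slope (mg/cc) per HU.
#' @slot intercept mg/cc.
#' @slot rSquared coefficient of determination in [0, 1].
#' @slot rodTable data.frame with columns `nominal` and `meanHU`.
#' @exportClass CalibrationFit
setClass("CalibrationFit", representation(
  slope = "numeric", intercept = "numeric", rSquared = "numeric",
  rodTable = "data.frame"
))

setValidity("CalibrationFit", function(object) {
  msg <- character()
  if (!is.na(object@rSquared) &&
      (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(unique(object@rodTable$nominal)) < 2L)
    msg <- c(msg, "at least 2 distinct rod densities are required")
  if (length(msg)) msg else TRUE
})

#' CrossCalibration: voxel-level density map between two scanners
#'
#' Affine map taking calibrated densities reported by the source scanner
#' onto the density scale of the target (reference) scanner.
#'
#' @slot sourceScannerID,targetScannerID character.
#' @slot slope dimensionless, positive.
#' @slot intercept mg/cc.
#' @exportClass CrossCalibration
setClass("CrossCalibration", representation(
  sourceScannerID = "character", targetScannerID = "character",
  slope = "numeric", intercept = "numeric"
))

setValidity("CrossCalibration", function(object) {
  if (object@slope <= 0) "slope must be positive" else TRUE
})

#' DXACrossCal: aBMD conversion between DXA manufacturers
#'
#' @slot sourceModel,targetModel character.
#' @slot slope dimensionless, positive; \code{intercept} g/cm^2.
#' @exportClass DXACrossCal
setClass("DXACrossCal", representation(
  sourceModel = "character", targetModel = "character",
  slope = "numeric", intercept = "numeric"
))

setValidity("DXACrossCal", function(object) {
  if (object@slope <= 0) "slope must be positive" else TRUE
})

# ---------------------------------------------------------------------------
# Finite-element classes
# ---------------------------------------------------------------------------

#' MaterialModel: density-parameterised four-region stress-strain law
#'
#' For equivalent mineral density rho (g/cm^3) the uniaxial law is:
#' elastic with modulus E(rho) = modulusCoef * rho^modulusExp up to the
#' yield stress sy(rho) = yieldCoef * rho^yieldExp; perfectly plastic for
#' a plateau of length plateauStrain beyond the yield strain; linear
#' softening with slope softeningRatio * E down to residualFraction * sy;
#' then a residual plateau. The curve is continuous by construction.
#'
#' @slot modulusCoef,modulusExp modulus power law, MPa at rho = 1 g/cm^3.
#' @slot yieldCoef,yieldExp yield-stress power law, MPa at rho = 1 g/cm^3.
#' @slot plateauStrain length of the perfectly-plastic plateau (strain).
#' @slot softeningRatio softening slope as a fraction of E (positive).
#' @slot residualFraction residual stress as a fraction of sy, in (0, 1].
#' @slot poisson Poisson ratio.
#' @exportClass MaterialModel
setClass("MaterialModel", representation(
  modulusCoef = "numeric", modulusExp = "numeric",
  yieldCoef = "numeric", yieldExp = "numeric",
  plateauStrain = "numeric", softeningRatio = "numeric",
  residualFraction = "numeric", poisson = "numeric"
))

setValidity("MaterialModel", function(object) {
  msg <- character()
  if (object@modulusCoef <= 0 || object@yieldCoef <= 0)
    msg <- c(msg, "power-law coefficients must be positive")
  if (object@plateauStrain < 0)
    msg <- c(msg, "plateauStrain must be non-negative")
  if (object@softeningRatio <= 0)
    msg <- c(msg, "softeningRatio must be positive")
  if (object@residualFraction <= 0 || object@residualFraction > 1)
    msg <- c(msg, "residualFraction must be in (0, 1]")
  if (object@poisson < 0 || object@poisson >= 0.5)
    msg <- c(msg, "poisson must be in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' HexMesh: voxel hexahedral mesh
#'
#' One 8-node hexahedral element per retained voxel, nodes shared between
#' face-adjacent voxels. Node sets mark the loaded femoral-head cap and
#' the fully constrained distal cut plane.
#'
#' @slot nodes numeric matrix (n x 3), mm.
#' @slot elements integer matrix (m x 8) of node indices in trilinear
#'   local order.
#' @slot elementDensity g/cm^3 per element.
#' @slot nodeSets list with integer vectors `headSurface` and `distalFace`.
#' @slot loadDirection unit vector of prescribed head displacement.
#' @slot spacing voxel edge lengths, mm.
#' @exportClass HexMesh
setClass("HexMesh", representation(
  nodes = "matrix", elements = "matrix", elementDensity = "numeric",
  nodeSets = "list", loadDirection = "numeric", spacing = "numeric"
))

setValidity("HexMesh", function(object) {
  msg <- character()
  if (ncol(object@nodes) != 3L) msg <- c(msg, "nodes must be n x 3")
  if (ncol(object@elements) != 8L) msg <- c(msg, "elements must be m x 8")
  if (nrow(object@elements) != length(object@elementDensity))
    msg <- c(msg, "one density per element required")
  if (nrow(object@elements) > 0 &&
      (max(object@elements) > nrow(object@nodes) || min(object@elements) < 1))
    msg <- c(msg, "element connectivity references missing nodes")
  hs <- object@nodeSets$headSurface; df <- object@nodeSets$distalFace
  if (!length(hs) || !length(df))
    msg <- c(msg, "headSurface and distalFace node sets must be non-empty")
  else if (length(intersect(hs, df)))
    msg <- c(msg, "headSurface and distalFace node sets must be disjoint")
  if (abs(sum(object@loadDirection^2) - 1) > 1e-8)
    msg <- c(msg, "loadDirection must be a unit vector")
  if (length(msg)) msg else TRUE
})

#' SolveConfig: displacement-controlled solver settings
#'
#' @slot displacementIncrement mm prescribed on the head cap per step.
#' @slot maxSteps maximum number of increments.
#' @slot secantTol relative reaction-force change declaring the secant
#'   loop converged.
#' @slot maxSecantIters iteration cap per increment.
#' @slot dropFraction stop once force < (1 - dropFraction) * running max.
#' @slot minModulusRatio floor on the secant modulus as a fraction of the
#'   initial elastic modulus (guards against singularity after softening).
#' @exportClass SolveConfig
setClass("SolveConfig", representation(
  displacementIncrement = "numeric", maxSteps = "numeric",
  secantTol = "numeric", maxSecantIters = "numeric",
  dropFraction = "numeric", minModulusRatio = "numeric"
))

setValidity("SolveConfig", function(object) {
  vals <- c(object@displacementIncrement, object@maxSteps, object@secantTol,
            object@maxSecantIters, object@dropFraction, object@minModulusRatio)
  msg <- character()
  if (any(vals <= 0)) msg <- c(msg, "all solver settings must be positive")
  if (object@dropFraction >= 1)
    msg <- c(msg, "dropFraction must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' FEResult: force-displacement history and load capacity
#'
#' @slot displacements mm of head-cap displacement per recorded step.
#' @slot reactionForces N of head reaction along the load direction.
#' @slot loadCapacity N; the running maximum reaction force.
#' @slot stoppedReason "force_drop", "max_steps" or "non_convergent".
#' @slot configuration "NLS", "NLF" or "custom".
#' @exportClass FEResult
setClass("FEResult", representation(
  displacements = "numeric", reactionForces = "numeric",
  loadCapacity = "numeric", stoppedReason = "character",
  configuration = "character"
))

setValidity("FEResult", function(object) {
  msg <- character()
  if (length(object@displacements) != length(object@reactionForces))
    msg <- c(msg, "history vectors must have equal length")
  if (length(object@reactionForces) &&
      abs(object@loadCapacity - max(object@reactionForces)) >
        1e-8 * max(1, abs(object@loadCapacity)))
    msg <- c(msg, "loadCapacity must equal max(reactionForces)")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Risk-band / classification classes
# ---------------------------------------------------------------------------

#' RiskBandConfig: operating-band thresholds
#'
#' Cut-points for the combined DXA / finite-element operating bands:
#' load-capacity permissible outcome limits (POL) for stance and fall
#' configurations, the DXA T-score certification and screening bounds,
#' least significant change (LSC) percentages, and the percentile used to
#' derive POLs from a reference cohort.
#'
#' @slot polNLS,polNLF N.
#' @slot tPreflight,tScreenFloor,tPostflightPOL T-score cut-points.
#' @slot lscNLS,lscNLF percent.
#' @slot percentileQ percentile in (0, 100); \code{alpha} test level.
#' @exportClass RiskBandConfig
setClass("RiskBandConfig", representation(
  polNLS = "numeric", polNLF = "numeric",
  tPreflight = "numeric", tScreenFloor = "numeric",
  tPostflightPOL = "numeric",
  lscNLS = "numeric", lscNLF = "numeric",
  percentileQ = "numeric", alpha = "numeric"
))

setValidity("RiskBandConfig", function(object) {
  msg <- character()
  if (object@tScreenFloor >= object@tPreflight)
    msg <- c(msg, "tScreenFloor must be below tPreflight")
  if (object@percentileQ <= 0 || object@percentileQ >= 100)
    msg <- c(msg, "percentileQ must be in (0, 100)")
  if (object@lscNLS <= 0 || object@lscNLF <= 0)
    msg <- c(msg, "LSC percentages must be positive")
  if (length(msg)) msg else TRUE
})

#' SubjectRecord: one subject's DXA and load-capacity record
#'
#' @slot subjectID character; \code{cohortLabel} character.
#' @slot dxaPre,dxaPost [DXAMeasure-class] objects.
#' @slot fNLSpre,fNLSpost,fNLFpre,fNLFpost load capacities, N (NA when
#'   absent); present values must be positive.
#' @exportClass SubjectRecord
setClass("SubjectRecord", representation(
  subjectID = "character", cohortLabel = "character",
  dxaPre = "DXAMeasure", dxaPost = "DXAMeasure",
  fNLSpre = "numeric", fNLSpost = "numeric",
  fNLFpre = "numeric", fNLFpost = "numeric"
))

setValidity("SubjectRecord", function(object) {
  f <- c(object@fNLSpre, object@fNLSpost, object@fNLFpre, object@fNLFpost)
  if (any(!is.na(f) & f <= 0))
    "load capacities must be positive when present" else TRUE
})

#' Classification: operating-band decision for one subject
#'
#' @slot quadrant one of pass_both / dxa_only / fe_only / fail_both on the
#'   T-score vs load-capacity chart.
#' @slot preflightDecision certified / screen_with_fe_passed /
#'   not_certified / not_applicable.
#' @slot postflightFlags named logical vector: below_t_pol,
#'   below_fe_pol_nls, below_fe_pol_nlf, significant_loss_nls,
#'   significant_loss_nlf.
#' @exportClass Classification
setClass("Classification", representation(
  quadrant = "character", preflightDecision = "character",
  postflightFlags = "logical"
))

# ---------------------------------------------------------------------------
# PRA classes
# ---------------------------------------------------------------------------

#' LoadDistribution: applied hip-load distribution for one scenario
#'
#' Loads are drawn from the family with the given location/scale and then
#' multiplied by gravityScale, the scenario's gravitational loading
#' relative to Earth (1 = Earth; 0 = microgravity).
#'
#' @slot scenario one of ISS, Moon, Mars, Earth_return.
#' @slot eventClass low_energy or high_energy.
#' @slot family "normal" (location = mean N, scale = SD N) or "lognormal"
#'   (location = meanlog, scale = sdlog of the load in N).
#' @slot location,scale distribution parameters; scale positive.
#' @slot gravityScale in [0, 1].
#' @exportClass LoadDistribution
setClass("LoadDistribution", representation(
  scenario = "character", eventClass = "character", family = "character",
  location = "numeric", scale = "numeric", gravityScale = "numeric"
))

setValidity("LoadDistribution", function(object) {
  msg <- character()
  if (!object@family %in% c("normal", "lognormal"))
    msg <- c(msg, "family must be 'normal' or 'lognormal'")
  if (object@scale <= 0) msg <- c(msg, "scale must be positive")
  if (object@gravityScale < 0 || object@gravityScale > 1)
    msg <- c(msg, "gravityScale must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' OverloadResult: probability that applied load exceeds capacity
#'
#' @slot probability P(load > capacity), in [0, 1].
#' @slot mcStandardError sqrt(p(1-p)/n) for Monte-Carlo estimates; NA for
#'   closed-form results.
#' @slot nSamples Monte-Carlo sample count (NA for closed form).
#' @slot capacityUsed N.
#' @slot method "monte_carlo" or "closed_form".
#' @exportClass OverloadResult
setClass("OverloadResult", representation(
  probability = "numeric", mcStandardError = "numeric",
  nSamples = "numeric", capacityUsed = "numeric", method = "character"
))

setValidity("OverloadResult", function(object) {
  msg <- character()
  if (object@probability < 0 || object@probability > 1)
    msg <- c(msg, "probability must be in [0, 1]")
  if (!object@method %in% c("monte_carlo", "closed_form"))
    msg <- c(msg, "method must be 'monte_carlo' or 'closed_form'")
  if (length(msg)) msg else TRUE
})
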