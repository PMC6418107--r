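# Synthetic QCT volumes, cohorts and simulated DXA.
#
# Real QCT scans of the reference populations (elderly Icelandic AGES
# cohort, Rochester/Mayo age-stratified cohort, astronaut corps) are
# restricted; this module generates stand-ins with the statistical
# structure the downstream calibration / FE / cut-point stages assume.

#' Construct a parametric femur geometry
#'
#' @param headRadius,neckRadius,neckLength,shaftRadius,shaftLength mm.
#' @param neckShaftAngle degrees between neck axis and distal shaft axis.
#' @param corticalThickness mm of uniform cortical shell.
#' @return A [FemurGeometry-class] object.
#' @export
#' @examples
#' femurGeometry()
femurGeometry <- function(headRadius = 24, neckRadius = 16, neckLength = 48,
                          neckShaftAngle = 130, shaftRadius = 16,
                          shaftLength = 80, corticalThickness = 5) {
  new("FemurGeometry", headRadius = headRadius, neckRadius = neckRadius,
      neckLength = neckLength, neckShaftAngle = neckShaftAngle,
      shaftRadius = shaftRadius, shaftLength = shaftLength,
      corticalThickness = corticalThickness)
}

#' Construct subject parameters
#'
#' @param subjectID character.
#' @param age years; \code{sex} "male"/"female"; \code{height} cm;
#'   \code{weight} kg.
#' @param geometry a [FemurGeometry-class].
#' @param corticalDensity,trabecularDensity g/cm^3 equivalent mineral.
#' @param scannerID character.
#' @param flightDuration days (NA if never flown).
#' @return A [SubjectParams-class] object.
#' @export
subjectParams <- function(subjectID = "S1", age = 46, sex = "male",
                          height = 176, weight = 72,
                          geometry = femurGeometry(),
                          corticalDensity = 1.0, trabecularDensity = 0.32,
                          scannerID = "scannerA", flightDuration = NA_real_) {
  new("SubjectParams", subjectID = subjectID, age = age, sex = sex,
      height = height, weight = weight, geometry = geometry,
      corticalDensity = corticalDensity,
      trabecularDensity = trabecularDensity,
      scannerID = scannerID, flightDuration = as.numeric(flightDuration))
}

#' Construct a CT scanner forward model
#'
#' @param scannerID character.
#' @param huSlope HU per mg/cc equivalent density (> 0).
#' @param huIntercept HU at zero equivalent density (soft tissue /
#'   water baseline).
#' @param noiseSD additive Gaussian HU noise.
#' @return A [ScannerModel-class] object.
#' @export
scannerModel <- function(scannerID = "scannerA", huSlope = 1.0,
                         huIntercept = 0, noiseSD = 0) {
  new("ScannerModel", scannerID = scannerID, huSlope = huSlope,
      huIntercept = huIntercept, noiseSD = noiseSD)
}

# penetration depth (positive inside) of points into a sphere
.depthSphere <- function(px, py, pz, center, r) {
  r - sqrt((px - center[1])^2 + (py - center[2])^2 + (pz - center[3])^2)
}

# penetration depth into a capped cylinder from p0 along unit axis u,
# length L, radius r; depth is distance to the nearest surface (side or cap)
.depthCylinder <- function(px, py, pz, p0, u, L, r) {
  dx <- px - p0[1]; dy <- py - p0[2]; dz <- pz - p0[3]
  t <- dx * u[1] + dy * u[2] + dz * u[3]
  rx <- dx - t * u[1]; ry <- dy - t * u[2]; rz <- dz - t * u[3]
  d <- sqrt(rx^2 + ry^2 + rz^2)
  pmin(r - d, t, L - t)
}

#' Generate a synthetic QCT volume for one subject
#'
#' Builds the parametric proximal femur (spherical head, angled
#' cylindrical neck, vertical shaft) with a uniform cortical shell at the
#' subject's cortical density and a trabecular interior, places an
#' in-field calibration phantom (three rods at the configured nominal
#' equivalent densities), and maps the density field through the scanner
#' forward model to uncalibrated HU. Background soft tissue sits at
#' 0 mg/cc equivalent density so the phantom intercept stays
#' identifiable. Deterministic given `seed`.
#'
#' @param params A [SubjectParams-class].
#' @param scanner A [ScannerModel-class].
#' @param voxelMM Isotropic voxel size, mm. Must satisfy
#'   `neckRadius >= 3 * voxelMM` so the neck is resolved.
#' @param seed Integer seed for scanner noise.
#' @param rodDensities Nominal phantom rod densities, mg/cc calcium
#'   hydroxyapatite.
#' @return An uncalibrated [QCTVolume-class] (grid in HU) whose landmarks
#'   record the head center/radius, distal cut plane and bone mask.
#' @export
#' @examples
#' vol <- generateVolume(subjectParams(), scannerModel(), voxelMM = 5, seed = 1)
#' vol
generateVolume <- function(params, scanner, voxelMM = 3, seed = 1,
                           rodDensities = c(0, 75, 150)) {
  stopifnot(is(params, "SubjectParams"), is(scanner, "ScannerModel"))
  g <- params@geometry
  if (g@neckRadius < 3 * voxelMM)
    stop("degenerate geometry: voxelMM too coarse, neck radius must span ",
         "at least 3 voxels", call. = FALSE)

  margin <- 10
  beta <- (g@neckShaftAngle - 90) * pi / 180
  u <- c(cos(beta), 0, sin(beta))            # neck axis, medial-superior
  z0 <- 28                                   # distal cut height; phantom below
  p0 <- c(0, 0, z0 + g@shaftLength - g@shaftRadius)  # neck origin
  headC <- p0 + u * g@neckLength

  xmin <- -(g@shaftRadius + margin)
  xmax <- headC[1] + g@headRadius + margin
  ymax <- max(g@shaftRadius, g@headRadius) + margin
  zmax <- headC[3] + g@headRadius + margin
  nx <- ceiling((xmax - xmin) / voxelMM)
  ny <- ceiling(2 * ymax / voxelMM)
  nz <- ceiling(zmax / voxelMM)
  xs <- xmin + (seq_len(nx) - 0.5) * voxelMM
  ys <- -ymax + (seq_len(ny) - 0.5) * voxelMM
  zs <- (seq_len(nz) - 0.5) * voxelMM

  px <- rep(xs, times = ny * nz)
  py <- rep(rep(ys, each = nx), times = nz)
  pz <- rep(zs, each = nx * ny)

  depth <- pmax(
    .depthSphere(px, py, pz, headC, g@headRadius),
    .depthCylinder(px, py, pz, p0, u, g@neckLength, g@neckRadius),
    .depthCylinder(px, py, pz, c(0, 0, z0), c(0, 0, 1),
                   g@shaftLength, g@shaftRadius))

  density <- numeric(nx * ny * nz)           # background 0 mg/cc
  bone <- depth > 0
  density[bone] <- ifelse(depth[bone] <= g@corticalThickness,
                          params@corticalDensity, params@trabecularDensity) * 1000

  # phantom: rods along y, below the femur, centred in x
  rodR <- 8
  rodZ <- z0 / 2
  rodX <- (xmin + xmax) / 2 + c(-1, 0, 1) * 3.2 * rodR
  rois <- vector("list", length(rodDensities))
  for (k in seq_along(rodDensities)) {
    dep <- .depthCylinder(px, py, pz, c(rodX[k], -ymax + 5, rodZ), c(0, 1, 0),
                          2 * ymax - 10, rodR)
    inRod <- dep > 0
    density[inRod] <- rodDensities[k]
    # conservative core ROI avoids partial-volume edges
    rois[[k]] <- list(indices = which(dep > 0.45 * rodR),
                      nominal = rodDensities[k])
  }

  hu <- withSeed(seed, {
    noise <- if (scanner@noiseSD > 0)
      stats::rnorm(length(density), 0, scanner@noiseSD) else 0
    scanner@huSlope * density + scanner@huIntercept + noise
  })

  new("QCTVolume",
      grid = array(hu, dim = c(nx, ny, nz)),
      spacing = rep(voxelMM, 3), calibrated = FALSE,
      phantomROIs = rois, scannerID = scanner@scannerID,
      landmarks = list(headCenter = headC, headRadius = g@headRadius,
                       distalZ = z0, neckAxis = u,
                       origin = c(xmin, -ymax, 0),
                       boneMask = which(bone)))
}

# ---------------------------------------------------------------------------
# Cohort demographics
# ---------------------------------------------------------------------------

# built-in cohort specifications: mean, sd, (lo, hi) truncation range.
# Demographics follow the published cohort summaries; equivalent-density
# distributions are modelling choices (see the methods vignette).
.cohortSpecs <- list(
  AGES_fractured = list(
    nDefault = 45, sex = "male", scanner = "AGES_CT",
    age = c(80.3, 5.7, 71.0, 93.0), height = c(175.1, 5.5, 159.2, 187.1),
    weight = c(80.1, 14.4, 50.3, 114.0),
    corticalDensity = c(0.90, 0.06, 0.70, 1.10),
    trabecularDensity = c(0.26, 0.05, 0.10, 0.45),
    densityShift = c(cortical = 0.05, trabecular = 0.06)),
  AGES_nonfractured = list(
    nDefault = 94, sex = "male", scanner = "AGES_CT",
    age = c(79.6, 5.2, 70.0, 90.0), height = c(174.9, 6.7, 162.4, 190.5),
    weight = c(82.6, 14.8, 52.4, 135.0),
    corticalDensity = c(0.90, 0.06, 0.70, 1.10),
    trabecularDensity = c(0.26, 0.05, 0.10, 0.45),
    densityShift = c(cortical = 0, trabecular = 0)),
  Mayo_male = list(
    nDefault = 181, sex = "male", scanner = "Mayo_CT",
    age = c(59.9, 16.6, 28.0, 90.0), height = c(176.3, 7.2, 157.0, 195.4),
    weight = c(90.2, 16.5, 53.0, 134.0),
    corticalDensity = c(0.95, 0.07, 0.72, 1.20),
    trabecularDensity = c(0.30, 0.06, 0.12, 0.50),
    densityShift = c(cortical = 0, trabecular = 0)),
  Mayo_female = list(
    nDefault = 216, sex = "female", scanner = "Mayo_CT",
    age = c(60.9, 14.5, 27.0, 90.0), height = c(162.3, 6.1, 148.5, 179.2),
    weight = c(74.4, 15.4, 51.0, 128.5),
    corticalDensity = c(0.92, 0.07, 0.70, 1.15),
    trabecularDensity = c(0.28, 0.06, 0.12, 0.48),
    densityShift = c(cortical = 0, trabecular = 0)),
  astronaut = list(
    nDefault = 8, sex = "male", scanner = "astro_CT",
    age = c(46.0, 5.0, 38.0, 53.0), height = c(176.0, 5.0, 168.0, 180.0),
    weight = c(72.0, 12.0, 59.0, 88.0),
    flightDuration = c(154.0, 19.0, 125.0, 169.0),
    corticalDensity = c(1.00, 0.06, 0.85, 1.15),
    trabecularDensity = c(0.34, 0.05, 0.20, 0.50),
    densityShift = c(cortical = 0, trabecular = 0))
)

#' Names of the built-in cohort specifications
#' @return Character vector of cohort names.
#' @export
cohortNames <- function() names(.cohortSpecs)

#' Generate a synthetic cohort of subject parameters
#'
#' Samples demographics (age, height, weight) and equivalent mineral
#' densities from truncated normal distributions matching the configured
#' cohort. For the fractured-cohort specification the density means are
#' shifted downward by the configured effect size, emulating the lower
#' bone quality of fracture cases. Femur geometry is scaled mildly with
#' height and jittered per subject. Deterministic given `seed`.
#'
#' @param cohortSpec Either one of [cohortNames()] or a custom list with
#'   elements `sex`, `scanner`, and `c(mean, sd, lo, hi)` vectors `age`,
#'   `height`, `weight`, `corticalDensity`, `trabecularDensity`
#'   (optional `densityShift`, `flightDuration`).
#' @param n Number of subjects; defaults to the cohort's published size.
#' @param seed Integer seed.
#' @return List of [SubjectParams-class] objects.
#' @export
#' @examples
#' coh <- generateCohort("astronaut", seed = 7)
#' length(coh)
generateCohort <- function(cohortSpec, n = NULL, seed = 1) {
  if (is.character(cohortSpec)) {
    if (!cohortSpec %in% names(.cohortSpecs))
      stop("unknown cohort '", cohortSpec, "'; see cohortNames()",
           call. = FALSE)
    label <- cohortSpec
    cohortSpec <- .cohortSpecs[[cohortSpec]]
  } else label <- "custom"
  if (is.null(n)) n <- cohortSpec$nDefault
  if (is.null(n)) stop("'n' required for custom cohort specs", call. = FALSE)
  if (n < 0) stop("'n' must be non-negative", call. = FALSE)
  if (n == 0) return(list())

  shift <- cohortSpec$densityShift
  if (is.null(shift)) shift <- c(cortical = 0, trabecular = 0)

  withSeed(seed, {
    tr <- function(p, n, dshift = 0)
      rtruncn(n, p[1] - dshift, p[2], p[3] - dshift, p[4])
    age <- tr(cohortSpec$age, n)
    height <- tr(cohortSpec$height, n)
    weight <- tr(cohortSpec$weight, n)
    cort <- tr(cohortSpec$corticalDensity, n, shift[["cortical"]])
    trab <- tr(cohortSpec$trabecularDensity, n, shift[["trabecular"]])
    trab <- pmin(trab, cort - 1e-3)
    fdur <- if (!is.null(cohortSpec$flightDuration))
      tr(cohortSpec$flightDuration, n) else rep(NA_real_, n)
    hscale <- height / 176
    gjit <- matrix(stats::rnorm(n * 3, 1, 0.03), n, 3)
    lapply(seq_len(n), function(i) {
      s <- hscale[i]
      subjectParams(
        subjectID = sprintf("%s_%03d", label, i),
        age = age[i], sex = cohortSpec$sex,
        height = height[i], weight = weight[i],
        geometry = femurGeometry(
          headRadius = 24 * s * gjit[i, 1], neckRadius = 16 * s * gjit[i, 2],
          neckLength = 48 * s * gjit[i, 3], neckShaftAngle = 130,
          shaftRadius = 16 * s * gjit[i, 2], shaftLength = 80 * s,
          corticalThickness = 5 * s),
        corticalDensity = cort[i], trabecularDensity = trab[i],
        scannerID = cohortSpec$scanner, flightDuration = fdur[i])
    })
  })
}

#' Apply a spaceflight bone-loss effect to subject parameters
#'
#' Reduces cortical and trabecular densities multiplicatively by
#' compartment-specific monthly loss rates compounded over the flight
#' duration, with optional subject-level lognormal noise. The default
#' rates keep trabecular loss faster than cortical loss, the direction
#' consistently reported for long-duration spaceflight. With zero noise
#' the log-scale loss is exactly linear in duration.
#'
#' @param params A [SubjectParams-class].
#' @param lossModel List with `trabecular` and `cortical` loss rates in
#'   percent per month (30.44-day months).
#' @param duration Days of exposure (>= 0).
#' @param seed Integer seed for the subject-level noise.
#' @param noiseSD SD of the lognormal noise on the retention factor.
#' @param allowGain Set TRUE to permit negative loss rates.
#' @return A new [SubjectParams-class] with post-flight densities.
#' @export
applyFlightEffect <- function(params,
                              lossModel = list(trabecular = 1.5, cortical = 1.0),
                              duration, seed = 1, noiseSD = 0.005,
                              allowGain = FALSE) {
  stopifnot(is(params, "SubjectParams"))
  if (duration < 0) stop("'duration' must be >= 0", call. = FALSE)
  rates <- c(lossModel$trabecular, lossModel$cortical)
  if (any(rates < 0) && !allowGain)
    stop("negative loss rates require allowGain = TRUE", call. = FALSE)
  if (duration == 0) return(params)
  months <- duration / 30.44
  keep <- (1 - rates / 100)^months
  noise <- withSeed(seed, exp(stats::rnorm(2, 0, noiseSD)))
  if (noiseSD == 0) noise <- c(1, 1)
  out <- params
  out@trabecularDensity <- params@trabecularDensity * keep[1] * noise[1]
  out@corticalDensity <- params@corticalDensity * keep[2] * noise[2]
  out@trabecularDensity <- min(out@trabecularDensity, out@corticalDensity)
  out@flightDuration <- duration
  validObject(out)
  out
}

#' Project a calibrated volume to a simulated DXA measurement
#'
#' Integrates equivalent mineral density over the bone mask along the
#' projection axis, divides by the projected area, and standardises the
#' resulting areal BMD against a configurable young-reference
#' distribution to obtain a T-score (the reference population of the DXA
#' manufacturer databases is not public; the defaults are documented
#' placeholders).
#'
#' @param volume Calibrated [QCTVolume-class] (mg/cc).
#' @param axis Projection axis (1, 2 or 3); 2 (anterior-posterior) by
#'   default.
#' @param refMean,refSD Young-reference aBMD mean and SD, g/cm^2.
#' @param mask Optional logical array or linear index vector selecting
#'   bone voxels; defaults to the generator's recorded bone mask, else
#'   voxels above 150 mg/cc outside the phantom.
#' @param scanDay Days relative to launch/return, recorded as metadata.
#' @return A [DXAMeasure-class].
#' @export
projectDXA <- function(volume, axis = 2, refMean = 0.94, refSD = 0.12,
                       mask = NULL, scanDay = NA_real_) {
  stopifnot(is(volume, "QCTVolume"))
  if (!volume@calibrated)
    stop("projectDXA requires a calibrated volume", call. = FALSE)
  d <- dim(volume@grid)
  if (is.null(mask)) {
    mask <- volume@landmarks$boneMask
    if (is.null(mask)) {
      mask <- which(volume@grid > 150)
      mask <- setdiff(mask, unlist(lapply(volume@phantomROIs, `[[`, "indices")))
    }
  }
  if (is.logical(mask)) mask <- which(mask)
  if (!length(mask)) stop("empty bone mask", call. = FALSE)

  sp <- volume@spacing
  voxVolCM3 <- prod(sp) / 1000                    # mm^3 -> cm^3
  massG <- sum(volume@grid[mask] / 1000) * voxVolCM3   # mg/cc -> g/cc
  ij <- arrayInd(mask, d)[, -axis, drop = FALSE]
  nPix <- nrow(unique(ij))
  areaCM2 <- nPix * prod(sp[-axis]) / 100         # mm^2 -> cm^2
  abmd <- massG / areaCM2
  new("DXAMeasure", aBMD = abmd, tScore = (abmd - refMean) / refSD,
      scanDay = as.numeric(scanDay))
}

# ---------------------------------------------------------------------------
# Record-level cohort generator (capacities + DXA, no imaging)
# ---------------------------------------------------------------------------

# Load-capacity and T-score distributions per cohort. The AGES-fractured
# capacity distributions are anchored so that the cohort's 75th
# percentiles sit at the published permissible-outcome-limit cut-points;
# Mayo and astronaut means/SDs/ranges follow the published summaries.
# `rNLS`/`rNLF` are the latent correlations between T-score and capacity
# implied by the published R^2 values.
.recordSpecs <- list(
  AGES_fractured = list(
    nDefault = 45,
    t = c(-2.2, 1.0, -4.5, 0.5), abmdRef = c(0.94, 0.12),
    fnls = c(8500, 1540, 4500, 14000), fnlf = c(3300, 540, 1800, 5200),
    rNLS = sqrt(0.77), rNLF = sqrt(0.63)),
  AGES_nonfractured = list(
    nDefault = 94,
    t = c(-1.5, 1.0, -4.0, 1.0), abmdRef = c(0.94, 0.12),
    fnls = c(10500, 2200, 5000, 17000), fnlf = c(4100, 700, 2200, 6500),
    rNLS = sqrt(0.77), rNLF = sqrt(0.63)),
  Mayo_male = list(
    nDefault = 181,
    t = c(0.0, 1.2, -3.0, 3.0), abmdRef = c(0.94, 0.12),
    fnls = c(11416, 2816, 5000, 20000), fnlf = c(4000, 950, 1800, 7500),
    rNLS = sqrt(0.77), rNLF = sqrt(0.63)),
  Mayo_female = list(
    nDefault = 216,
    t = c(-0.4, 1.2, -3.5, 2.8), abmdRef = c(0.86, 0.11),
    fnls = c(9500, 2400, 4200, 17000), fnlf = c(3400, 850, 1500, 6500),
    rNLS = sqrt(0.77), rNLF = sqrt(0.63)),
  astronaut = list(
    nDefault = 8,
    t = c(0.97, 1.04, -0.48, 2.46), abmdRef = c(0.94, 0.12),
    fnls = c(14279, 3673, 10030, 22072), fnlf = c(4037, 385, 3488, 4590),
    tPostDelta = c(-0.23, 0.15, -0.46, 0.01),
    fnlsPost = c(13624, 3215, 10757, 20914),
    fnlfPost = c(3925, 456, 3350, 4486),
    flight = c(154, 19, 125, 169),
    rNLS = sqrt(0.13), rNLF = sqrt(0.43))
)

#' Generate a record-level synthetic cohort
#'
#' Draws per-subject DXA T-scores and stance (NLS) / fall (NLF) hip load
#' capacities from truncated normal marginals with the configured
#' latent correlation between T-score and capacity, matching the
#' moderate population-level and weak astronaut-level DXA-FE agreement.
#' For the astronaut cohort, correlated post-flight values and flight
#' durations are added.
#'
#' @param cohort One of [cohortNames()].
#' @param n Number of subjects; defaults to the published cohort size.
#' @param seed Integer seed.
#' @return data.frame with columns `subject_id`, `cohort`, `t_score`,
#'   `abmd`, `f_nls`, `f_nlf` and, for astronauts, `t_score_post`,
#'   `abmd_post`, `f_nls_post`, `f_nlf_post`, `flight_days`.
#' @export
#' @examples
#' head(generateRecordCohort("AGES_fractured", n = 10, seed = 1))
generateRecordCohort <- function(cohort, n = NULL, seed = 1) {
  if (!cohort %in% names(.recordSpecs))
    stop("unknown cohort '", cohort, "'", call. = FALSE)
  sp <- .recordSpecs[[cohort]]
  if (is.null(n)) n <- sp$nDefault
  if (n < 0) stop("'n' must be non-negative", call. = FALSE)

  withSeed(seed, {
    z <- stats::rnorm(n)
    mix <- function(r, n) r * z + sqrt(1 - r^2) * stats::rnorm(n)
    clampQ <- function(p, latent)   # map latent N(0,1) through truncated marginal
      pmin(pmax(p[1] + p[2] * latent, p[3]), p[4])
    t <- clampQ(sp$t, z)
    fnls <- clampQ(sp$fnls, mix(sp$rNLS, n))
    fnlf <- clampQ(sp$fnlf, mix(sp$rNLF, n))
    out <- data.frame(
      subject_id = sprintf("%s_%03d", cohort, seq_len(n)),
      cohort = cohort, t_score = t,
      abmd = sp$abmdRef[1] + sp$abmdRef[2] * t,
      f_nls = fnls, f_nlf = fnlf,
      stringsAsFactors = FALSE)
    if (!is.null(sp$tPostDelta)) {
      dt <- clampQ(sp$tPostDelta, stats::rnorm(n))
      out$t_score_post <- out$t_score + dt
      out$abmd_post <- sp$abmdRef[1] + sp$abmdRef[2] * out$t_score_post
      # post-flight capacity: shrink toward the post-flight marginal while
      # keeping subjects' rank order (pre/post strongly correlated)
      zp <- 0.9 * (fnls - sp$fnls[1]) / sp$fnls[2] +
        sqrt(1 - 0.81) * stats::rnorm(n)
      out$f_nls_post <- clampQ(sp$fnlsPost, zp)
      zq <- 0.9 * (fnlf - sp$fnlf[1]) / sp$fnlf[2] +
        sqrt(1 - 0.81) * stats::rnorm(n)
      out$f_nlf_post <- clampQ(sp$fnlfPost, zq)
      out$flight_days <- round(clampQ(sp$flight, stats::rnorm(n)))
    }
    out
  })
}

#' Construct a subject record
#'
#' @param subjectID,cohortLabel character.
#' @param dxaPre,dxaPost [DXAMeasure-class] objects.
#' @param fNLSpre,fNLSpost,fNLFpre,fNLFpost load capacities, N.
#' @return A [SubjectRecord-class].
#' @export
subjectRecord <- function(subjectID, cohortLabel = "custom",
                          dxaPre = new("DXAMeasure", aBMD = 0, tScore = 0,
                                       scanDay = NA_real_),
                          dxaPost = dxaPre,
                          fNLSpre = NA_real_, fNLSpost = NA_real_,
                          fNLFpre = NA_real_, fNLFpost = NA_real_) {
  new("SubjectRecord", subjectID = subjectID, cohortLabel = cohortLabel,
      dxaPre = dxaPre, dxaPost = dxaPost,
      fNLSpre = fNLSpre, fNLSpost = fNLSpost,
      fNLFpre = fNLFpre, fNLFpost = fNLFpost)
}
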