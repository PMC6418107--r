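# Pipeline orchestration: simulate -> calibrate -> FE -> cut-points ->
# classification -> PRA -> report, with NIfTI + JSON-sidecar volume I/O,
# a single master seed with derived per-stage seeds, and a run manifest.

#' Write a QCT volume to NIfTI with a JSON sidecar
#'
#' The voxel grid and spacing go to `.nii`/`.nii.gz` (float64, lossless
#' for this pipeline); phantom ROIs, scanner ID, calibration flag and
#' landmarks go to a sidecar `<path>.json`.
#'
#' @param volume A [QCTVolume-class].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "QCTVolume"))
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("unrecognised volume format: use .nii or .nii.gz", call. = FALSE)
  img <- RNifti::asNifti(volume@grid)
  RNifti::pixdim(img) <- volume@spacing
  RNifti::writeNifti(img, path, datatype = "double")
  side <- list(
    calibrated = volume@calibrated,
    scannerID = volume@scannerID,
    spacing = volume@spacing,
    phantomROIs = lapply(volume@phantomROIs, function(r)
      list(indices = r$indices, nominal = r$nominal)),
    landmarks = volume@landmarks)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a QCT volume written by [writeVolume()]
#'
#' @param path Path ending in `.nii` or `.nii.gz`.
#' @return A [QCTVolume-class].
#' @export
readVolume <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("unrecognised volume format: use .nii or .nii.gz", call. = FALSE)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  sidePath <- paste0(path, ".json")
  side <- if (file.exists(sidePath))
    jsonlite::read_json(sidePath, simplifyVector = TRUE) else NULL
  spacing <- if (!is.null(side$spacing)) as.numeric(side$spacing)
             else as.numeric(RNifti::pixdim(img))[1:3]
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume spacing missing or invalid", call. = FALSE)
  rois <- list()
  if (!is.null(side$phantomROIs)) {
    pr <- side$phantomROIs
    nROI <- if (is.data.frame(pr)) nrow(pr) else length(pr)
    rois <- lapply(seq_len(nROI), function(i) {
      r <- if (is.data.frame(pr)) pr[i, ] else pr[[i]]
      list(indices = as.integer(unlist(r$indices)),
           nominal = as.numeric(r$nominal))
    })
  }
  lm <- if (!is.null(side$landmarks)) lapply(side$landmarks, unlist) else list()
  if (!is.null(lm$boneMask)) lm$boneMask <- as.integer(lm$boneMask)
  new("QCTVolume", grid = array(as.numeric(img), dim = dim(img)),
      spacing = spacing,
      calibrated = isTRUE(side$calibrated),
      phantomROIs = rois,
      scannerID = if (!is.null(side$scannerID)) side$scannerID else "unknown",
      landmarks = lm)
}

# known configuration schema and stage dependency table
.configKeys <- c("master_seed", "stages", "cohort", "subject", "voxel_mm",
                 "scanner", "flight", "dxa", "material", "solve",
                 "bone_threshold", "cutpoints", "pra")
.stageDeps <- list(simulate = character(), calibrate = "simulate",
                   fe = "calibrate", cutpoints = character(),
                   classify = c("fe", "cutpoints"), pra = "cutpoints",
                   report = character())

#' Default demo pipeline configuration
#'
#' Small, coarse-voxel settings that run the full chain in minutes on a
#' single core.
#'
#' @return Named list accepted by [runPipeline()].
#' @export
demoConfig <- function() {
  yaml::read_yaml(system.file("extdata", "demo_config.yaml",
                              package = "hipFE"))
}

.deriveStageSeed <- function(master, k) (master %% 1000000L) * 1000L + k

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order: `simulate` (synthetic cohorts,
#' demo-subject pre/post-flight QCT volumes), `calibrate` (phantom fit +
#' voxel calibration), `fe` (stance and fall load capacities pre and
#' post), `cutpoints` (percentile POLs from a synthetic fractured
#' reference cohort), `classify` (operating-band decisions for the demo
#' subject and the astronaut record cohort), `pra` (mission overload
#' table) and `report` (run manifest with file digests). Rerunning with
#' the same configuration and seed reproduces identical tables.
#'
#' @param config Path to a YAML configuration or an equivalent named
#'   list; see [demoConfig()].
#' @param outDir Output directory (created if needed).
#' @param seed Optional master-seed override.
#' @return The run manifest, invisibly (also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(config = demoConfig(), outDir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  bad <- setdiff(names(config), .configKeys)
  if (length(bad))
    stop("config error: unknown keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  stages <- config$stages
  if (is.null(stages)) stages <- names(.stageDeps)
  unknown <- setdiff(stages, names(.stageDeps))
  if (length(unknown))
    stop("config error: unknown stages: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (st in stages) {
    miss <- setdiff(.stageDeps[[st]], stages)
    if (length(miss))
      stop("config error: stage '", st, "' requires ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  master <- if (!is.null(seed)) seed else config$master_seed
  if (is.null(master)) master <- 1L
  master <- as.integer(master)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  cfgGet <- function(path, default) {
    x <- config
    for (k in path) {
      x <- x[[k]]
      if (is.null(x)) return(default)
    }
    x
  }
  seeds <- list(); outputs <- character()
  state <- new.env(parent = emptyenv())
  sv <- function(name, obj) assign(name, obj, envir = state)
  gv <- function(name) get(name, envir = state)
  writeCSV <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  writeJSON <- function(x, name) {
    p <- file.path(outDir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <<- c(outputs, p)
    p
  }

  if ("simulate" %in% stages) {
    s <- .deriveStageSeed(master, 1L); seeds$simulate <- s
    cohortName <- cfgGet(c("cohort", "name"), "astronaut")
    nCoh <- cfgGet(c("cohort", "n"), 8)
    cohort <- generateCohort(cohortName, n = nCoh, seed = s)
    demo <- data.frame(
      subject_id = vapply(cohort, function(p) p@subjectID, character(1)),
      age = vapply(cohort, function(p) p@age, numeric(1)),
      sex = vapply(cohort, function(p) p@sex, character(1)),
      height_cm = vapply(cohort, function(p) p@height, numeric(1)),
      weight_kg = vapply(cohort, function(p) p@weight, numeric(1)),
      cortical_density_gcc = vapply(cohort, function(p) p@corticalDensity,
                                    numeric(1)),
      trabecular_density_gcc = vapply(cohort, function(p) p@trabecularDensity,
                                      numeric(1)))
    writeCSV(demo, "demographics.csv")
    writeCSV(generateRecordCohort(cohortName, n = nCoh, seed = s + 1L),
             "cohort_records.csv")

    scanner <- scannerModel(
      scannerID = cfgGet(c("scanner", "id"), "scannerA"),
      huSlope = cfgGet(c("scanner", "hu_slope"), 1.2),
      huIntercept = cfgGet(c("scanner", "hu_intercept"), -15),
      noiseSD = cfgGet(c("scanner", "noise_sd"), 5))
    vox <- cfgGet("voxel_mm", 5)
    paramsPre <- cohort[[1]]
    paramsPost <- applyFlightEffect(
      paramsPre,
      lossModel = list(
        trabecular = cfgGet(c("flight", "trabecular_loss_pct_month"), 1.5),
        cortical = cfgGet(c("flight", "cortical_loss_pct_month"), 1.0)),
      duration = cfgGet(c("flight", "duration_days"), 154),
      seed = s + 2L)
    volPre <- generateVolume(paramsPre, scanner, voxelMM = vox, seed = s + 3L)
    volPost <- generateVolume(paramsPost, scanner, voxelMM = vox, seed = s + 4L)
    outputs <- c(outputs,
                 writeVolume(volPre, file.path(outDir, "subject_pre.nii.gz")),
                 writeVolume(volPost, file.path(outDir, "subject_post.nii.gz")))
    sv("volPre", volPre); sv("volPost", volPost)
  }

  if ("calibrate" %in% stages) {
    s <- .deriveStageSeed(master, 2L); seeds$calibrate <- s
    fit <- fitPhantomCalibration(gv("volPre"))
    writeJSON(list(slope = fit@slope, intercept = fit@intercept,
                   r_squared = fit@rSquared, rod_table = fit@rodTable),
              "calibration.json")
    sv("calPre", applyCalibration(gv("volPre"), fit))
    sv("calPost", applyCalibration(gv("volPost"),
                                   fitPhantomCalibration(gv("volPost"))))
  }

  if ("fe" %in% stages) {
    s <- .deriveStageSeed(master, 3L); seeds$fe <- s
    material <- materialModel()
    scfg <- solveConfig(
      displacementIncrement = cfgGet(c("solve", "displacement_increment_mm"),
                                     0.3),
      maxSteps = cfgGet(c("solve", "max_steps"), 18),
      dropFraction = cfgGet(c("solve", "drop_fraction"), 0.05))
    thr <- cfgGet("bone_threshold", 200)
    runs <- list(
      pre_NLS = runConfiguration(gv("calPre"), "NLS", material, scfg,
                                 boneThreshold = thr),
      pre_NLF = runConfiguration(gv("calPre"), "NLF", material, scfg,
                                 boneThreshold = thr),
      post_NLS = runConfiguration(gv("calPost"), "NLS", material, scfg,
                                  boneThreshold = thr),
      post_NLF = runConfiguration(gv("calPost"), "NLF", material, scfg,
                                  boneThreshold = thr))
    writeJSON(lapply(runs, function(r)
      list(configuration = r@configuration,
           load_capacity_N = r@loadCapacity,
           stopped_reason = r@stoppedReason)), "fe_results.json")
    fd <- do.call(rbind, lapply(names(runs), function(nm) {
      h <- forceDisplacement(runs[[nm]])
      cbind(run = nm, h)
    }))
    writeCSV(fd, "force_displacement.csv")
    sv("feRuns", runs)
  }

  if ("cutpoints" %in% stages) {
    s <- .deriveStageSeed(master, 4L); seeds$cutpoints <- s
    refCohort <- cfgGet(c("cutpoints", "cohort"), "AGES_fractured")
    nRef <- cfgGet(c("cutpoints", "n"), 2000)
    q <- cfgGet(c("cutpoints", "percentile"), 75)
    ref <- generateRecordCohort(refCohort, n = nRef, seed = s)
    band <- riskBandConfig(polNLS = derivePOL(ref$f_nls, q),
                           polNLF = derivePOL(ref$f_nlf, q),
                           percentileQ = q)
    writeJSON(list(reference_cohort = refCohort, n = nRef, percentile = q,
                   pol_nls_N = band@polNLS, pol_nlf_N = band@polNLF,
                   percentile_definition = "linear interpolation between closest ranks"),
              "cutpoints.json")
    sv("band", band)
  }

  if ("classify" %in% stages) {
    s <- .deriveStageSeed(master, 5L); seeds$classify <- s
    band <- gv("band"); runs <- gv("feRuns")
    refMean <- cfgGet(c("dxa", "ref_mean"), 0.94)
    refSD <- cfgGet(c("dxa", "ref_sd"), 0.12)
    dxaPre <- projectDXA(gv("calPre"), refMean = refMean, refSD = refSD)
    dxaPost <- projectDXA(gv("calPost"), refMean = refMean, refSD = refSD)
    pre <- classifyPreflight(tScore(dxaPre), runs$pre_NLS@loadCapacity, band)
    post <- classifyPostflight(
      tScore(dxaPost), runs$post_NLS@loadCapacity,
      runs$post_NLF@loadCapacity,
      list(fNLSpre = runs$pre_NLS@loadCapacity,
           fNLFpre = runs$pre_NLF@loadCapacity), band)
    writeCSV(data.frame(
      phase = c("pre", "post"),
      t_score = c(tScore(dxaPre), tScore(dxaPost)),
      abmd = c(aBMD(dxaPre), aBMD(dxaPost)),
      f_nls = c(runs$pre_NLS@loadCapacity, runs$post_NLS@loadCapacity),
      f_nlf = c(runs$pre_NLF@loadCapacity, runs$post_NLF@loadCapacity),
      quadrant = c(pre@quadrant, post@quadrant),
      preflight_decision = c(pre@preflightDecision, NA),
      below_t_pol = c(NA, post@postflightFlags[["below_t_pol"]]),
      below_fe_pol_nls = c(NA, post@postflightFlags[["below_fe_pol_nls"]]),
      below_fe_pol_nlf = c(NA, post@postflightFlags[["below_fe_pol_nlf"]]),
      significant_loss_nls = c(NA,
        post@postflightFlags[["significant_loss_nls"]]),
      significant_loss_nlf = c(NA,
        post@postflightFlags[["significant_loss_nlf"]])),
      "classification.csv")

    ast <- generateRecordCohort("astronaut",
                                n = cfgGet(c("cohort", "n"), 8), seed = s)
    rows <- lapply(seq_len(nrow(ast)), function(i) {
      cl <- classifyPreflight(ast$t_score[i], ast$f_nls[i], band)
      po <- classifyPostflight(ast$t_score_post[i], ast$f_nls_post[i],
                               ast$f_nlf_post[i],
                               list(fNLSpre = ast$f_nls[i],
                                    fNLFpre = ast$f_nlf[i]), band)
      data.frame(subject_id = ast$subject_id[i],
                 preflight_decision = cl@preflightDecision,
                 quadrant_post = po@quadrant,
                 below_fe_pol_nlf = po@postflightFlags[["below_fe_pol_nlf"]])
    })
    writeCSV(do.call(rbind, rows), "classification_records.csv")
  }

  if ("pra" %in% stages) {
    s <- .deriveStageSeed(master, 6L); seeds$pra <- s
    cap <- if (exists("band", envir = state)) gv("band")@polNLF
           else riskBandConfig()@polNLF
    writeCSV(missionReport(capacityNLF = cap,
                           n = cfgGet(c("pra", "n"), 1e5), seed = s),
             "pra.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hipFE")),
    master_seed = master,
    stage_seeds = seeds,
    stages = stages,
    config = config,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p))),
    timestamp = format(Sys.time(), tz = "UTC"))
  if ("report" %in% stages)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
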