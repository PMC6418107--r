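# Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

# noiseless default-subject volume on a known scanner
noiselessVolume <- function() {
  if (is.null(.fx$nv))
    .fx$nv <- generateVolume(subjectParams(),
                             scannerModel(huSlope = 1.5, huIntercept = -20),
                             voxelMM = 5, seed = 11)
  .fx$nv
}

# calibrated femur volume with mild scanner noise (demo-scale)
calibratedFemur <- function() {
  if (is.null(.fx$cal)) {
    v <- generateVolume(subjectParams(),
                        scannerModel(huSlope = 1.2, huIntercept = -15,
                                     noiseSD = 5),
                        voxelMM = 5, seed = 11)
    .fx$cal <- applyCalibration(v, fitPhantomCalibration(v))
  }
  .fx$cal
}

# hand-built calibrated volume: uniform-density box, no landmarks
boxVolume <- function(dims = c(10, 4, 10), spacing = c(2, 2, 2),
                      density = 500) {
  new("QCTVolume", grid = array(density, dim = dims), spacing = spacing,
      calibrated = TRUE, phantomROIs = list(), scannerID = "box",
      landmarks = list())
}

solveCfgFemur <- function()
  solveConfig(displacementIncrement = 0.15, maxSteps = 30,
              dropFraction = 0.05)
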