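# Density-dependent bone material law.
#
# Each element follows a uniaxial four-region stress-strain curve:
# linear elastic to yield, perfectly plastic plateau, linear strain
# softening, residual plateau. Modulus and yield stress scale with
# equivalent mineral density through power laws. The published modelling
# lineage does not print its constants, so they are configuration here;
# the defaults are in the range used for QCT voxel models of the femur
# (modulus ~15 GPa and yield ~100 MPa at 1 g/cm^3).

#' Construct a density-parameterised material model
#'
#' @param modulusCoef,modulusExp E(rho) = modulusCoef * rho^modulusExp,
#'   MPa with rho in g/cm^3.
#' @param yieldCoef,yieldExp sy(rho) = yieldCoef * rho^yieldExp, MPa.
#' @param plateauStrain Length of the perfectly-plastic plateau beyond
#'   the yield strain (dimensionless). Expressed as a length rather than
#'   an absolute end-strain so the four regions stay well ordered at
#'   every density.
#' @param softeningRatio Magnitude of the softening slope as a fraction
#'   of E(rho).
#' @param residualFraction Residual stress as a fraction of the yield
#'   stress, in (0, 1]. 1 recovers an elastic-perfectly-plastic law.
#' @param poisson Poisson ratio.
#' @return A [MaterialModel-class].
#' @export
#' @examples
#' materialModel()
#' uniaxialStress(materialModel(), rho = 0.3, strain = c(0, 0.005, 0.02))
materialModel <- function(modulusCoef = 14900, modulusExp = 1.86,
                          yieldCoef = 102, yieldExp = 1.72,
                          plateauStrain = 0.004, softeningRatio = 1 / 3,
                          residualFraction = 0.3, poisson = 0.3) {
  new("MaterialModel", modulusCoef = modulusCoef, modulusExp = modulusExp,
      yieldCoef = yieldCoef, yieldExp = yieldExp,
      plateauStrain = plateauStrain, softeningRatio = softeningRatio,
      residualFraction = residualFraction, poisson = poisson)
}

#' Evaluate the per-density curve parameters
#'
#' @param model A [MaterialModel-class].
#' @param rho Equivalent mineral density, g/cm^3 (vectorised).
#' @return List with vectors `E`, `sy`, `epsYield`, `epsPlateauEnd`,
#'   `epsSofteningEnd` (strain where the residual plateau starts) and
#'   `residualStress`.
#' @export
materialCurveAt <- function(model, rho) {
  stopifnot(is(model, "MaterialModel"))
  E <- model@modulusCoef * rho^model@modulusExp
  sy <- model@yieldCoef * rho^model@yieldExp
  epsY <- ifelse(E > 0, sy / E, 0)
  eps1 <- epsY + model@plateauStrain
  Es <- model@softeningRatio * E
  eps2 <- eps1 + ifelse(Es > 0, (1 - model@residualFraction) * sy / Es, 0)
  list(E = E, sy = sy, epsYield = epsY, epsPlateauEnd = eps1,
       epsSofteningEnd = eps2, residualStress = model@residualFraction * sy)
}

#' Uniaxial stress at a given effective strain
#'
#' Piecewise evaluation of the four-region curve. Continuous and
#' non-negative; zero density gives zero stress.
#'
#' @param model A [MaterialModel-class].
#' @param rho Density g/cm^3 (scalar or vector matching `strain`).
#' @param strain Non-negative effective strain (vectorised).
#' @return Stress in MPa.
#' @export
uniaxialStress <- function(model, rho, strain) {
  stopifnot(is(model, "MaterialModel"))
  if (any(strain < 0)) stop("strain must be non-negative", call. = FALSE)
  n <- max(length(rho), length(strain))
  rho <- rep_len(rho, n); strain <- rep_len(strain, n)
  cv <- materialCurveAt(model, rho)
  Es <- model@softeningRatio * cv$E
  s <- numeric(n)
  el <- strain <= cv$epsYield
  s[el] <- cv$E[el] * strain[el]
  pl <- !el & strain <= cv$epsPlateauEnd
  s[pl] <- cv$sy[pl]
  so <- !el & !pl & strain <= cv$epsSofteningEnd
  s[so] <- cv$sy[so] - Es[so] * (strain[so] - cv$epsPlateauEnd[so])
  re <- strain > cv$epsSofteningEnd
  s[re] <- cv$residualStress[re]
  pmax(s, 0)
}
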