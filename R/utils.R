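#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so generators are pure functions of (inputs, seed)
#' without clobbering the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Truncated normal sampler
#'
#' Inverse-CDF sampling of N(mean, sd) restricted to [lower, upper].
#' Used for cohort demographics where summaries are reported as
#' mean +/- SD (range).
#'
#' @param n Number of draws.
#' @param mean,sd Normal parameters.
#' @param lower,upper Truncation bounds (may be -Inf/Inf).
#' @return Numeric vector of length `n`.
#' @keywords internal
rtruncn <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("'sd' must be non-negative", call. = FALSE)
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi <= plo) stop("empty truncation interval", call. = FALSE)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

#' von Mises effective strain from engineering strain components
#'
#' Distortion-energy equivalent strain, normalised so that a uniaxial
#' stress state with Poisson contraction nu maps to the axial strain.
#' Input rows are (exx, eyy, ezz, gxy, gyz, gzx) with engineering shears.
#'
#' @param eps Numeric matrix (m x 6) or length-6 vector.
#' @param nu Poisson ratio used for the normalisation.
#' @return Numeric vector of effective strains (non-negative).
#' @keywords internal
vonMisesStrain <- function(eps, nu) {
  if (is.null(dim(eps))) eps <- matrix(eps, nrow = 1L)
  dxy <- eps[, 1L] - eps[, 2L]
  dyz <- eps[, 2L] - eps[, 3L]
  dzx <- eps[, 3L] - eps[, 1L]
  sh <- eps[, 4L]^2 + eps[, 5L]^2 + eps[, 6L]^2
  sqrt(0.5 * (dxy^2 + dyz^2 + dzx^2) + 0.75 * sh) / (1 + nu)
}

# unit vector helper
unitVec <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("zero-length direction vector", call. = FALSE)
  v / nv
}

# "mean +/- sd (lo-hi)" formatting used by cohort summary tables
fmtSummary <- function(m, s, lo, hi, digits = 1) {
  sprintf("%.*f ± %.*f (%.*f–%.*f)",
          digits, m, digits, s, digits, lo, digits, hi)
}
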