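# Probabilistic risk assessment: mission- and event-class-specific
# applied hip-load distributions and the probability that an applied
# load exceeds an individual's fall load capacity.

#' Construct an applied-load distribution
#'
#' @param scenario "ISS", "Moon", "Mars" or "Earth_return".
#' @param eventClass "low_energy" (e.g. a trip and fall) or
#'   "high_energy" (e.g. a sports collision).
#' @param family "lognormal" (location = meanlog, scale = sdlog) or
#'   "normal" (location = mean N, scale = SD N).
#' @param location,scale Distribution parameters before gravity scaling.
#' @param gravityScale Multiplier on drawn loads, the scenario's
#'   gravitational loading relative to Earth.
#' @return A [LoadDistribution-class].
#' @export
loadDistribution <- function(scenario = "Earth_return",
                             eventClass = "low_energy",
                             family = "lognormal",
                             location = log(2500), scale = 0.34,
                             gravityScale = 1) {
  new("LoadDistribution", scenario = scenario, eventClass = eventClass,
      family = family, location = location, scale = scale,
      gravityScale = gravityScale)
}

# gravitational loading relative to Earth per scenario
.gravityScales <- c(ISS = 0.0, Moon = 0.165, Mars = 0.38, Earth_return = 1.0)

# base (Earth) load-distribution parameters per event class. These are
# placeholders calibrated qualitatively: low-energy mass concentrated in
# 1-4 kN, high-energy shifted upward; the source load model is not
# public. See the methods vignette.
.eventParams <- list(
  low_energy = c(location = log(2500), scale = 0.34),
  high_energy = c(location = log(4600), scale = 0.50))

#' Default mission scenario set
#'
#' Lognormal load distributions for every (scenario, event class) pair,
#' with Earth-calibrated parameters scaled by each scenario's
#' gravitational loading.
#'
#' @return Named list of [LoadDistribution-class] objects.
#' @export
defaultScenarioSet <- function() {
  out <- list()
  for (sc in names(.gravityScales)) for (ev in names(.eventParams)) {
    p <- .eventParams[[ev]]
    out[[paste(sc, ev, sep = ".")]] <- loadDistribution(
      scenario = sc, eventClass = ev, family = "lognormal",
      location = p[["location"]], scale = p[["scale"]],
      gravityScale = .gravityScales[[sc]])
  }
  out
}

#' Sample applied hip loads
#'
#' @param dist A [LoadDistribution-class].
#' @param n Number of draws (> 0).
#' @param seed Integer seed.
#' @return Numeric vector of loads, N (i.i.d. draws scaled by the
#'   scenario's gravity factor).
#' @export
sampleLoads <- function(dist, n, seed = 1) {
  stopifnot(is(dist, "LoadDistribution"))
  if (n <= 0) stop("'n' must be positive", call. = FALSE)
  withSeed(seed, {
    raw <- switch(dist@family,
      normal = stats::rnorm(n, dist@location, dist@scale),
      lognormal = stats::rlnorm(n, dist@location, dist@scale),
      stop("invalid family", call. = FALSE))
    dist@gravityScale * raw
  })
}

#' Probability that the applied load exceeds a load capacity
#'
#' For the normal and lognormal families the tail probability
#' P(gravityScale * X > capacity) is available in closed form and is
#' returned by default; `method = "monte_carlo"` estimates it by
#' simulation instead (retained as a cross-check), reporting the
#' binomial standard error sqrt(p(1-p)/n).
#'
#' @param dist A [LoadDistribution-class].
#' @param capacity Load capacity, N (> 0).
#' @param n Monte-Carlo sample count.
#' @param seed Integer seed (Monte Carlo only).
#' @param method "closed_form" or "monte_carlo".
#' @return An [OverloadResult-class].
#' @export
#' @examples
#' d <- loadDistribution(family = "normal", location = 3000, scale = 500)
#' overloadProb(overloadProbability(d, capacity = 3664))
overloadProbability <- function(dist, capacity, n = 1e5, seed = 1,
                                method = c("closed_form", "monte_carlo")) {
  stopifnot(is(dist, "LoadDistribution"))
  method <- match.arg(method)
  if (capacity <= 0) stop("'capacity' must be positive", call. = FALSE)
  if (method == "closed_form") {
    p <- if (dist@gravityScale == 0) {
      0    # degenerate: all loads are zero
    } else {
      thr <- capacity / dist@gravityScale
      switch(dist@family,
        normal = stats::pnorm(thr, dist@location, dist@scale,
                              lower.tail = FALSE),
        lognormal = stats::plnorm(thr, dist@location, dist@scale,
                                  lower.tail = FALSE))
    }
    new("OverloadResult", probability = p, mcStandardError = NA_real_,
        nSamples = NA_real_, capacityUsed = capacity,
        method = "closed_form")
  } else {
    loads <- sampleLoads(dist, n, seed)
    p <- mean(loads > capacity)
    new("OverloadResult", probability = p,
        mcStandardError = sqrt(p * (1 - p) / n), nSamples = n,
        capacityUsed = capacity, method = "monte_carlo")
  }
}

#' Factor of risk
#'
#' Ratio of applied load to load capacity; values above 1 indicate an
#' expected overload.
#'
#' @param appliedLoad,capacity N; capacity must be positive.
#' @return Dimensionless ratio (vectorised).
#' @export
#' @examples
#' factorOfRisk(4000, 3664)
factorOfRisk <- function(appliedLoad, capacity) {
  if (any(capacity <= 0)) stop("'capacity' must be positive", call. = FALSE)
  appliedLoad / capacity
}

#' Mission overload report
#'
#' Overload probabilities for every (scenario, event class) pair in the
#' scenario set, evaluated at a given fall load capacity (by default the
#' fall-configuration POL cut-point, mirroring how the risk chart is
#' constructed). With the default gravity scalings, reduced-gravity
#' scenarios give lower overload probabilities than Earth return for the
#' same event class.
#'
#' @param capacityNLF Fall load capacity, N.
#' @param scenarioSet List of [LoadDistribution-class] objects.
#' @param n Monte-Carlo sample count for the cross-check column.
#' @param seed Integer seed.
#' @return data.frame with one row per (scenario, event class):
#'   closed-form probability, Monte-Carlo estimate, standard error, n.
#' @export
missionReport <- function(capacityNLF = riskBandConfig()@polNLF,
                          scenarioSet = defaultScenarioSet(),
                          n = 1e5, seed = 1) {
  rows <- lapply(seq_along(scenarioSet), function(i) {
    d <- scenarioSet[[i]]
    cf <- overloadProbability(d, capacityNLF, method = "closed_form")
    mc <- overloadProbability(d, capacityNLF, n = n, seed = seed + i,
                              method = "monte_carlo")
    data.frame(scenario = d@scenario, event_class = d@eventClass,
               probability = cf@probability,
               probability_mc = mc@probability,
               mc_se = mc@mcStandardError, n = n,
               capacity_N = capacityNLF,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
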