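# Percentile cut-points (permissible outcome limits), combined DXA /
# FE operating-band classification, change metrics and the summary
# statistics used for cohort tables.

#' Construct the operating-band configuration
#'
#' Defaults encode the recommended standards: load-capacity POLs of
#' 9537 N (stance) and 3664 N (fall) set at the 75th percentile of the
#' fractured reference cohort, the DXA certification cut at T = -1.0
#' with a secondary FE screening band down to T = -1.5, the post-flight
#' DXA POL at T = -2.0, and least-significant-change thresholds of 3.6%
#' (NLS) and 11.3% (NLF).
#'
#' @param polNLS,polNLF Load-capacity cut-points, N.
#' @param tPreflight,tScreenFloor,tPostflightPOL T-score cut-points.
#' @param lscNLS,lscNLF Least significant change, percent.
#' @param percentileQ Percentile used by [derivePOL()].
#' @param alpha Significance level for the correlation test.
#' @return A [RiskBandConfig-class].
#' @export
riskBandConfig <- function(polNLS = 9537, polNLF = 3664,
                           tPreflight = -1.0, tScreenFloor = -1.5,
                           tPostflightPOL = -2.0,
                           lscNLS = 3.6, lscNLF = 11.3,
                           percentileQ = 75, alpha = 0.05) {
  new("RiskBandConfig", polNLS = polNLS, polNLF = polNLF,
      tPreflight = tPreflight, tScreenFloor = tScreenFloor,
      tPostflightPOL = tPostflightPOL, lscNLS = lscNLS, lscNLF = lscNLF,
      percentileQ = percentileQ, alpha = alpha)
}

#' Derive a percentile cut-point from cohort load capacities
#'
#' The q-th percentile with linear interpolation between closest ranks:
#' for sorted values x(1) <= ... <= x(n), the percentile sits at rank
#' 1 + (n - 1) q/100 and is interpolated linearly between the
#' neighbouring order statistics. Applied to a fractured reference
#' cohort this yields the permissible outcome limit.
#'
#' @param values Numeric load capacities, N (>= 4 values).
#' @param q Percentile in (0, 100).
#' @return The cut-point, N.
#' @export
#' @examples
#' derivePOL(1:100, q = 75)   # 75.25
derivePOL <- function(values, q = 75) {
  if (length(values) < 4L)
    stop("need at least 4 values to derive a percentile cut-point",
         call. = FALSE)
  if (q <= 0 || q >= 100) stop("'q' must be in (0, 100)", call. = FALSE)
  x <- sort(values)
  h <- 1 + (length(x) - 1) * q / 100
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

.quadrant <- function(tScore, f, tCut, fCut) {
  if (tScore >= tCut && f >= fCut) "pass_both"
  else if (tScore >= tCut) "dxa_only"
  else if (f >= fCut) "fe_only"
  else "fail_both"
}

#' Pre-flight certification decision
#'
#' Subjects at or above the DXA T-score standard are certified. Subjects
#' in the screening band (below the standard but above the screening
#' floor) progress via the FE stance capacity: at or above the stance
#' POL they are certified, otherwise not. At or below the screening
#' floor the subject is not certified regardless of FE capacity.
#' Boundary convention: values equal to a cut-point pass it.
#'
#' @param tScore DXA total-hip T-score.
#' @param fNLS Stance load capacity, N.
#' @param cfg A [RiskBandConfig-class].
#' @return A [Classification-class] with the pre-flight decision and the
#'   T-score vs stance-capacity quadrant.
#' @export
#' @examples
#' classifyPreflight(-1.2, 10000, riskBandConfig())  # certified via FE screen
classifyPreflight <- function(tScore, fNLS, cfg = riskBandConfig()) {
  stopifnot(is.finite(tScore), is.finite(fNLS))
  decision <-
    if (tScore >= cfg@tPreflight) "certified"
    else if (tScore > cfg@tScreenFloor) {
      if (fNLS >= cfg@polNLS) "screen_with_fe_passed" else "not_certified"
    } else "not_certified"
  new("Classification",
      quadrant = .quadrant(tScore, fNLS, cfg@tPreflight, cfg@polNLS),
      preflightDecision = decision,
      postflightFlags = logical(0))
}

#' Post-flight operating-band flags
#'
#' Flags a post-flight measurement against the permissible outcome
#' limits (DXA T-score POL and the FE stance/fall POLs) and, given the
#' pre-flight record, marks losses exceeding the configuration's least
#' significant change.
#'
#' @param tScore Post-flight T-score.
#' @param fNLS,fNLF Post-flight load capacities, N.
#' @param pre A [SubjectRecord-class], or a named list with `fNLSpre`
#'   and `fNLFpre`, providing the pre-flight capacities.
#' @param cfg A [RiskBandConfig-class].
#' @return A [Classification-class]; `postflightFlags` holds
#'   `below_t_pol`, `below_fe_pol_nls`, `below_fe_pol_nlf`,
#'   `significant_loss_nls`, `significant_loss_nlf`.
#' @export
classifyPostflight <- function(tScore, fNLS, fNLF, pre,
                               cfg = riskBandConfig()) {
  if (is(pre, "SubjectRecord")) {
    preNLS <- pre@fNLSpre; preNLF <- pre@fNLFpre
  } else {
    preNLS <- pre$fNLSpre; preNLF <- pre$fNLFpre
  }
  chNLS <- significantChange(preNLS, fNLS, cfg@lscNLS)
  chNLF <- significantChange(preNLF, fNLF, cfg@lscNLF)
  flags <- c(
    below_t_pol = tScore < cfg@tPostflightPOL,
    below_fe_pol_nls = fNLS < cfg@polNLS,
    below_fe_pol_nlf = fNLF < cfg@polNLF,
    significant_loss_nls = chNLS$significant && chNLS$relativeChange < 0,
    significant_loss_nlf = chNLF$significant && chNLF$relativeChange < 0)
  new("Classification",
      quadrant = .quadrant(tScore, fNLS, cfg@tPreflight, cfg@polNLS),
      preflightDecision = "not_applicable",
      postflightFlags = flags)
}

#' Relative change against a least-significant-change threshold
#'
#' @param pre,post Values in the same units; `pre` must be positive.
#' @param lscPercent Least significant change, percent.
#' @return List with `relativeChange` (percent, signed) and
#'   `significant` (TRUE when |change| strictly exceeds the LSC).
#' @export
#' @examples
#' significantChange(14279, 13624, 3.6)
significantChange <- function(pre, post, lscPercent) {
  if (!is.finite(pre) || pre <= 0)
    stop("'pre' must be positive", call. = FALSE)
  rel <- 100 * (post - pre) / pre
  list(relativeChange = rel, significant = abs(rel) > lscPercent)
}

#' Simple linear regression R-squared and correlation test
#'
#' Coefficient of determination from the least-squares line of y on x,
#' with the two-sided p-value for the null hypothesis of zero
#' correlation (t-test on n - 2 degrees of freedom).
#'
#' @param x,y Numeric vectors, length >= 3; x must vary.
#' @return List with `rSquared`, `pValue` and `n`.
#' @export
regressR2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need matched x/y with n >= 3", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot else 1
  list(rSquared = r2, pValue = ct$p.value, n = length(x))
}

#' Cohort summary in mean +/- SD (range) form
#'
#' @param records data.frame of per-subject values.
#' @param variables Columns to summarise; defaults to all numeric
#'   columns.
#' @return data.frame with columns `variable`, `mean`, `sd`, `min`,
#'   `max`, `formatted`.
#' @export
summarizeCohort <- function(records, variables = NULL) {
  if (!nrow(records)) stop("empty cohort", call. = FALSE)
  if (is.null(variables))
    variables <- names(records)[vapply(records, is.numeric, logical(1))]
  rows <- lapply(variables, function(v) {
    x <- records[[v]]
    s <- if (length(x) > 1) stats::sd(x) else 0
    data.frame(variable = v, mean = mean(x), sd = s,
               min = min(x), max = max(x),
               formatted = fmtSummary(mean(x), s, min(x), max(x)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Welch's t-test comparison between two cohorts' capacities
#'
#' Used for astronaut-vs-population load-capacity comparisons (the
#' population study does not name its test; Welch's unequal-variance
#' t-test is applied here and labelled as such).
#'
#' @param x,y Numeric capacity vectors.
#' @return List with `pValue`, `meanX`, `meanY`.
#' @export
compareCohorts <- function(x, y) {
  tt <- stats::t.test(x, y)
  list(pValue = tt$p.value, meanX = mean(x), meanY = mean(y))
}
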