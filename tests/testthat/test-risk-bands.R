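test_that("percentile cut-point uses linear rank interpolation", {
  expect_equal(derivePOL(1:100, q = 75), 75.25, tolerance = 1e-12)
  expect_equal(derivePOL(rep(7, 10), q = 75), 7)
  expect_error(derivePOL(1:3), "at least 4")
  expect_error(derivePOL(1:10, q = 0), "in \\(0, 100\\)")
  # independent oracle: stats::quantile type 7 on random vectors
  set.seed(17)
  for (i in 1:50) {
    x <- rnorm(sample(4:60, 1), sd = 1000)
    q <- runif(1, 1, 99)
    expect_equal(derivePOL(x, q),
                 unname(quantile(x, q / 100, type = 7)), tolerance = 1e-12)
  }
})

test_that("percentile is equivariant under positive affine maps", {
  set.seed(3)
  x <- rlnorm(200, 8, 0.4)
  p <- derivePOL(x, 75)
  expect_equal(derivePOL(3.5 * x + 100, 75), 3.5 * p + 100,
               tolerance = 1e-9)
})

test_that("pre-flight certification matches the operating bands", {
  cfg <- riskBandConfig()
  expect_identical(classifyPreflight(0.97, 14279, cfg)@preflightDecision,
                   "certified")
  expect_identical(classifyPreflight(-1.2, 10000, cfg)@preflightDecision,
                   "screen_with_fe_passed")
  expect_identical(classifyPreflight(-1.2, 9000, cfg)@preflightDecision,
                   "not_certified")
  expect_identical(classifyPreflight(-1.6, 20000, cfg)@preflightDecision,
                   "not_certified")
  # boundary conventions: cut-point values pass, the screen floor does not
  expect_identical(classifyPreflight(-1.0, 5000, cfg)@preflightDecision,
                   "certified")
  expect_identical(classifyPreflight(-1.5, 20000, cfg)@preflightDecision,
                   "not_certified")
  expect_identical(classifyPreflight(-1.2, 9537, cfg)@preflightDecision,
                   "screen_with_fe_passed")
})

test_that("classification decisions are monotone in T-score and capacity", {
  cfg <- riskBandConfig()
  rank <- c(not_certified = 0, screen_with_fe_passed = 1, certified = 2)
  ts <- c(-2, -1.5, -1.4, -1.0, -0.5, 1)
  fs <- c(5000, 9537, 12000)
  for (f in fs) {
    d <- rank[vapply(ts, function(t)
      classifyPreflight(t, f, cfg)@preflightDecision, character(1))]
    expect_true(all(diff(d) >= 0))
  }
  for (t in ts) {
    d <- rank[vapply(fs, function(f)
      classifyPreflight(t, f, cfg)@preflightDecision, character(1))]
    expect_true(all(diff(d) >= 0))
  }
})

test_that("post-flight flags respect the POLs and the LSC", {
  cfg <- riskBandConfig()
  pre <- list(fNLSpre = 14279, fNLFpre = 4037)
  cl <- classifyPostflight(0.74, 13624, 3488, pre, cfg)
  expect_true(cl@postflightFlags[["below_fe_pol_nlf"]])   # 3488 < 3664
  expect_false(cl@postflightFlags[["below_fe_pol_nls"]])  # 13624 > 9537
  expect_false(cl@postflightFlags[["below_t_pol"]])       # 0.74 > -2
  # -4.59% NLS change exceeds the 3.6% LSC; -13.6% NLF exceeds 11.3%
  expect_true(cl@postflightFlags[["significant_loss_nls"]])
  expect_true(cl@postflightFlags[["significant_loss_nlf"]])
  # a -2.8% NLF change stays inside the 11.3% LSC
  cl2 <- classifyPostflight(0.74, 14000, 3925, pre, cfg)
  expect_false(cl2@postflightFlags[["significant_loss_nlf"]])
  # unchanged record raises no flags
  cl0 <- classifyPostflight(0.97, 14279, 4037, pre, cfg)
  expect_false(any(cl0@postflightFlags))
})

test_that("below-POL fraction equals the empirical CDF at the POL", {
  cfg <- riskBandConfig()
  r <- generateRecordCohort("AGES_fractured", n = 500, seed = 21)
  flagged <- vapply(seq_len(nrow(r)), function(i)
    classifyPostflight(r$t_score[i], r$f_nls[i], r$f_nlf[i],
                       list(fNLSpre = r$f_nls[i], fNLFpre = r$f_nlf[i]),
                       cfg)@postflightFlags[["below_fe_pol_nlf"]],
    logical(1))
  expect_equal(mean(flagged), stats::ecdf(r$f_nlf)(cfg@polNLF - 1e-9))
})

test_that("significant change uses signed percent and a strict threshold", {
  ch <- significantChange(14279, 13624, 3.6)
  expect_equal(ch$relativeChange, 100 * (13624 - 14279) / 14279,
               tolerance = 1e-12)
  expect_true(ch$significant)
  expect_false(significantChange(100, 103.6, 3.6)$significant)  # exactly LSC
  expect_false(significantChange(100, 100, 3.6)$significant)
  expect_error(significantChange(0, 10, 3.6), "positive")
})

test_that("regression R^2 and correlation test match first principles", {
  x <- 1:10
  expect_equal(regressR2(x, 2 * x - 3)$rSquared, 1, tolerance = 1e-12)
  set.seed(8)
  xs <- rnorm(40); ys <- 0.5 * xs + rnorm(40)
  out <- regressR2(xs, ys)
  expect_equal(out$rSquared, cor(xs, ys)^2, tolerance = 1e-12)
  r <- cor(xs, ys); tstat <- r * sqrt(38 / (1 - r^2))
  expect_equal(out$pValue, 2 * pt(-abs(tstat), 38), tolerance = 1e-10)
  expect_error(regressR2(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(regressR2(1:2, 1:2), "n >= 3")
})

test_that("cohort summaries reproduce mean +/- SD (range) per column", {
  df <- data.frame(age = c(40, 50, 60), w = c(70, 80, 90))
  s <- summarizeCohort(df)
  expect_equal(s$mean, c(50, 80))
  expect_equal(s$sd, c(10, 10))
  expect_equal(s$min, c(40, 70)); expect_equal(s$max, c(60, 90))
  expect_match(s$formatted[1], "50.0 ± 10.0 \\(40.0–60.0\\)")
  one <- summarizeCohort(data.frame(x = 5))
  expect_equal(one$sd, 0); expect_equal(one$min, one$max)
  expect_error(summarizeCohort(data.frame()), "empty")
})

test_that("cohort comparison detects a true mean difference", {
  a <- generateRecordCohort("astronaut", n = 200, seed = 4)$f_nls
  m <- generateRecordCohort("Mayo_male", n = 200, seed = 5)$f_nls
  cmp <- compareCohorts(a, m)
  expect_lt(cmp$pValue, 0.05)
  expect_gt(cmp$meanX, cmp$meanY)
})
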