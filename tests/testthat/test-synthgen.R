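test_that("configuration validation enforces stochasticity and Nyquist", {
  bad <- defaultTransitionMatrix("baseline")
  bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(syntheticConfig(transitionBaseline = bad), "row-stochastic")
  expect_error(syntheticConfig(thetaFreqHz = 80, fsHz = 152), "Nyquist")
  expect_error(syntheticConfig(aversionGain = 1.5))
  cfg <- syntheticConfig()
  expect_s3_class(cfg, "SyntheticConfig")
  expect_equal(rowSums(cfg$transitionBaseline), rep(1, 7),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- syntheticConfig(seed = 42, nFlies = 2, nTrialsPerFly = 4)
  c1 <- genBehaviorCohort(cfg)
  c2 <- genBehaviorCohort(cfg)
  expect_identical(c1$tracking, c2$tracking)
  expect_identical(c1$labels, c2$labels)

  ce1 <- genCalciumCohort(cfg, nCells = 8)
  ce2 <- genCalciumCohort(cfg, nCells = 8)
  expect_identical(SummarizedExperiment::assay(ce1, "F"),
                   SummarizedExperiment::assay(ce2, "F"))

  d1 <- genClassifierDataset(5, classes = c("walking", "grooming"), seed = 7)
  d2 <- genClassifierDataset(5, classes = c("walking", "grooming"), seed = 7)
  expect_identical(d1$x, d2$x)
  d3 <- genClassifierDataset(5, classes = c("walking", "grooming"), seed = 8)
  expect_false(identical(d1$x, d3$x))
})

test_that("long baseline runs recover the stationary state distribution", {
  P <- defaultTransitionMatrix("baseline")
  pi0 <- stationaryDistribution(P)
  n <- 60000
  chain <- withr::with_seed(5, flygate:::sampleMarkov(n, P, start = 3L))
  freq <- tabulate(chain, 7) / n
  # effective sample size is reduced by chain autocorrelation; with
  # P = 0.9 I + 0.1 1w', lag-1 autocorrelation is 0.9 -> ESS ~ n / 19
  ess <- n * (1 - 0.9) / (1 + 0.9)
  for (s in 1:7) {
    se <- sqrt(pi0[s] * (1 - pi0[s]) / ess)
    expect_lt(abs(freq[s] - pi0[s]), 3 * se)
  }
  # analytic stationary distribution of the rank-one construction is the
  # target weight vector itself
  expect_equal(unname(pi0), unname(P[1, ] * 0 +
    c(0.40, 0.05, 0.38, 0.12, 0.02, 0.02, 0.01)), tolerance = 1e-9)
})

test_that("the aversive gate biases walking and scales with gain", {
  # gain 1, deterministic walking: trajectory moves monotonically away
  cfg1 <- syntheticConfig(seed = 2, nFlies = 1, nTrialsPerFly = 2,
                          aversionGain = 1,
                          walkSpeedMeanSd = c(1, 0),
                          transitionPostpuff = {
                            P <- diag(7); dimnames(P) <- list(behaviorStates(),
                                                              behaviorStates())
                            P[, ] <- 0; P[, 4] <- 1; P
                          })
  coh <- genBehaviorCohort(cfg1)
  plus <- coh$tracking[coh$tracking$condition == "puff+", ]
  for (tr in unique(plus$trial)) {
    d <- plus[plus$trial == tr, ]
    expect_true(all(d$dx * d$object_side <= 0))
    ai <- avoidanceIndex(sum(abs(d$dx[d$dx * d$object_side < 0])),
                         sum(abs(d$dx[d$dx * d$object_side > 0])))
    expect_equal(ai, 1.0)
  }

  # zero gain: cohort-mean delta AI is indistinguishable from 0
  cfg0 <- syntheticConfig(seed = 8, nFlies = 12, nTrialsPerFly = 6,
                          aversionGain = 0)
  run0 <- avoidanceTable(genBehaviorCohort(cfg0))
  ok <- run0[is.finite(run0$ai), ]
  fm <- stats::aggregate(ai ~ fly_id + condition, ok, mean)
  names(fm)[3] <- "mean_ai"
  both <- names(which(table(fm$fly_id) == 2L))
  d0 <- deltaAvoidance(fm[fm$fly_id %in% both, ])
  se <- sd(d0$delta_ai) / sqrt(nrow(d0))
  expect_lt(abs(mean(d0$delta_ai)), 2 * se + 1e-12)
})

test_that("the exponential gate mode runs and still biases gated walking", {
  cfg <- syntheticConfig(seed = 17, nFlies = 4, nTrialsPerFly = 4,
                         aversionGain = 1, gateMode = "exponential")
  tab <- avoidanceTable(genBehaviorCohort(cfg))
  tab <- tab[is.finite(tab$ai), ]
  expect_gt(mean(tab$ai[tab$condition == "puff+"]),
            mean(tab$ai[tab$condition == "puff-"]))
  # deterministic like the binary mode
  t2 <- avoidanceTable(genBehaviorCohort(cfg))
  expect_identical(tab$ai, t2$ai[is.finite(t2$ai)])
})

test_that("expected delta AI is non-decreasing in the aversion gain", {
  meanDelta <- vapply(c(0, 0.3, 0.6, 1.0), function(g) {
    cfg <- syntheticConfig(seed = 31, nFlies = 10, nTrialsPerFly = 6,
                           aversionGain = g)
    tab <- avoidanceTable(genBehaviorCohort(cfg))
    tab <- tab[is.finite(tab$ai), ]
    fm <- stats::aggregate(ai ~ fly_id + condition, tab, mean)
    names(fm)[3] <- "mean_ai"
    both <- names(which(table(fm$fly_id) == 2L))
    mean(deltaAvoidance(fm[fm$fly_id %in% both, ])$delta_ai)
  }, numeric(1))
  expect_true(all(diff(meanDelta) > 0))
})

test_that("calcium cohorts honor the responder fraction and construction", {
  cfg <- syntheticConfig(seed = 11)
  ce <- genCalciumCohort(cfg, nCells = 200)
  nResp <- sum(SummarizedExperiment::rowData(ce)$responder)
  ci <- qbinom(c(0.005, 0.995), 200, 0.64)
  expect_gte(nResp, ci[1])
  expect_lte(nResp, ci[2])

  # noiseless single responder, 10 puffs at 5 %/puff: peak dF/F0 = 50 %
  ev <- data.frame(kind = c("rest", "puff", "rest"),
                   t_on_s = c(0, 5, 15), t_off_s = c(5, 15, 25),
                   gated = FALSE)
  oneBlock <- methods::new("StimulusSchedule", events = ev)
  cfgClean <- syntheticConfig(seed = 1, noiseSd = 0, responderFraction = 1,
                              thetaAmp = 0)
  ce1 <- genCalciumCohort(cfgClean, nCells = 1, schedule = oneBlock)
  dff <- deltaFOverF(ce1)
  expect_equal(max(SummarizedExperiment::assay(dff, "dff")), 50,
               tolerance = 1e-9)
  # decay returns near baseline roughly 10 s after puff offset
  t <- frameTimes(ce1)
  tail10 <- SummarizedExperiment::assay(dff, "dff")[1, t > 24.9]
  expect_lt(max(tail10), 0.02 * 50)

  # non-responders carry noise only
  cfgNR <- syntheticConfig(seed = 4, responderFraction = 0, noiseSd = 0,
                           thetaAmp = 0)
  ceNR <- genCalciumCohort(cfgNR, nCells = 3)
  expect_equal(max(abs(SummarizedExperiment::assay(ceNR, "F") - 100)), 0)

  expect_error(genCalciumCohort(cfg, nCells = 0), "positive")
})

test_that("theta appears only in gated visual windows of responder cells", {
  cfgT <- syntheticConfig(seed = 6, noiseSd = 0, responderFraction = 1,
                          puffRiseRate = 0)
  ce <- genCalciumCohort(cfgT, nCells = 2)
  ev <- eventTable(ce)
  t <- frameTimes(ce)
  dff <- SummarizedExperiment::assay(ce, "F") - 100
  gated <- ev[ev$kind == "visual" & ev$gated, ]
  pre <- ev[ev$kind == "visual" & !ev$gated, ]
  inG <- t >= gated$t_on_s[1] & t < gated$t_off_s[1]
  inP <- t >= pre$t_on_s[1] & t < pre$t_off_s[1]
  expect_gt(sd(dff[1, inG]), 1)
  expect_equal(sd(dff[1, inP]), 0)
  # zero-theta configuration leaves gated windows silent too
  cfg0 <- syntheticConfig(seed = 6, noiseSd = 0, responderFraction = 1,
                          puffRiseRate = 0, thetaAmp = 0)
  ce0 <- genCalciumCohort(cfg0, nCells = 1)
  expect_equal(max(abs(SummarizedExperiment::assay(ce0, "F") - 100)), 0)
})

test_that("frame stacks round-trip traces and reject bad layouts", {
  traces <- matrix(seq(10, 100, length.out = 20), nrow = 1)
  layout <- data.frame(x = 16, y = 16, sigma = 2)
  movie <- genFrameStack(traces, layout, c(32, 32))
  m <- matrix(FALSE, 32, 32); m[10:22, 10:22] <- TRUE
  rec <- extractRoiTraces(movie, list(m))
  expect_gt(cor(rec[1, ], traces[1, ]), 0.99)
  # overlap and out-of-frame layouts error
  expect_error(genFrameStack(rbind(traces, traces),
                             data.frame(x = c(16, 17), y = c(16, 16),
                                        sigma = c(2, 2)), c(32, 32)),
               "overlap")
  expect_error(genFrameStack(traces, data.frame(x = 2, y = 16, sigma = 2),
                             c(32, 32)), "margin")
})

test_that("glyph datasets are balanced, jittered and size-checked", {
  ds <- genClassifierDataset(200, imageSize = c(16, 16), seed = 1,
                             noiseSd = 0)
  expect_equal(dim(ds$x)[1], 1400L)
  expect_equal(unname(table(ds$y)), rep(200L, 7), ignore_attr = TRUE)
  # within-class variance positive when jitter is on
  cls1 <- ds$x[ds$y == "walking", , , 1]
  expect_gt(sum(apply(cls1, c(2, 3), var)), 0)
  # jitter off and no noise: identical images within a class
  ds0 <- genClassifierDataset(3, classes = c("walking", "grooming"),
                              imageSize = c(16, 16), jitter = 0, noiseSd = 0)
  expect_equal(ds0$x[1, , , ], ds0$x[2, , , ])
  expect_error(genClassifierDataset(2, imageSize = c(8, 8)), "too small")
  expect_error(genClassifierDataset(2, classes = "walking"), "2 classes")
})
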