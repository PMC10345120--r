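test_that("asymmetry calibration recovers the per-frame bias and rejects short segments", {
  raw <- genTrackingRaw(60, 192, velocity = 0, asymmetry = 0.2)
  expect_equal(calibrateAsymmetry(raw), 0.2)
  corrected <- downsampleTrack(raw, profile = 0.2)
  expect_equal(mean(corrected$dx), 0, tolerance = 1e-12)

  # zero-mean noise over 3 min: estimate within 3 standard errors
  raw <- genTrackingRaw(180, 192, velocity = 0, noiseSd = 0.5, seed = 4)
  se <- 0.5 / sqrt(nrow(raw))
  expect_lt(abs(calibrateAsymmetry(raw)), 3 * se)

  expect_error(calibrateAsymmetry(genTrackingRaw(5, 192)), "10 s")
  expect_error(calibrateAsymmetry(data.frame(t_s = numeric(), dx = numeric())),
               "nonempty")
})

test_that("downsampling to 10 Hz conserves displacement and localizes impulses", {
  raw <- genTrackingRaw(1, 192, velocity = 1)
  tr <- downsampleTrack(raw)
  expect_equal(nrow(tr), 10L)
  expect_equal(tr$dx, rep(0.1, 10), tolerance = 1e-9)
  expect_equal(sum(tr$dx), sum(raw$dx), tolerance = 1e-6)

  # a velocity ramp still conserves total displacement
  raw <- genTrackingRaw(12, 192, velocity = function(t) sin(t) + 0.3)
  tr <- downsampleTrack(raw)
  expect_equal(sum(tr$dx), sum(raw$dx), tolerance = 1e-6)
  expect_equal(diff(tr$t_s), rep(0.1, nrow(tr) - 1), tolerance = 1e-9)

  # impulse at t = 0.05 lands in the first bin only
  raw <- genTrackingRaw(1, 192)
  raw$dx[raw$t_s > 0.045 & raw$t_s < 0.055] <- 1
  tr <- downsampleTrack(raw)
  expect_gt(tr$dx[1], 0.99)
  expect_equal(sum(abs(tr$dx[-1])), 0, tolerance = 1e-9)

  bad <- data.frame(t_s = c(0.1, 0.1, 0.3), dx = 0)
  expect_error(downsampleTrack(bad), "strictly increasing")
})

test_that("object-angle updates follow the sign convention and wrap", {
  cfg <- arenaConfig(gainDegPerUnit = 5)
  # leftward walking (dx < 0) shifts the object rightward
  expect_equal(updateObjectPosition(60, -1, cfg), 65)
  expect_equal(updateObjectPosition(60, 0, cfg), 60)
  expect_equal(updateObjectPosition(178, -1, cfg), -177)
  expect_true(all(updateObjectPosition(seq(-180, 179), 37.3, cfg) >= -180))
  expect_true(all(updateObjectPosition(seq(-180, 179), 37.3, cfg) < 180))
  expect_true(objectVisible(135))
  expect_false(objectVisible(-136))
})

test_that("object specs carry the paradigm geometry and validate sizes", {
  spot <- objectSpec("spot")
  expect_equal(c(spot$widthDeg, spot$heightDeg), c(22.5, 22.5))
  bar <- objectSpec("bar")
  expect_equal(c(bar$widthDeg, bar$heightDeg), c(22.5, 57))
  expect_equal(bar$luminanceCdM2, 0)
  expect_error(objectSpec("spot", widthDeg = -1))
})

test_that("schedules are balanced, seed-stable and follow the duty-cycle rule", {
  s <- makeSchedule(10, c("puff-", "puff+"), seed = 3)
  tab <- table(scheduleTrials(s)$condition)
  expect_equal(unname(as.integer(tab)), c(5L, 5L))
  s2 <- makeSchedule(10, c("puff-", "puff+"), seed = 3)
  expect_identical(scheduleTrials(s), scheduleTrials(s2))
  expect_false(identical(
    scheduleTrials(makeSchedule(10, c("puff-", "puff+"), seed = 4))$condition,
    scheduleTrials(s)$condition) &&
    identical(
      scheduleTrials(makeSchedule(10, c("puff-", "puff+"), seed = 4))$object_side_deg,
      scheduleTrials(s)$object_side_deg))

  expect_error(makeSchedule(10, c("a", "b", "c")), "multiple")

  ph <- makeSchedule(14, paste0("light+", c(1, 3, 6, 10, 12, 25, 60)),
                     photostimHz = c(1, 3, 6, 10, 12, 25, 60), seed = 1)
  tr <- scheduleTrials(ph)
  expect_equal(sort(unique(tr$pulse_ms)),
               sort(1000 * 0.5 / c(1, 3, 6, 10, 12, 25, 60)))
  expect_equal(tr$pulse_ms[tr$photostim_hz == 6][1], 500 / 6, tolerance = 1e-9)
  expect_equal(tr$pulse_ms[tr$photostim_hz == 1][1], 500)
})

test_that("the closed loop integrates, holds still agents still, and mirrors", {
  sched <- makeSchedule(2, c("puff-", "puff+"), seed = 5)
  # stationary agent: angle stays at the initial side
  still <- runClosedLoop(function(tr, k, a) 0, sched)
  for (tr in unique(still$trial)) {
    a <- still$angle_deg[still$trial == tr]
    expect_true(all(a == a[1]))
    expect_true(abs(a[1]) == 60)
  }
  # constant walking away: |angle| grows monotonically until wrap
  away <- runClosedLoop(function(tr, k, a) -sign(a) * 0.5, sched)
  a1 <- abs(away$angle_deg[away$trial == 1])
  k <- which.max(a1)
  expect_true(all(diff(a1[1:k]) > 0))
  expect_gt(a1[k], 170)

  # mirror symmetry: mirrored agent + mirrored side gives a mirrored trace
  tr1 <- scheduleTrials(sched)
  schedM <- sched
  schedM@trials$object_side_deg <- -tr1$object_side_deg
  f <- function(tr, k, a) 0.3 * sin(k / 3) - 0.1 * sign(a)
  fM <- function(tr, k, a) -f(tr, k, -a)
  out <- runClosedLoop(f, sched)
  outM <- runClosedLoop(fM, schedM)
  expect_equal(outM$angle_deg, -out$angle_deg, tolerance = 1e-9)

  expect_error(runClosedLoop(list(rep(0, 10)), sched), "one displacement")
})
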