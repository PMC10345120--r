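# FFT band energies serve as the independent oracle for the wavelet
# band-power ranking checks.
fftBandEnergy <- function(x, fs, band) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))^2 / n
  fr <- (seq_len(n) - 1) * fs / n
  sel <- fr >= band[1] & fr < band[2] & fr <= fs / 2
  sum(sp[sel])
}

test_that("Morlet power localizes sinusoid frequencies within one scale step", {
  fs <- 152
  t <- seq(0, 30, by = 1 / fs)
  z <- cos(2 * pi * 6 * t)
  sp <- morletCWT(z, fs)
  peakF <- spectrumFrequencies(sp)[which.max(colMeans(spectrumPower(sp)))]
  # one scale step = factor 2^dj
  expect_lt(abs(log2(peakF / 6)), sp@dj + 1e-9)
  # FFT oracle agrees on the dominant frequency
  fr <- (seq_along(z) - 1) * fs / length(z)
  fftPeak <- fr[which.max(Mod(fft(z - mean(z)))[fr <= fs / 2]^2)]
  expect_lt(abs(log2(peakF / fftPeak)), sp@dj + 1e-9)

  # zero signal: zero power
  expect_equal(max(spectrumPower(morletCWT(rep(0, 512), fs))), 0)

  # two summed sines produce ridges at both oracle frequencies
  z2 <- sin(2 * pi * 3 * t) + sin(2 * pi * 12 * t)
  sp2 <- morletCWT(z2, fs)
  prof <- colMeans(spectrumPower(sp2))
  f <- spectrumFrequencies(sp2)
  ridge3 <- f[which.max(prof * (f < 6))]
  ridge12 <- f[which.max(prof * (f > 6))]
  expect_lt(abs(log2(ridge3 / 3)), sp2@dj + 1e-9)
  expect_lt(abs(log2(ridge12 / 12)), sp2@dj + 1e-9)
})

test_that("band power ranking matches FFT band energies for pure tones", {
  fs <- 152
  t <- seq(0, 20, by = 1 / fs)
  bands <- frequencyBands()
  for (f0 in c(2, 3, 6, 10, 12, 20, 25)) {
    z <- sin(2 * pi * f0 * t)
    sp <- morletCWT(z, fs)
    mid <- spectrumTime(sp) > 4 & spectrumTime(sp) < 16
    bp <- vapply(bands, function(b) {
      mean(bandPower(sp, b)$power[mid])
    }, numeric(1))
    fe <- vapply(bands, function(b) fftBandEnergy(z, fs, b), numeric(1))
    expect_equal(names(which.max(bp)), names(which.max(fe)),
                 info = sprintf("tone at %g Hz", f0))
    # the true band dominates every other band by 10x in steady state
    expect_true(all(bp[which.max(bp)] >= 10 * bp[-which.max(bp)]),
                info = sprintf("tone at %g Hz", f0))
  }
  # 10 Hz sine: alpha band dominates by definition of the 8-16 Hz edges
  z10 <- sin(2 * pi * 10 * t)
  sp10 <- morletCWT(z10, fs)
  mid <- spectrumTime(sp10) > 4 & spectrumTime(sp10) < 16
  expect_gt(mean(bandPower(sp10, "alpha")$power[mid]),
            10 * mean(bandPower(sp10, "theta")$power[mid]))
})

test_that("white noise never shows 10x dominance of one band over all others", {
  fs <- 152
  withr::with_seed(9, {
    ok <- vapply(1:5, function(i) {
      z <- rnorm(20 * fs)
      sp <- morletCWT(z, fs)
      mid <- spectrumTime(sp) > 4 & spectrumTime(sp) < 16
      bp <- vapply(frequencyBands(), function(b)
        mean(bandPower(sp, b)$power[mid]), numeric(1))
      all(max(bp) < 10 * min(bp))
    }, logical(1))
  })
  expect_true(all(ok))
})

test_that("band requests above Nyquist are refused and empty bands error", {
  z <- sin(2 * pi * 1 * seq(0, 20, by = 0.25))
  sp <- morletCWT(z, 4)  # slow volumetric mode
  expect_error(bandPower(sp, c(4, 8)), "Nyquist")
  spFast <- morletCWT(rnorm(512), 152)
  expect_error(bandPower(spFast, c(0.001, 0.002)), "inside")
})

test_that("delta power vanishes for stationary signals and detects bursts", {
  fs <- 152
  t <- seq(0, 10, by = 1 / fs)
  z <- sin(2 * pi * 6 * t)
  bp <- bandPower(morletCWT(z, fs), "theta")
  expect_lt(abs(deltaBandPower(bp, window = c(4, 6))),
            0.02 * mean(bp$power[bp$t_s > 3 & bp$t_s < 7]))
  # 6 Hz burst confined to the window: theta delta large, beta negligible
  zb <- rnorm(length(t), sd = 0.1)
  inWin <- t >= 5 & t < 7
  zb[inWin] <- zb[inWin] + sin(2 * pi * 6 * t[inWin])
  spb <- morletCWT(zb, fs)
  dTheta <- deltaBandPower(bandPower(spb, "theta"), c(5, 7))
  dBeta <- deltaBandPower(bandPower(spb, "beta"), c(5, 7))
  expect_gt(dTheta, 0)
  expect_gt(dTheta, 10 * abs(dBeta))
  expect_error(deltaBandPower(bp, window = c(0.2, 1)), "preceding")
})

test_that("delta power of a stationary process is zero in expectation", {
  fs <- 76  # decimated profile keeps the Monte-Carlo run fast
  withr::with_seed(21, {
    deltas <- vapply(1:200, function(i) {
      z <- rnorm(6 * fs)
      deltaBandPower(bandPower(morletCWT(z, fs), "theta"), c(2.5, 4))
    }, numeric(1))
  })
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se)
})

test_that("cross-cell spectrum averaging is element-wise and grid-checked", {
  fs <- 152
  z1 <- sin(2 * pi * 6 * seq(0, 5, by = 1 / fs))
  s1 <- morletCWT(z1, fs)
  s2 <- morletCWT(z1 * 0, fs)
  avg <- averageCrossSpectrum(list(s1, s2))
  expect_equal(spectrumPower(avg), spectrumPower(s1) / 2)
  expect_equal(spectrumPower(averageCrossSpectrum(list(s1, s1))),
               spectrumPower(s1))
  sShort <- morletCWT(z1[1:400], fs)
  expect_error(averageCrossSpectrum(list(s1, sShort)), "identical")
  # variance of the mean of N i.i.d. noise spectra scales as 1/N
  withr::with_seed(3, {
    mk <- function() morletCWT(rnorm(256), fs)
    v1 <- var(as.vector(spectrumPower(averageCrossSpectrum(
      lapply(1:2, function(i) mk())))))
    v8 <- var(as.vector(spectrumPower(averageCrossSpectrum(
      lapply(1:16, function(i) mk())))))
  })
  expect_lt(v8, v1 / 2)
})

test_that("responder restriction excludes cells without puff responses", {
  cfg <- syntheticConfig(seed = 13, noiseSd = 0.5, thetaAmp = 8)
  # adversarial fixture: theta injected into non-responders only
  ceAdv <- genCalciumCohort(cfg, nCells = 24,
                            thetaCells = "nonresponders")
  ceAdv <- zScoreTrace(deltaFOverF(ceAdv))
  rrdAdv <- responderRestrictedDelta(ceAdv)
  thetaPost <- rrdAdv$mean$delta_power[rrdAdv$mean$band == "theta" &
                                         rrdAdv$mean$window == "visual_post"]
  # restricted to responders, the injected non-responder theta is invisible;
  # compare against the honest cohort at the same settings
  ce <- zScoreTrace(deltaFOverF(genCalciumCohort(cfg, nCells = 24)))
  rrd <- responderRestrictedDelta(ce)
  thetaPostTrue <- rrd$mean$delta_power[rrd$mean$band == "theta" &
                                          rrd$mean$window == "visual_post"]
  expect_lt(abs(thetaPost), 0.1 * thetaPostTrue)

  noResp <- rep(FALSE, nrow(ce))
  expect_warning(empty <- responderRestrictedDelta(ce, responders = noResp),
                 "no responder")
  expect_equal(nrow(empty$mean), 0L)
  expect_equal(empty$n_responders, 0L)
})
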