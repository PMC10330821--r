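test_that("linear I-V fit recovers the bilayer chord parameters and is
           exact/equivariant on collinear data", {
  f <- fitLinearIV(data.frame(v_mV = c(-40.5, 0), i_pA = c(0, 24.3)))
  expect_equal(f@slopePS, 600)
  expect_equal(f@erevMV, -40.5)
  expect_error(fitLinearIV(data.frame(v_mV = c(-20, 0, 20),
                                      i_pA = c(3, 3, 3))), "slope")
  expect_error(fitLinearIV(data.frame(v_mV = c(5, 5), i_pA = c(1, 2))),
               "distinct")
  ## exact recovery on collinear points; voltage shift moves Erev only
  v <- seq(-60, 60, 20)
  g <- 0.275; er <- -52
  f2 <- fitLinearIV(data.frame(v_mV = v, i_pA = g * (v - er)))
  expect_equal(f2@slopePS, 275)
  expect_equal(f2@erevMV, -52)
  f3 <- fitLinearIV(data.frame(v_mV = v + 15, i_pA = g * (v - er)))
  expect_equal(f3@slopePS, f2@slopePS)
  expect_equal(f3@erevMV, f2@erevMV + 15)
  expect_equal(chordConductance(24.3, 0, -40.5), 600)
  expect_error(chordConductance(1, -40.5, -40.5), "undefined")
})

test_that("half-amplitude idealization is exact on square waves and >=99%
           accurate at SNR 5", {
  ## noiseless square wave: exact transition samples
  i <- rep(c(0, 5.4, 0, 5.4, 0), c(50, 30, 40, 60, 20))
  seg <- idealizeHalfAmplitude(i, amplitudePA = 5.4, baselinePA = 0)
  expect_equal(seg$level, c(0, 1, 0, 1, 0))
  expect_equal(seg$start, c(1, 51, 81, 121, 181))
  expect_equal(seg$duration, c(50, 30, 40, 60, 20))
  ## all-closed trace: one segment
  seg0 <- idealizeHalfAmplitude(rep(0, 100) + rnorm(100, 0, 0.01),
                                amplitudePA = 5.4, baselinePA = 0)
  expect_equal(nrow(seg0), 1L)
  expect_equal(seg0$level, 0)
  ## generator trace at SNR 5: per-sample state accuracy
  p <- ChannelSimParams(seed = 1, nChannels = 1, openRate = 10,
    closeRate = 10, noiseSdPA = 5.39 / 5, sampleIntervalS = 1e-4,
    unitaryConductancePS = 110, reversalMV = -49,
    voltageProtocol = data.frame(level_mV = 0, duration_s = 10))
  sim <- makeChannelTrace(p)
  seg1 <- idealizeHalfAmplitude(sim$trace, amplitudePA = 5.39)
  expect_gte(mean(attr(seg1, "states") == sim$truth$n_open), 0.99)
  expect_error(idealizeHalfAmplitude(i, amplitudePA = 0), "nonzero")
  expect_error(idealizeHalfAmplitude(i, 5.4, minDwellSamples = 0), ">= 1")
})

test_that("unitary current estimation is baseline-invariant and recovers the
           simulated amplitude", {
  i <- rep(c(0, 5.4), 50)
  seg <- idealizeHalfAmplitude(i, amplitudePA = 5.4, baselinePA = 0,
                               minDwellSamples = 1)
  est <- meanUnitaryCurrent(i, seg)
  expect_equal(est@meanIpA, 5.4)
  est2 <- meanUnitaryCurrent(i + 100, seg)
  expect_equal(est2@meanIpA, 5.4)
  ## recovery for a 10.2-pA channel
  p <- ChannelSimParams(seed = 1, nChannels = 1, openRate = 8, closeRate = 8,
    noiseSdPA = 1, sampleIntervalS = 1e-4, unitaryConductancePS = 196,
    reversalMV = -52.04,
    voltageProtocol = data.frame(level_mV = 0, duration_s = 10))
  sim <- makeChannelTrace(p)
  trueI <- 0.196 * 52.04
  seg1 <- idealizeHalfAmplitude(sim$trace, amplitudePA = trueI)
  est1 <- meanUnitaryCurrent(sim$trace, seg1)
  se <- est1@sdPA / sqrt(sum(sim$truth$n_open == 1))
  expect_lt(abs(est1@meanIpA - trueI), 2 * se + 0.02)
  expect_error(meanUnitaryCurrent(rep(0, 10), data.frame(level = 0,
    start = 1, duration = 10)), "no openings")
})

test_that("idealization plus amplitude estimation has <2% bias over 100
           seeded traces at SNR 5", {
  ests <- vapply(1:100, function(s) {
    p <- ChannelSimParams(seed = s, nChannels = 1, openRate = 10,
      closeRate = 10, noiseSdPA = 5.39 / 5, sampleIntervalS = 1e-4,
      unitaryConductancePS = 110, reversalMV = -49,
      voltageProtocol = data.frame(level_mV = 0, duration_s = 4))
    sim <- makeChannelTrace(p)
    seg <- idealizeHalfAmplitude(sim$trace, amplitudePA = 5.39)
    if (!any(seg$level == 1) || !any(seg$level == 0)) return(NA_real_)
    meanUnitaryCurrent(sim$trace, seg)@meanIpA
  }, numeric(1))
  expect_lt(abs(mean(ests, na.rm = TRUE) - 5.39) / 5.39, 0.02)
})

test_that("channel counting and percent change match the reference estimates", {
  expect_identical(estimateChannelCount(600, 110), 5L)
  expect_identical(estimateChannelCount(0, 110), 0L)
  expect_identical(estimateChannelCount(280, 140), 2L)
  for (k in 0:10) expect_identical(estimateChannelCount(k * 137.5, 137.5),
                                   as.integer(k))
  expect_error(estimateChannelCount(600, 0), "> 0")
  expect_equal(percentChange(5.4, 10.2), 88.9, tolerance = 0.001)
  expect_equal(percentChange(7, 7), 0)
  expect_equal(percentChange(10.2, 13.4), 31.37, tolerance = 0.001)
  expect_error(percentChange(0, 5), "undefined")
  ## round trip to machine precision
  for (x in c(5.4, 10.2, 13.4)) {
    pc <- percentChange(x, 13.4)
    expect_equal(x * (1 + pc / 100), 13.4)
  }
})

test_that("single-exponential inactivation fitting: exact when noiseless,
           within 10% on a noisy ensemble, flags non-decaying sweeps", {
  tt <- seq(0, 8, 0.01)
  f <- fitExponentialInactivation(data.frame(t_s = tt,
                                             i_pA = 3 * exp(-tt / 2) + 1))
  expect_equal(f@tauS, 2, tolerance = 1e-6)
  expect_equal(f@amplitudePA, 3, tolerance = 1e-6)
  expect_equal(f@offsetPA, 1, tolerance = 1e-6)
  expect_false(f@flagged)
  ## macroscopic ensemble with tau = 2 s and recording noise
  p <- ChannelSimParams(seed = 1, nChannels = 200, openRate = 50,
    closeRate = 50, noiseSdPA = 2, tauInactS = 2, sampleIntervalS = 1e-3,
    unitaryConductancePS = 110, reversalMV = -49,
    voltageProtocol = data.frame(level_mV = 0, duration_s = 8))
  sw <- makeMacroscopicSweeps(p)
  fn <- fitExponentialInactivation(
    data.frame(t_s = sw$sweeps$t_s, i_pA = sw$sweeps$i_pA))
  expect_lt(abs(fn@tauS - 2) / 2, 0.1)
  ## constant sweep is flagged, not an error
  fc <- fitExponentialInactivation(data.frame(t_s = tt, i_pA = rep(5, length(tt))))
  expect_true(fc@flagged)
  expect_error(fitExponentialInactivation(
    data.frame(t_s = tt, i_pA = tt), fitWindow = c(-1, 3)), "outside")
  expect_error(fitExponentialInactivation(
    data.frame(t_s = 1:5, i_pA = 1:5)), "10 samples")
})

test_that("whole-cell current change rate matches the compound-Poisson
           staircase expectation", {
  expect_equal(currentChangeRate(data.frame(t_s = 1:10, i_pA = rep(4, 10))), 0)
  expect_equal(currentChangeRate(data.frame(t_s = 0:20,
                                            i_pA = 12 * (0:20) + 3)), 12)
  expect_error(currentChangeRate(data.frame(t_s = 1:2, i_pA = 1:2)),
               "3 points")
  wc <- makeWholeCellSession(SecretionSimParams(seed = 1))
  rate <- currentChangeRate(data.frame(t_s = wc$series$t_s,
                                       i_pA = wc$series$i_plus80_pA))
  p <- wc$params
  expected <- p@pulseRateHz * p@fusionRatePerPulse *
    p@conductancePerEventNS * (80 - p@erevMV)
  expect_gt(rate, 0)
  expect_lt(abs(rate - expected) / expected, 0.15)
})

test_that("Welch comparison matches the closed form and has power for a
           1-sigma shift", {
  r0 <- compareGroups(c(3, 4, 5), c(3, 4, 5))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  ## two 2-point samples against the hand-computed Welch statistic
  a <- c(1, 2); b <- c(4, 8)
  r <- compareGroups(a, b, adjustment = "none")
  se <- sqrt(var(a) / 2 + var(b) / 2)
  tHand <- (mean(a) - mean(b)) / se
  dfHand <- se^4 / ((var(a) / 2)^2 / 1 + (var(b) / 2)^2 / 1)
  expect_equal(r$t, tHand)
  expect_equal(r$df, dfHand)
  expect_equal(r$p, 2 * pt(tHand, dfHand))
  ## Bonferroni multiplies and caps
  r2 <- compareGroups(a, b, nComparisons = 3)
  expect_equal(r2$pAdjusted, min(1, 3 * r2$p))
  expect_equal(compareGroups(c(1, 2), c(1.01, 2.01),
                             nComparisons = 50)$pAdjusted, 1)
  ## power check: shifted normals
  set.seed(1)
  x <- rnorm(50); y <- rnorm(50, 1)
  expect_lt(compareGroups(x, y)$p, 0.05)
  expect_error(compareGroups(1, c(1, 2)), "n >= 2")
})
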