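test_that("generators are deterministic: identical params and seed give
           bit-identical output", {
  p <- EMFieldParams(nGranules = 6, seed = 9)
  a <- makeEMField(p); b <- makeEMField(p)
  expect_identical(intensity(a$image), intensity(b$image))
  expect_identical(a$truth, b$truth)
  expect_identical(a$rings@rings, b$rings@rings)
  c <- makeEMField(EMFieldParams(nGranules = 6, seed = 10))
  expect_false(identical(intensity(a$image), intensity(c$image)))
  t1 <- makeChannelTrace(ChannelSimParams(seed = 5))
  t2 <- makeChannelTrace(ChannelSimParams(seed = 5))
  expect_identical(t1$trace, t2$trace)
  f1 <- makeFluxSeries(FluxSimParams(seed = 5))
  f2 <- makeFluxSeries(FluxSimParams(seed = 5))
  expect_identical(f1$traces, f2$traces)
  pu1 <- makePunctaImage(10, seed = 5)
  pu2 <- makePunctaImage(10, seed = 5)
  expect_identical(intensity(pu1$image), intensity(pu2$image))
})

test_that("empty EM field is noise only with empty truth", {
  f <- makeEMField(EMFieldParams(nGranules = 0, seed = 1))
  expect_equal(nrow(f$truth), 0L)
  expect_length(f$rings@rings, 0L)
  img <- intensity(f$image)
  expect_equal(mean(img), 0.75, tolerance = 0.005)
  expect_lt(max(abs(img - 0.75)), 0.15)
})

test_that("EM truth respects the generator invariants", {
  truth <- defaultTruth()
  expect_true(all(truth$d_nm >= -20 - 1e-9))
  expect_true(all(truth$d_nm <= truth$granule_r_nm + 1e-9))
  expect_true(all(truth$class %in% c("chgb", "insulin")))
  radii <- unique(truth$granule_r_nm)
  expect_true(all(radii >= 40 & radii <= 220))
})

test_that("model distributions match their specification at large n
           (3 standard errors)", {
  set.seed(77)
  ## truncated-normal granule radius model
  r <- GranulePhys:::rtruncnorm(1e5, 90, 40, 40, 220)
  a <- (40 - 90) / 40; b <- (220 - 90) / 40
  Z <- pnorm(b) - pnorm(a)
  m <- 90 + 40 * (dnorm(a) - dnorm(b)) / Z
  v <- 40^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                 ((dnorm(a) - dnorm(b)) / Z)^2)
  expect_lt(abs(mean(r) - m), 3 * sqrt(v / 1e5))
  expect_true(all(r >= 40 & r <= 220))
  ## membrane-proximal shell distance model
  s <- GranulePhys:::rtruncnorm(1e5, 25, 16, -20, 98)
  a2 <- (-20 - 25) / 16; b2 <- (98 - 25) / 16
  Z2 <- pnorm(b2) - pnorm(a2)
  m2 <- 25 + 16 * (dnorm(a2) - dnorm(b2)) / Z2
  expect_lt(abs(mean(s) - m2), 3 * 16 / sqrt(1e5))
})

test_that("realized label distances stay close to the placement model
           (collision lifts are small)", {
  truth <- defaultTruth()
  ins <- truth[truth$class == "insulin", ]
  ## model: d = R - s, s half-normal(6); realized mean within 3.5 nm
  modelMean <- mean(ins$granule_r_nm) - 6 * sqrt(2 / pi)
  expect_lt(abs(mean(ins$d_nm) - modelMean), 3.5)
  ## shell component essentially undistorted: CHGB mass near 25 nm
  chg <- truth$d_nm[truth$class == "chgb"]
  expect_gt(mean(chg >= -20 & chg <= 40), 0.3)
})

test_that("channel traces obey the stated current model", {
  ## pinned-open channel: i = g (V - Erev) exactly
  p <- ChannelSimParams(seed = 1, nChannels = 1, openRate = 1, closeRate = 0,
    startOpen = TRUE, noiseSdPA = 0, unitaryConductancePS = 110,
    reversalMV = -49, voltageProtocol = data.frame(level_mV = 0,
                                                   duration_s = 1))
  tr <- makeChannelTrace(p)
  expect_equal(unique(tr$trace$i_pA), 5.39)
  ## closed channel with zero opening rate: flat zero-mean trace
  p0 <- ChannelSimParams(seed = 2, nChannels = 1, openRate = 0,
    closeRate = 5, noiseSdPA = 0.1)
  tr0 <- makeChannelTrace(p0)
  expect_true(all(tr0$truth$n_open == 0))
  expect_lt(abs(mean(tr0$trace$i_pA)), 0.01)
  ## invalid sampling interval rejected at construction
  expect_error(ChannelSimParams(sampleIntervalS = 0), "> 0")
})

test_that("ensemble inactivation decays with the programmed time constant
           and tau = Inf sweeps do not decay", {
  p <- ChannelSimParams(seed = 2, nChannels = 300, openRate = 50,
    closeRate = 50, noiseSdPA = 0, tauInactS = 2, sampleIntervalS = 2e-3,
    voltageProtocol = data.frame(level_mV = c(0, 0), duration_s = c(8, 8)))
  sw <- makeMacroscopicSweeps(p)
  f <- fitExponentialInactivation(data.frame(t_s = sw$sweeps$t_s,
                                             i_pA = sw$sweeps$i_pA))
  expect_lt(abs(f@tauS - 2) / 2, 0.1)
  pInf <- ChannelSimParams(seed = 2, nChannels = 100, openRate = 50,
    closeRate = 50, noiseSdPA = 0, sampleIntervalS = 2e-3,
    voltageProtocol = data.frame(level_mV = 0, duration_s = 6))
  swInf <- makeMacroscopicSweeps(pInf)
  fInf <- fitExponentialInactivation(data.frame(t_s = swInf$sweeps$t_s,
                                                i_pA = swInf$sweeps$i_pA))
  ## no decay: fitted amplitude negligible or non-decaying flag raised
  expect_true(fInf@flagged ||
                abs(fInf@amplitudePA) < 0.05 * mean(swInf$sweeps$i_pA))
})

test_that("whole-cell sessions: calcium gates fusion and chloride carries
           the added current", {
  noCa <- makeWholeCellSession(SecretionSimParams(seed = 1,
                                                  calciumPresent = FALSE))
  expect_true(all(noCa$series$g_nS == 0))
  expect_equal(currentChangeRate(data.frame(t_s = noCa$series$t_s,
                                            i_pA = noCa$series$i_plus80_pA)), 0)
  noCl <- makeWholeCellSession(SecretionSimParams(seed = 1,
                                                  chloridePresent = FALSE))
  expect_equal(unique(noCl$series$i_plus80_pA), noCl$params@leakPA)
  wc <- makeWholeCellSession(SecretionSimParams(seed = 1))
  expect_true(all(diff(wc$series$g_nS) >= 0))
  ## conductance accumulates to the order of tens of nS over the session
  expect_gt(max(wc$series$g_nS), 10)
})

test_that("puncta images place the requested number of resolvable spots", {
  p0 <- makePunctaImage(0, seed = 1)
  expect_equal(nrow(p0$truth), 0L)
  p <- makePunctaImage(25, seed = 2)
  expect_equal(nrow(p$truth), 25L)
  d <- as.matrix(dist(cbind(p$truth$x_nm, p$truth$y_nm)))
  diag(d) <- Inf
  expect_gt(min(d), 6 * 150)
})
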