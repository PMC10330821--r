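#' @include AllClasses.R utils.R
NULL

#' Ordinary least-squares fit of a current-voltage series
#'
#' Fits I = g (V - Erev) by OLS on (V, I) pairs; the slope in pA/mV is
#' reported in pS (x1000) and Erev = -intercept/slope. Exact on collinear
#' input and equivariant under voltage-axis shifts.
#'
#' @param series data.frame with columns `v_mV` and `i_pA` (>= 2 distinct
#'   voltages).
#' @return A [ConductanceFit-class].
#' @examples
#' fitLinearIV(data.frame(v_mV = c(-40.5, 0), i_pA = c(0, 24.3)))
#' @export
fitLinearIV <- function(series) {
  stopifnot(is.data.frame(series), all(c("v_mV", "i_pA") %in% names(series)))
  if (length(unique(series$v_mV)) < 2L)
    stop("need at least 2 distinct voltages")
  fit <- lm(i_pA ~ v_mV, data = series)
  b <- coef(fit)
  if (abs(b[2]) < 1e-12)
    stop("slope is zero: reversal potential undefined")
  n <- nrow(series)
  if (fit$df.residual > 0 && sum(fit$residuals^2) > 1e-20) {
    vc <- vcov(fit)
    slopeSe <- sqrt(vc[2, 2])
    erevSe <- sqrt(vc[1, 1] / b[2]^2 + b[1]^2 * vc[2, 2] / b[2]^4 -
                   2 * b[1] * vc[1, 2] / b[2]^3)
    r2 <- summary(fit)$r.squared
  } else {
    slopeSe <- 0; erevSe <- 0; r2 <- 1
  }
  new("ConductanceFit", slopePS = unname(b[2]) * 1000,
      erevMV = unname(-b[1] / b[2]), slopeSePS = slopeSe * 1000,
      erevSeMV = erevSe, r2 = r2, n = as.integer(n))
}

#' Chord conductance
#'
#' g = I / (V - Erev), the conductance referenced to the reversal potential
#' (as opposed to the fitted slope conductance).
#'
#' @param iPA current (pA).
#' @param vMV membrane potential (mV).
#' @param erevMV reversal potential (mV); must differ from `vMV`.
#' @return Chord conductance in pS.
#' @examples
#' chordConductance(24.3, 0, -40.5) # ~600 pS
#' @export
chordConductance <- function(iPA, vMV, erevMV) {
  if (abs(vMV - erevMV) < 1e-12)
    stop("chord conductance undefined at the reversal potential")
  1000 * iPA / (vMV - erevMV)
}

#' Half-amplitude threshold idealization of a two-level trace
#'
#' Classifies each sample as closed (0) or open (1) by thresholding at
#' baseline + amplitude/2, then merges dwells shorter than
#' `minDwellSamples` into their neighbours (shortest first). The returned
#' segments partition the trace. When `baselinePA` is not supplied it is
#' estimated as the mode of the all-points histogram (kernel density
#' maximum).
#'
#' @param trace data.frame with column `i_pA` (and optionally `t_s`), or a
#'   numeric vector of currents.
#' @param amplitudePA unitary current amplitude (pA, nonzero; sign gives the
#'   open-level direction).
#' @param baselinePA closed-level current (pA); estimated if NULL.
#' @param minDwellSamples minimum dwell length in samples (>= 1, default 2).
#' @return data.frame with columns `level` (0/1), `start` (sample index) and
#'   `duration` (samples), with the per-sample state in attribute `states`.
#' @export
idealizeHalfAmplitude <- function(trace, amplitudePA, baselinePA = NULL,
                                  minDwellSamples = 2L) {
  i <- if (is.data.frame(trace)) trace$i_pA else as.numeric(trace)
  if (amplitudePA == 0) stop("amplitudePA must be nonzero")
  if (minDwellSamples < 1L) stop("minDwellSamples must be >= 1")
  if (is.null(baselinePA)) {
    d <- stats::density(i, n = 1024)
    baselinePA <- d$x[which.max(d$y)]
  }
  open <- as.integer((i - baselinePA) / amplitudePA > 0.5)
  ## merge sub-resolution dwells, shortest first
  repeat {
    r <- rle(open)
    short <- which(r$lengths < minDwellSamples)
    if (!length(short) || length(r$lengths) == 1L) break
    k <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    open[starts[k]:ends[k]] <- 1L - r$values[k]
  }
  r <- rle(open)
  ends <- cumsum(r$lengths)
  seg <- data.frame(level = r$values, start = ends - r$lengths + 1L,
                    duration = r$lengths)
  attr(seg, "states") <- open
  attr(seg, "baselinePA") <- baselinePA
  seg
}

#' Dwell-weighted mean unitary current
#'
#' mean(open-level samples) minus mean(closed-level samples), weighting each
#' sample equally (dwell-weighted). Invariant under constant baseline
#' offsets.
#'
#' @param trace the trace used for idealization (data.frame with `i_pA` or
#'   numeric vector).
#' @param segments idealized segments from [idealizeHalfAmplitude()].
#' @return An [AmplitudeEstimate-class].
#' @export
meanUnitaryCurrent <- function(trace, segments) {
  i <- if (is.data.frame(trace)) trace$i_pA else as.numeric(trace)
  states <- attr(segments, "states")
  if (is.null(states)) {
    states <- integer(length(i))
    for (k in seq_len(nrow(segments)))
      states[segments$start[k] + seq_len(segments$duration[k]) - 1L] <-
        segments$level[k]
  }
  nOpenSeg <- sum(segments$level == 1L)
  if (nOpenSeg == 0L) stop("no openings detected")
  if (!any(states == 0L)) stop("no closed-level samples")
  est <- mean(i[states == 1L]) - mean(i[states == 0L])
  new("AmplitudeEstimate", meanIpA = est, sdPA = sd(i[states == 1L]),
      nEvents = as.integer(nOpenSeg))
}

#' Channel count from macroscopic and unitary conductance
#'
#' round(macroscopic / unitary), half away from zero.
#'
#' @param macroConductancePS macroscopic (chord or slope) conductance (pS).
#' @param unitaryConductancePS unitary conductance (pS, > 0).
#' @return Integer channel count.
#' @examples
#' estimateChannelCount(600, 110) # ~5 channels
#' @export
estimateChannelCount <- function(macroConductancePS, unitaryConductancePS) {
  if (unitaryConductancePS <= 0) stop("unitary conductance must be > 0")
  x <- macroConductancePS / unitaryConductancePS
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Percent change
#'
#' 100 x (after - before) / before.
#'
#' @param before reference value (nonzero).
#' @param after new value.
#' @return Percent change.
#' @examples
#' percentChange(5.4, 10.2) # ~89%
#' @export
percentChange <- function(before, after) {
  if (before == 0) stop("percent change undefined for before = 0")
  100 * (after - before) / before
}

#' Single-exponential inactivation fit
#'
#' Fits I(t) = A exp(-t/tau) + C by least squares: for fixed tau, A and C
#' are solved in closed form (linear regression on exp(-t/tau)), and tau is
#' optimized on a log scale. Non-decaying data (A <= 0 or tau at the upper
#' bound) is flagged rather than an error.
#'
#' @param sweep data.frame with columns `t_s` and `i_pA`.
#' @param fitWindow optional c(t0, t1) in seconds restricting the fit.
#' @return An [InactivationFit-class].
#' @export
fitExponentialInactivation <- function(sweep, fitWindow = NULL) {
  stopifnot(is.data.frame(sweep), all(c("t_s", "i_pA") %in% names(sweep)))
  t <- sweep$t_s; y <- sweep$i_pA
  if (!is.null(fitWindow)) {
    if (fitWindow[1] < min(t) - 1e-12 || fitWindow[2] > max(t) + 1e-12)
      stop("fitWindow outside sweep")
    keep <- t >= fitWindow[1] & t <= fitWindow[2]
    t <- t[keep]; y <- y[keep]
  }
  if (length(t) < 10L) stop("need at least 10 samples in the fit window")
  t0 <- t - min(t)
  span <- max(t0)
  rssOf <- function(logTau) {
    x <- exp(-t0 / exp(logTau))
    f <- lm.fit(cbind(1, x), y)
    sum(f$residuals^2)
  }
  opt <- optimize(rssOf, lower = log(span / 1e4), upper = log(span * 100),
                  tol = 1e-12)
  tau <- exp(opt$minimum)
  x <- exp(-t0 / tau)
  cf <- lm.fit(cbind(1, x), y)$coefficients
  flagged <- cf[2] <= 1e-8 * max(abs(y), 1) || tau >= span * 99
  if (flagged) tau <- min(tau, span * 100)
  new("InactivationFit", tauS = tau, amplitudePA = unname(cf[2]),
      offsetPA = unname(cf[1]),
      rmse = sqrt(opt$objective / length(t)), flagged = flagged)
}

#' Rate of change of per-pulse peak currents
#'
#' OLS slope of peak current against time, the standard summary of gradual
#' whole-cell current growth during stimulated granule release.
#'
#' @param series data.frame with columns `t_s` and `i_pA` (>= 3 points), or
#'   two vectors via `t` and `i` columns of a list.
#' @return Slope in pA/s.
#' @export
currentChangeRate <- function(series) {
  stopifnot(all(c("t_s", "i_pA") %in% names(series)))
  if (length(series$t_s) < 3L) stop("need at least 3 points")
  unname(coef(lm(i_pA ~ t_s, data = as.data.frame(series)))[2])
}

#' Welch two-sided t-test with multiplicity adjustment
#'
#' Two-sided Welch (unequal-variance) t-test, with the p-value multiplied by
#' `nComparisons` and capped at 1 (Bonferroni) when requested. Two identical
#' zero-variance samples return t = 0, p = 1 by convention.
#'
#' @param sampleA,sampleB numeric samples (each n >= 2).
#' @param adjustment "bonferroni" (default) or "none".
#' @param nComparisons number of comparisons for the adjustment.
#' @return list with elements `t`, `p`, `pAdjusted`, `df`.
#' @export
compareGroups <- function(sampleA, sampleB,
                          adjustment = c("bonferroni", "none"),
                          nComparisons = 1) {
  adjustment <- match.arg(adjustment)
  if (length(sampleA) < 2L || length(sampleB) < 2L)
    stop("each sample needs n >= 2")
  if (var(sampleA) == 0 && var(sampleB) == 0) {
    if (mean(sampleA) == mean(sampleB)) {
      tt <- list(statistic = 0, p.value = 1, parameter = NA_real_)
    } else {
      warning("zero-variance samples with different means; p set to 0")
      tt <- list(statistic = Inf, p.value = 0, parameter = NA_real_)
    }
  } else {
    ht <- t.test(sampleA, sampleB, var.equal = FALSE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value,
               parameter = unname(ht$parameter))
  }
  pAdj <- if (adjustment == "bonferroni")
    min(1, tt$p.value * nComparisons) else tt$p.value
  list(t = tt$statistic, p = tt$p.value, pAdjusted = pAdj,
       df = tt$parameter)
}
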