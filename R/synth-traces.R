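#' @include AllClasses.R utils.R
NULL

## Simulate one channel's conducting indicator on a sample grid.
## Two-state (closed/open) continuous-time Markov chain with optional
## irreversible inactivation at constant hazard 1/tauInact, so the ensemble
## open probability decays as exp(-t/tau).
simulateChannelPath <- function(tGrid, openRate, closeRate, startOpen,
                                tauInactS) {
  tEnd <- tGrid[length(tGrid)] + (tGrid[2] - tGrid[1])
  times <- 0
  states <- as.integer(startOpen)
  t <- 0; s <- as.integer(startOpen)
  while (t < tEnd) {
    rate <- if (s == 1L) closeRate else openRate
    if (rate <= 0) break
    t <- t + rexp(1, rate)
    if (t >= tEnd) break
    s <- 1L - s
    times <- c(times, t)
    states <- c(states, s)
  }
  open <- states[findInterval(tGrid, times)]
  if (!is.na(tauInactS)) {
    tInact <- rexp(1, 1 / tauInactS)
    open[tGrid >= tInact] <- 0L
  }
  open
}

protocolVoltage <- function(protocol, tGrid) {
  edges <- cumsum(c(0, protocol$duration_s))
  idx <- pmin(findInterval(tGrid, edges, rightmost.closed = TRUE),
              nrow(protocol))
  protocol$level_mV[pmax(idx, 1L)]
}

#' Simulate a two-level single-channel current trace
#'
#' Each of `nChannels` independent channels follows a closed/open Markov
#' scheme with the given rates; with `tauInactS` set, each channel also
#' inactivates irreversibly at rate 1/tau. The recorded current is
#' sum(open channels) x g x (V - Erev) plus Gaussian noise, with g in pS and
#' V in mV giving pA via the factor 1/1000. The true per-sample open-channel
#' count is returned alongside the trace.
#'
#' @param params a [ChannelSimParams-class].
#' @return list with elements `trace` (data.frame t_s, i_pA), `truth`
#'   (data.frame t_s, n_open, v_mV) and `params`.
#' @export
makeChannelTrace <- function(params) {
  stopifnot(is(params, "ChannelSimParams"))
  validObject(params)
  dt <- params@sampleIntervalS
  total <- sum(params@voltageProtocol$duration_s)
  n <- floor(total / dt)
  tGrid <- (seq_len(n) - 1) * dt
  withSeed(deriveSeed(params@seed, 0L), {
    nOpen <- integer(n)
    for (c in seq_len(params@nChannels)) {
      set.seed(deriveSeed(params@seed, c))
      nOpen <- nOpen + simulateChannelPath(tGrid, params@openRate,
        params@closeRate, params@startOpen, params@tauInactS)
    }
    v <- protocolVoltage(params@voltageProtocol, tGrid)
    i <- nOpen * params@unitaryConductancePS * (v - params@reversalMV) / 1000
    set.seed(deriveSeed(params@seed, params@nChannels + 1L))
    if (params@noiseSdPA > 0) i <- i + rnorm(n, 0, params@noiseSdPA)
    list(trace = data.frame(t_s = tGrid, i_pA = i),
         truth = data.frame(t_s = tGrid, n_open = nOpen, v_mV = v),
         params = params)
  })
}

#' Simulate a set of macroscopic sweeps over a voltage protocol
#'
#' One sweep per voltage-protocol row, each simulated as in
#' [makeChannelTrace()] with a fresh channel population (inactivation resets
#' between sweeps, as with long inter-sweep holding intervals).
#'
#' @param params a [ChannelSimParams-class]; each `voltageProtocol` row
#'   becomes one sweep at that level and duration.
#' @return list with `sweeps` (data.frame sweep, level_mV, t_s, i_pA),
#'   `truth` (sweep, t_s, n_open) and `params`.
#' @export
makeMacroscopicSweeps <- function(params) {
  stopifnot(is(params, "ChannelSimParams"))
  vp <- params@voltageProtocol
  out <- vector("list", nrow(vp))
  for (k in seq_len(nrow(vp))) {
    pk <- params
    pk@voltageProtocol <- vp[k, , drop = FALSE]
    pk@seed <- deriveSeed(params@seed, 10000L + k)
    sim <- makeChannelTrace(pk)
    out[[k]] <- list(
      sweeps = data.frame(sweep = k, level_mV = vp$level_mV[k],
                          t_s = sim$trace$t_s, i_pA = sim$trace$i_pA),
      truth = data.frame(sweep = k, t_s = sim$truth$t_s,
                         n_open = sim$truth$n_open))
  }
  list(sweeps = do.call(rbind, lapply(out, `[[`, "sweeps")),
       truth = do.call(rbind, lapply(out, `[[`, "truth")),
       params = params)
}

#' Simulate a depolarization-evoked whole-cell session
#'
#' Per-pulse peak currents at +80 and -80 mV while calcium-triggered granule
#' fusion adds anion conductance as a compound-Poisson staircase: at each
#' pulse, Poisson(fusionRatePerPulse) fusion events each add
#' `conductancePerEventNS`; the peak current is G(t) x (V - Erev) + leak
#' (nS x mV = pA). Without calcium no fusion occurs; without extracellular
#' chloride the anionic driving-force term is zero and only the leak remains.
#'
#' @param params a [SecretionSimParams-class].
#' @return list with `series` (data.frame t_s, g_nS, i_plus80_pA,
#'   i_minus80_pA) and `params`.
#' @export
makeWholeCellSession <- function(params) {
  stopifnot(is(params, "SecretionSimParams"))
  validObject(params)
  nPulse <- floor(params@durationS * params@pulseRateHz)
  tPulse <- seq_len(nPulse) / params@pulseRateHz
  withSeed(deriveSeed(params@seed, 0L), {
    events <- if (params@calciumPresent)
      rpois(nPulse, params@fusionRatePerPulse) else integer(nPulse)
    g <- cumsum(events) * params@conductancePerEventNS
    drive <- if (params@chloridePresent) 1 else 0
    iP <- drive * g * (80 - params@erevMV) + params@leakPA
    iM <- drive * g * (-80 - params@erevMV) - params@leakPA
    list(series = data.frame(t_s = tPulse, g_nS = g, i_plus80_pA = iP,
                             i_minus80_pA = iM),
         params = params)
  })
}
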