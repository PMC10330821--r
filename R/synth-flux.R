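#' @include AllClasses.R utils.R flux-kinetics.R
NULL

#' Simulate a valinomycin-triggered light-scattering flux series
#'
#' For each ligand concentration and replicate, generates a scattering trace
#' trace(t) = baseline - A x (1 - exp(-t/tau_flux)) + noise for t >= 0, with
#' a pre-trigger baseline window (t < 0; valinomycin added at t = 0) and a
#' zero-amplitude vehicle-control trace. The replicate amplitude is
#' A = amplitude x clip(HillResponse([L]; kdTrue, nTrue) + eps, 0, 1.05)
#' with eps ~ N(0, noiseSd), and the same noiseSd is added per sample as
#' instrument noise. The generator also returns its own normalized amplitude
#' table (A / amplitude per replicate), the ground truth for dose-response
#' fitting.
#'
#' @param params a [FluxSimParams-class].
#' @return list with `traces` (concentration, replicate, t_s, intensity),
#'   `control` (t_s, intensity), `doseTable` (ligand, response, replicate)
#'   and `params`.
#' @export
makeFluxSeries <- function(params) {
  stopifnot(is(params, "FluxSimParams"))
  validObject(params)
  if (length(params@ligandConcentrations) == 0L)
    stop("empty concentration list")
  ## 20-s pre-trigger baseline; run to 12 tau so the plateau is reached
  tGrid <- seq(-20, 12 * params@tauFluxS, by = params@tauFluxS / 40)
  decay <- ifelse(tGrid < 0, 0, 1 - exp(-tGrid / params@tauFluxS))
  conc <- params@ligandConcentrations
  traces <- vector("list", length(conc) * params@replicateCount)
  dose <- vector("list", length(traces))
  idx <- 0L
  for (ci in seq_along(conc)) {
    h <- hillResponse(conc[ci], params@kdTrue, params@nTrue)
    for (r in seq_len(params@replicateCount)) {
      idx <- idx + 1L
      withSeed(deriveSeed(params@seed, idx), {
        resp <- if (params@noiseSd > 0)
          min(max(h + rnorm(1, 0, params@noiseSd), 0), 1.05) else h
        y <- 1 - params@amplitude * resp * decay
        if (params@noiseSd > 0)
          y <- y + rnorm(length(tGrid), 0, params@noiseSd)
        traces[[idx]] <- data.frame(concentration = conc[ci], replicate = r,
                                    t_s = tGrid, intensity = y)
        dose[[idx]] <- data.frame(ligand = conc[ci], response = resp,
                                  replicate = r)
      })
    }
  }
  control <- withSeed(deriveSeed(params@seed, idx + 1L), {
    y <- rep(1, length(tGrid))
    if (params@noiseSd > 0) y <- y + rnorm(length(tGrid), 0, params@noiseSd)
    data.frame(t_s = tGrid, intensity = y)
  })
  list(traces = do.call(rbind, traces), control = control,
       doseTable = do.call(rbind, dose), params = params)
}
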