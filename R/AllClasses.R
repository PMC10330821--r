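#' @import methods
#' @importFrom stats rnorm runif rexp rpois qnorm pnorm dnorm optim optimize
#'   lm lm.fit coef vcov t.test sd var median quantile density setNames
#' @importFrom utils modifyList
#' @importFrom tools md5sum
NULL

## ---------------------------------------------------------------------------
## Central data containers
## ---------------------------------------------------------------------------

#' Calibrated micrograph
#'
#' A single-channel grayscale image with a physical calibration (nanometres
#' per pixel). Intensities are stored in [0, 1] and written to disk as 16-bit
#' TIFF. Pixel (i, j) of the matrix has its centre at
#' ((i - 0.5) * nmPerPx, (j - 0.5) * nmPerPx) in the continuous nm frame
#' shared with ring annotations and particle tables.
#'
#' @slot intensity numeric matrix of pixel intensities in [0, 1].
#' @slot nmPerPx positive scalar, nanometres per pixel.
#' @slot metadata list of provenance fields (seed, generator parameters, ...).
#' @exportClass Micrograph
setClass("Micrograph",
  representation(intensity = "matrix", nmPerPx = "numeric", metadata = "list"),
  prototype(intensity = matrix(0, 1, 1), nmPerPx = 1, metadata = list()))

setValidity("Micrograph", function(object) {
  if (length(object@nmPerPx) != 1L || !is.finite(object@nmPerPx) ||
      object@nmPerPx <= 0)
    return("nmPerPx must be a single positive finite number")
  if (!all(is.finite(object@intensity)))
    return("intensity must be finite everywhere")
  TRUE
})

#' Construct a Micrograph
#'
#' @param intensity numeric matrix in [0, 1].
#' @param nmPerPx nanometres per pixel (> 0).
#' @param metadata optional list of provenance fields.
#' @return A [Micrograph-class] object.
#' @export
Micrograph <- function(intensity, nmPerPx = 1, metadata = list()) {
  new("Micrograph", intensity = intensity, nmPerPx = nmPerPx,
      metadata = metadata)
}

#' Granule ring annotations
#'
#' Closed polygonal boundaries (in nm) of manually or synthetically annotated
#' secretory granules. Each ring is an n x 2 matrix of vertex coordinates;
#' the polygon is implicitly closed (last vertex connects to the first).
#'
#' @slot rings list of n x 2 numeric matrices (columns x_nm, y_nm).
#' @slot ids integer ring identifiers, parallel to `rings`.
#' @exportClass GranuleRingSet
setClass("GranuleRingSet",
  representation(rings = "list", ids = "integer"),
  prototype(rings = list(), ids = integer()))

setValidity("GranuleRingSet", function(object) {
  if (length(object@rings) != length(object@ids))
    return("ids must parallel rings")
  for (r in object@rings) {
    if (!is.matrix(r) || ncol(r) != 2L || nrow(r) < 3L)
      return("each ring must be an n x 2 matrix with n >= 3")
    if (!all(is.finite(r))) return("ring vertices must be finite")
  }
  TRUE
})

#' Construct a GranuleRingSet
#' @param rings list of n x 2 matrices of vertex coordinates in nm.
#' @param ids optional integer identifiers (default 1..length(rings)).
#' @return A [GranuleRingSet-class] object.
#' @export
GranuleRingSet <- function(rings, ids = seq_along(rings)) {
  new("GranuleRingSet", rings = rings, ids = as.integer(ids))
}

## ---------------------------------------------------------------------------
## Simulation parameter objects
## ---------------------------------------------------------------------------

#' Parameters for the synthetic immunogold field generator
#'
#' Defaults emulate high-pressure-frozen immuno-EM fields of insulin secretory
#' granules double-labelled with 6-nm gold (insulin, granule core) and 12-nm
#' gold (CHGB, membrane-proximal shell plus core). Granule radii follow a
#' truncated normal; label counts per granule are Poisson with mean
#' proportional to (R / 98)^2 so that larger granules carry more labels.
#' CHGB labels are a mixture of a membrane-proximal shell (truncated normal
#' signed distance) and a core population placed as a half-normal offset s
#' from the granule centre (d = R - s); insulin labels are core-only.
#'
#' @slot nGranules integer number of granules.
#' @slot radiusMeanNm,radiusSdNm,radiusBoundsNm truncated-normal granule
#'   radius model (nm).
#' @slot chgbCountRate,insulinCountRate mean labels per granule at R = 98 nm.
#' @slot shellWeight probability a CHGB label belongs to the shell component.
#' @slot shellMeanNm,shellSdNm,shellLowerNm truncated-normal shell distance
#'   model (nm); upper truncation is the granule radius.
#' @slot coreOffsetSigmaNm half-normal s.d. of the centre offset s (nm).
#' @slot goldDiametersNm named numeric, gold diameters for the insulin and
#'   chgb classes (nm).
#' @slot nmPerPx image calibration.
#' @slot noiseSd background Gaussian intensity noise s.d. (intensity units).
#' @slot seed integer master seed.
#' @exportClass EMFieldParams
setClass("EMFieldParams",
  representation(nGranules = "integer", radiusMeanNm = "numeric",
    radiusSdNm = "numeric", radiusBoundsNm = "numeric",
    chgbCountRate = "numeric", insulinCountRate = "numeric",
    shellWeight = "numeric", shellMeanNm = "numeric", shellSdNm = "numeric",
    shellLowerNm = "numeric", coreOffsetSigmaNm = "numeric",
    goldDiametersNm = "numeric", nmPerPx = "numeric", noiseSd = "numeric",
    seed = "integer"),
  prototype(nGranules = 324L, radiusMeanNm = 90, radiusSdNm = 40,
    radiusBoundsNm = c(40, 220), chgbCountRate = 3, insulinCountRate = 4,
    shellWeight = 0.48, shellMeanNm = 25, shellSdNm = 16, shellLowerNm = -20,
    coreOffsetSigmaNm = 6, goldDiametersNm = c(insulin = 6, chgb = 12),
    nmPerPx = 1, noiseSd = 0.02, seed = 1L))

setValidity("EMFieldParams", function(object) {
  if (object@nGranules < 0L) return("nGranules must be >= 0")
  if (object@radiusSdNm <= 0) return("radiusSdNm must be > 0")
  b <- object@radiusBoundsNm
  if (length(b) != 2L || b[1] <= 0 || b[2] <= b[1])
    return("radiusBoundsNm must be increasing and positive")
  if (object@chgbCountRate < 0 || object@insulinCountRate < 0)
    return("label count rates must be >= 0")
  if (object@shellWeight < 0 || object@shellWeight > 1)
    return("shellWeight must be in [0, 1]")
  if (object@shellSdNm <= 0 || object@coreOffsetSigmaNm <= 0)
    return("shellSdNm and coreOffsetSigmaNm must be > 0")
  if (length(object@goldDiametersNm) != 2L ||
      is.null(names(object@goldDiametersNm)) ||
      !setequal(names(object@goldDiametersNm), c("insulin", "chgb")))
    return("goldDiametersNm must be named c(insulin=, chgb=)")
  if (any(object@goldDiametersNm <= 0)) return("gold diameters must be > 0")
  if (object@nmPerPx <= 0) return("nmPerPx must be > 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' Construct EMFieldParams
#' @param nGranules number of granules (default 324, the pooled study size).
#' @param seed master seed.
#' @param ... any other slot of [EMFieldParams-class] to override.
#' @return An `EMFieldParams` object with validated slots.
#' @export
EMFieldParams <- function(nGranules = 324, seed = 1, ...) {
  new("EMFieldParams", nGranules = as.integer(nGranules),
      seed = as.integer(seed), ...)
}

#' Parameters for the two-level single-channel trace generator
#'
#' @slot unitaryConductancePS unitary conductance (pS).
#' @slot reversalMV reversal potential (mV).
#' @slot nChannels number of independent channels.
#' @slot openRate,closeRate opening/closing rates (s^-1).
#' @slot noiseSdPA Gaussian recording noise s.d. (pA).
#' @slot tauInactS irreversible inactivation time constant (s); NA disables.
#' @slot sampleIntervalS sampling interval (s).
#' @slot voltageProtocol data.frame with columns level_mV and duration_s.
#' @slot startOpen logical, start channels in the open state.
#' @slot seed integer seed.
#' @exportClass ChannelSimParams
setClass("ChannelSimParams",
  representation(unitaryConductancePS = "numeric", reversalMV = "numeric",
    nChannels = "integer", openRate = "numeric", closeRate = "numeric",
    noiseSdPA = "numeric", tauInactS = "numeric", sampleIntervalS = "numeric",
    voltageProtocol = "data.frame", startOpen = "logical", seed = "integer"),
  prototype(unitaryConductancePS = 110, reversalMV = -49, nChannels = 1L,
    openRate = 5, closeRate = 5, noiseSdPA = 0.2, tauInactS = NA_real_,
    sampleIntervalS = 1e-3,
    voltageProtocol = data.frame(level_mV = 0, duration_s = 5),
    startOpen = FALSE, seed = 1L))

setValidity("ChannelSimParams", function(object) {
  if (object@unitaryConductancePS <= 0) return("conductance must be > 0")
  if (object@nChannels < 0L) return("nChannels must be >= 0")
  if (object@openRate < 0 || object@closeRate < 0)
    return("rates must be >= 0")
  if (object@noiseSdPA < 0) return("noiseSdPA must be >= 0")
  if (!is.na(object@tauInactS) && object@tauInactS <= 0)
    return("tauInactS must be > 0 (or NA)")
  if (object@sampleIntervalS <= 0) return("sampleIntervalS must be > 0")
  vp <- object@voltageProtocol
  if (!all(c("level_mV", "duration_s") %in% names(vp)))
    return("voltageProtocol needs columns level_mV, duration_s")
  if (nrow(vp) < 1L || any(vp$duration_s <= 0))
    return("voltage step durations must be > 0")
  TRUE
})

#' Construct ChannelSimParams
#' @param seed integer seed.
#' @param ... any slot of [ChannelSimParams-class] to override.
#' @return A validated `ChannelSimParams` object.
#' @export
ChannelSimParams <- function(seed = 1, ...) {
  args <- list(...)
  if (!is.null(args$nChannels)) args$nChannels <- as.integer(args$nChannels)
  do.call(new, c(list("ChannelSimParams", seed = as.integer(seed)), args))
}

#' Parameters for the light-scattering flux assay generator
#'
#' Defaults are the bovine-CHGB chloride-inhibition condition: 8 ligand
#' concentrations log-spaced 0.01-10 mM, true k_D 0.47 mM, Hill n 1.0, three
#' replicates, amplitude noise s.d. 0.02. Use `preset = "dids"` for the DIDS
#' block condition (k_D 0.43 uM, concentrations in uM).
#'
#' @slot ligandConcentrations concentrations (units of kdTrue).
#' @slot kdTrue true dissociation constant.
#' @slot nTrue true Hill coefficient.
#' @slot amplitude full flux amplitude (arbitrary scattering units).
#' @slot tauFluxS flux relaxation time constant (s).
#' @slot replicateCount replicates per concentration.
#' @slot noiseSd amplitude/trace noise s.d.
#' @slot seed integer seed.
#' @exportClass FluxSimParams
setClass("FluxSimParams",
  representation(ligandConcentrations = "numeric", kdTrue = "numeric",
    nTrue = "numeric", amplitude = "numeric", tauFluxS = "numeric",
    replicateCount = "integer", noiseSd = "numeric", seed = "integer"),
  prototype(
    ligandConcentrations = 10^seq(log10(0.01), log10(10), length.out = 8),
    kdTrue = 0.47, nTrue = 1.0, amplitude = 1, tauFluxS = 20,
    replicateCount = 3L, noiseSd = 0.02, seed = 1L))

setValidity("FluxSimParams", function(object) {
  if (length(object@ligandConcentrations) == 0L)
    return("ligandConcentrations must be non-empty")
  if (any(object@ligandConcentrations < 0))
    return("concentrations must be >= 0")
  if (object@kdTrue <= 0 || object@nTrue <= 0)
    return("kdTrue and nTrue must be > 0")
  if (object@amplitude <= 0 || object@tauFluxS <= 0)
    return("amplitude and tauFluxS must be > 0")
  if (object@replicateCount < 1L) return("replicateCount must be >= 1")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' Construct FluxSimParams
#' @param preset "chloride" (k_D 0.47 mM) or "dids" (k_D 0.43 uM); sets the
#'   true parameters and a matching log-spaced concentration grid.
#' @param seed integer seed.
#' @param ... any slot of [FluxSimParams-class] to override the preset.
#' @return A validated `FluxSimParams` object.
#' @export
FluxSimParams <- function(preset = c("chloride", "dids"), seed = 1, ...) {
  preset <- match.arg(preset)
  args <- list(...)
  if (preset == "dids") {
    if (is.null(args$kdTrue)) args$kdTrue <- 0.43
    if (is.null(args$ligandConcentrations))
      args$ligandConcentrations <-
        10^seq(log10(0.01), log10(10), length.out = 8)
  }
  if (!is.null(args$replicateCount))
    args$replicateCount <- as.integer(args$replicateCount)
  do.call(new, c(list("FluxSimParams", seed = as.integer(seed)), args))
}

#' Parameters for the depolarization-evoked whole-cell session generator
#'
#' Emulates 1-Hz depolarizing pulse trains that trigger calcium-dependent
#' granule fusion; each fusion event adds a fixed anion conductance to the
#' cell surface, so the per-pulse peak current grows as a compound-Poisson
#' staircase. Defaults give ~30 nS of added conductance over a 300-s session,
#' of the order of the ~28 nS per cell seen in stimulated neuroendocrine
#' cells.
#'
#' @slot pulseRateHz depolarizing pulse rate.
#' @slot fusionRatePerPulse mean fusion events per pulse (Poisson).
#' @slot conductancePerEventNS conductance added per fusion event (nS).
#' @slot erevMV anion reversal potential (mV).
#' @slot leakPA leak current at +80 mV (pA).
#' @slot calciumPresent logical; without calcium no fusion occurs.
#' @slot chloridePresent logical; without chloride the anionic driving force
#'   term is zero and only leak remains.
#' @slot durationS session duration (s).
#' @slot seed integer seed.
#' @exportClass SecretionSimParams
setClass("SecretionSimParams",
  representation(pulseRateHz = "numeric", fusionRatePerPulse = "numeric",
    conductancePerEventNS = "numeric", erevMV = "numeric", leakPA = "numeric",
    calciumPresent = "logical", chloridePresent = "logical",
    durationS = "numeric", seed = "integer"),
  prototype(pulseRateHz = 1, fusionRatePerPulse = 0.5,
    conductancePerEventNS = 0.2, erevMV = -62, leakPA = 50,
    calciumPresent = TRUE, chloridePresent = TRUE, durationS = 300,
    seed = 1L))

setValidity("SecretionSimParams", function(object) {
  if (object@pulseRateHz <= 0 || object@durationS <= 0)
    return("pulseRateHz and durationS must be > 0")
  if (object@fusionRatePerPulse < 0) return("fusionRatePerPulse must be >= 0")
  if (object@conductancePerEventNS <= 0)
    return("conductancePerEventNS must be > 0")
  TRUE
})

#' Construct SecretionSimParams
#' @param seed integer seed.
#' @param ... any slot of [SecretionSimParams-class] to override.
#' @return A validated `SecretionSimParams` object.
#' @export
SecretionSimParams <- function(seed = 1, ...) {
  do.call(new, c(list("SecretionSimParams", seed = as.integer(seed)),
                 list(...)))
}

## ---------------------------------------------------------------------------
## Recording condition (ionic composition)
## ---------------------------------------------------------------------------

#' Two-sided ionic recording condition
#'
#' Holds the ionic composition on the cis and trans sides of a membrane with
#' per-species valence and relative permeability, plus the temperature. The
#' trans compartment is the reference ("inner") side throughout, so
#' `nernstPotential()` with this convention reproduces the standard
#' signs for a 150/30 mM KCl gradient (-41.2 mV for Cl-, +41.2 mV for K+ at
#' 297.1 K).
#'
#' @slot species data.frame with columns name, z, concCis, concTrans,
#'   relPermeability.
#' @slot temperatureK absolute temperature (K), default 297.1.
#' @exportClass RecordingCondition
setClass("RecordingCondition",
  representation(species = "data.frame", temperatureK = "numeric"),
  prototype(species = data.frame(name = character(), z = integer(),
    concCis = numeric(), concTrans = numeric(), relPermeability = numeric()),
    temperatureK = 297.1))

setValidity("RecordingCondition", function(object) {
  sp <- object@species
  need <- c("name", "z", "concCis", "concTrans", "relPermeability")
  if (!all(need %in% names(sp)))
    return(paste("species needs columns:", paste(need, collapse = ", ")))
  if (object@temperatureK <= 0) return("temperatureK must be > 0")
  if (nrow(sp)) {
    if (any(sp$concCis < 0 | sp$concTrans < 0))
      return("concentrations must be >= 0")
    if (any(sp$relPermeability < 0))
      return("relative permeabilities must be >= 0")
    if (any(sp$z == 0)) return("valence must be nonzero")
    perm <- sp$relPermeability > 0
    if (any(perm & sp$concCis == 0 & sp$concTrans == 0))
      return("a permeant species needs a nonzero concentration on one side")
  }
  TRUE
})

#' Define one ionic species
#'
#' @param name species label, e.g. "Cl".
#' @param z signed valence (|z| in {1, 2}).
#' @param concCis,concTrans concentrations (mM) on the cis / trans sides.
#' @param relPermeability relative permeability (dimensionless, >= 0).
#' @return One-row data.frame suitable for [recordingCondition()].
#' @export
ionSpecies <- function(name, z, concCis, concTrans, relPermeability = 1) {
  stopifnot(abs(z) %in% c(1, 2))
  data.frame(name = name, z = as.integer(z), concCis = concCis,
             concTrans = concTrans, relPermeability = relPermeability)
}

#' Assemble a RecordingCondition
#'
#' @param ... one-row data.frames from [ionSpecies()], or a single data.frame.
#' @param temperatureK absolute temperature in K (default 297.1).
#' @return A [RecordingCondition-class] object.
#' @export
recordingCondition <- function(..., temperatureK = 297.1) {
  parts <- list(...)
  sp <- if (length(parts) == 1L && is.data.frame(parts[[1]]) &&
            nrow(parts[[1]]) != 1L) parts[[1]] else do.call(rbind, parts)
  new("RecordingCondition", species = sp, temperatureK = temperatureK)
}

## ---------------------------------------------------------------------------
## Fitted-model result objects
## ---------------------------------------------------------------------------

#' Linear current-voltage fit
#' @slot slopePS fitted slope conductance (pS).
#' @slot erevMV fitted reversal potential (mV), -intercept/slope.
#' @slot slopeSePS,erevSeMV standard errors.
#' @slot r2 coefficient of determination.
#' @slot n number of points.
#' @exportClass ConductanceFit
setClass("ConductanceFit",
  representation(slopePS = "numeric", erevMV = "numeric", slopeSePS = "numeric",
    erevSeMV = "numeric", r2 = "numeric", n = "integer"))

#' Unitary current amplitude estimate
#' @slot meanIpA dwell-weighted mean open-minus-closed current (pA).
#' @slot sdPA pooled sample s.d. of the open-level samples (pA).
#' @slot nEvents number of open dwell segments.
#' @exportClass AmplitudeEstimate
setClass("AmplitudeEstimate",
  representation(meanIpA = "numeric", sdPA = "numeric", nEvents = "integer"))

setValidity("AmplitudeEstimate", function(object)
  if (object@nEvents < 1L) "nEvents must be >= 1" else TRUE)

#' Single-exponential inactivation fit
#' @slot tauS time constant (s).
#' @slot amplitudePA decaying amplitude (pA).
#' @slot offsetPA steady-state offset (pA).
#' @slot rmse root-mean-square residual (pA).
#' @slot flagged TRUE when the data did not decay (tau at bound).
#' @exportClass InactivationFit
setClass("InactivationFit",
  representation(tauS = "numeric", amplitudePA = "numeric",
    offsetPA = "numeric", rmse = "numeric", flagged = "logical"))

setValidity("InactivationFit", function(object)
  if (object@tauS <= 0) "tauS must be > 0" else TRUE)

#' Hill dose-response fit
#' @slot kd dissociation constant (input concentration units).
#' @slot hillN Hill coefficient.
#' @slot rss residual sum of squares.
#' @slot ci optional bootstrap 95% CIs, matrix with rows kd, hillN.
#' @slot nBoot number of bootstrap replicates (0 = none).
#' @slot seed bootstrap seed.
#' @exportClass HillFit
setClass("HillFit",
  representation(kd = "numeric", hillN = "numeric", rss = "numeric",
    ci = "matrix", nBoot = "integer", seed = "integer"),
  prototype(ci = matrix(numeric(0), 0, 2), nBoot = 0L, seed = NA_integer_))

setValidity("HillFit", function(object) {
  if (object@kd <= 0) return("kd must be > 0")
  if (object@hillN <= 0) return("hillN must be > 0")
  TRUE
})

#' One-dimensional Gaussian mixture fit of radial distances
#' @slot k number of components (1 or 2).
#' @slot weights,means,sds per-component parameters (weights sum to 1, nm).
#' @slot logLik final log-likelihood.
#' @slot bic Bayesian information criterion.
#' @slot converged logical convergence flag.
#' @slot separationP Welch-t p-value between posterior-assigned subgroups
#'   (NA for k = 1).
#' @slot logLikTrace per-iteration log-likelihood of the best start.
#' @slot n sample size.
#' @exportClass RadialMixtureFit
setClass("RadialMixtureFit",
  representation(k = "integer", weights = "numeric", means = "numeric",
    sds = "numeric", logLik = "numeric", bic = "numeric",
    converged = "logical", separationP = "numeric", logLikTrace = "numeric",
    n = "integer"))

setValidity("RadialMixtureFit", function(object) {
  if (length(object@weights) != object@k ||
      length(object@means) != object@k || length(object@sds) != object@k)
    return("component vectors must have length k")
  if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-6)
    return("weights must be >= 0 and sum to 1")
  if (any(object@sds <= 0)) return("sds must be > 0")
  TRUE
})

#' Antibody/gold label geometry
#'
#' Sizes (nm) of the immunolabelling sandwich used to bound how far a gold
#' particle can sit from the epitope it reports: primary antibody, gold-
#' conjugated secondary antibody, chemical linker, the epitope-bearing part
#' of the target protein outside the membrane, the gold particle itself, and
#' the bilayer thickness.
#'
#' @slot primaryAb,secondaryAb,linker,epitopeExtension,goldDiameter,bilayer
#'   lengths in nm, all >= 0.
#' @exportClass LabelGeometry
setClass("LabelGeometry",
  representation(primaryAb = "numeric", secondaryAb = "numeric",
    linker = "numeric", epitopeExtension = "numeric",
    goldDiameter = "numeric", bilayer = "numeric"),
  prototype(primaryAb = 14.5, secondaryAb = 14.5, linker = 1,
    epitopeExtension = 4, goldDiameter = 12, bilayer = 4))

setValidity("LabelGeometry", function(object) {
  v <- c(object@primaryAb, object@secondaryAb, object@linker,
         object@epitopeExtension, object@goldDiameter, object@bilayer)
  if (any(v < 0)) "all geometry lengths must be >= 0" else TRUE
})

#' Construct a LabelGeometry
#' @param ... any slot of [LabelGeometry-class] to override the defaults
#'   (14.5-nm antibodies, 1-nm linker, 4-nm epitope extension, 12-nm gold,
#'   4-nm bilayer).
#' @return A validated `LabelGeometry` object.
#' @export
LabelGeometry <- function(...) new("LabelGeometry", ...)
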