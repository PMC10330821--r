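#' @include AllClasses.R immunogold.R mixture.R io.R
NULL

#' Densitometric purity of a gel lane
#'
#' 100 x sum(main-band intensities) / sum(all band intensities).
#'
#' @param intensities non-negative band intensities (at least one band).
#' @param mainIndices indices of the band(s) attributed to the protein of
#'   interest.
#' @return Purity in percent.
#' @examples
#' bandPurity(c(992, 5, 3), 1) # 99.2
#' @export
bandPurity <- function(intensities, mainIndices) {
  if (!length(intensities)) stop("empty lane profile")
  if (any(intensities < 0)) stop("band intensities must be >= 0")
  tot <- sum(intensities)
  if (tot <= 0) stop("lane profile sums to zero")
  100 * sum(intensities[mainIndices]) / tot
}

#' Normalized distribution of a lane or fraction profile
#'
#' intensities / sum(intensities); sums to 1 and is equivariant under
#' permutation of the bands.
#'
#' @param intensities non-negative intensities (not all zero).
#' @return Normalized numeric vector.
#' @export
fractionProfile <- function(intensities) {
  if (!length(intensities)) stop("empty profile")
  if (any(intensities < 0)) stop("band intensities must be >= 0")
  tot <- sum(intensities)
  if (tot <= 0) stop("profile sums to zero")
  intensities / tot
}

#' Run manifest for reproducible pipeline reports
#'
#' Records the command, configuration snapshot, master seed, input hashes
#' (MD5 for on-disk inputs), package version and timestamp. Reports citing
#' the same manifest are reproducible.
#'
#' @param command character label of the operation.
#' @param config list of configuration values.
#' @param seed master seed.
#' @param inputFiles optional character vector of input paths to hash.
#' @return list with manifest fields.
#' @export
makeRunManifest <- function(command, config = list(), seed = NA_integer_,
                            inputFiles = character()) {
  hashes <- if (length(inputFiles)) as.list(tools::md5sum(inputFiles))
            else list()
  list(command = command, config = config, seed = seed,
       input_hashes = hashes,
       package_version = as.character(utils::packageVersion("GranulePhys")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

stageCall <- function(stage, imageId, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for input '%s': %s", stage, imageId,
                 conditionMessage(e)), call. = FALSE))
}

#' End-to-end immunogold quantification pipeline
#'
#' Chains, for each field: particle segmentation, feature extraction,
#' size/shape classification, ring assignment and signed membrane distance
#' measurement; then pools particles across fields (as pooling across
#' independent experiments) and computes the study summaries: 20-nm distance
#' histograms per class, a two-component Gaussian mixture of the CHGB
#' distances and a one-component fit of the insulin distances, the fraction
#' of CHGB labels within the membrane zone, and the mean ring
#' equivalent-circle diameter. Any stage error propagates with the stage
#' name and input id.
#'
#' @param images a [Micrograph-class] or list of them.
#' @param rings a [GranuleRingSet-class] or list of them (one per image).
#' @param config list of stage options: `extensionNm` (ring dilation, 20),
#'   `binWidth` (20), `zoneCutoff` (40), `zoneLower` (-20), `mixtureSeed`
#'   (1), plus any [segmentParticles()] parameter.
#' @return list with `particles` (pooled table), `histograms` (per class),
#'   `mixtureChgb`, `mixtureInsulin`, `summary` (named numerics) and
#'   `manifest`.
#' @export
runEMPipeline <- function(images, rings, config = list()) {
  if (is(images, "Micrograph")) images <- list(images)
  if (is(rings, "GranuleRingSet")) rings <- list(rings)
  if (length(images) != length(rings))
    stop("need one ring set per image")
  cfg <- utils::modifyList(list(extensionNm = 20, binWidth = 20,
    zoneCutoff = 40, zoneLower = -20, mixtureSeed = 1,
    dogSigmaLowNm = 1, dogSigmaHighNm = 32, minSeedSepNm = 4,
    watershedTolerance = 0.1), config)
  parts <- vector("list", length(images))
  ringOffset <- 0L
  for (f in seq_along(images)) {
    id <- sprintf("image_%d", f)
    seg <- stageCall("segment", id,
      segmentParticles(images[[f]], cfg$dogSigmaLowNm, cfg$dogSigmaHighNm,
                       cfg$minSeedSepNm, cfg$watershedTolerance))
    feat <- stageCall("features", id, extractParticleFeatures(seg))
    cls <- stageCall("classify", id, classifyParticles(feat))
    asg <- stageCall("assign", id,
      assignToRings(cls, rings[[f]], cfg$extensionNm))
    asg$field <- f
    asg$ring_id <- asg$ring_id + ringOffset
    ringOffset <- ringOffset + length(rings[[f]]@rings)
    parts[[f]] <- asg
  }
  particles <- do.call(rbind, parts)
  analyzed <- particles[!particles$removed & !is.na(particles$ring_id), ]
  dC <- analyzed$d_nm[analyzed$class == "chgb"]
  dI <- analyzed$d_nm[analyzed$class == "insulin"]
  histC <- stageCall("histogram", "chgb",
    distanceHistogram(dC, cfg$binWidth, cfg$zoneLower))
  histI <- stageCall("histogram", "insulin",
    distanceHistogram(dI, cfg$binWidth, cfg$zoneLower))
  mixC <- stageCall("mixture", "chgb",
    fitRadialMixture(dC, k = 2, seed = cfg$mixtureSeed))
  mixI <- stageCall("mixture", "insulin",
    fitRadialMixture(dI, k = 1, seed = cfg$mixtureSeed))
  diams <- unlist(lapply(rings, equivalentDiameters))
  summary <- c(
    nParticles = nrow(analyzed),
    nChgb = length(dC),
    nInsulin = length(dI),
    nRings = length(diams),
    meanEquivalentDiameterNm = mean(diams),
    fracChgbWithinZone = fractionWithinMembraneZone(dC, cfg$zoneCutoff,
                                                    cfg$zoneLower),
    proximalPeakNm = min(mixC@means),
    distalPeakNm = max(mixC@means),
    insulinPeakNm = mixI@means,
    separationP = mixC@separationP)
  list(particles = particles, histograms = list(chgb = histC, insulin = histI),
       mixtureChgb = mixC, mixtureInsulin = mixI, summary = summary,
       manifest = makeRunManifest("runEMPipeline", cfg,
                                  seed = cfg$mixtureSeed))
}
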