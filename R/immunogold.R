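#' @include AllClasses.R utils.R
#' @importFrom EBImage gblur otsu fillHull watershed Image
#'   imageData computeFeatures.moment computeFeatures.shape
NULL

#' Detect gold-label particles in a calibrated micrograph
#'
#' Deterministic segmentation chain for immunogold micrographs:
#' (1) contrast inversion and a difference-of-Gaussians band-pass (the
#' deterministic stand-in for a trained pixel-probability map), rescaled to
#' [0, 1]; (2) Otsu threshold on a 256-bin histogram; (3) hole filling;
#' (4) watershed splitting of touching particles, seeded at local maxima of
#' the enhanced intensity inside the mask (each gold disk keeps its own
#' intensity peak even in dense clusters, where distance-map maxima merge);
#' (5) connected-component labelling with border-touching components
#' removed.
#'
#' The high-pass sigma defaults to 32 nm rather than the 12-nm disk size:
#' labels cluster in granule cores, and a tighter high-pass subtracts a
#' cluster's own local mean, eroding member disks below the 20-nm^2 noise
#' cutoff.
#'
#' @param img a [Micrograph-class] (calibration is required; a bare matrix
#'   is rejected).
#' @param dogSigmaLowNm,dogSigmaHighNm band-pass Gaussian sigmas in nm
#'   (defaults 1 and 32).
#' @param minSeedSepNm minimum separation of watershed seed maxima in nm
#'   (default 4; sets the maxima detection neighbourhood).
#' @param watershedTolerance minimum enhanced-intensity depth separating two
#'   objects (default 0.1).
#' @return list with `labels` (integer label matrix), `enhanced` (the [0,1]
#'   band-passed image used as intensity reference) and `nmPerPx`.
#' @export
segmentParticles <- function(img, dogSigmaLowNm = 1, dogSigmaHighNm = 32,
                             minSeedSepNm = 4, watershedTolerance = 0.1) {
  if (!is(img, "Micrograph"))
    stop("segmentParticles needs a calibrated Micrograph")
  nmpp <- img@nmPerPx
  inv <- 1 - img@intensity
  sigCap <- (floor((min(dim(inv)) - 1) / 2) - 1) / 3  # keep kernel <= image
  s1 <- min(max(dogSigmaLowNm / nmpp, 0.5), sigCap)
  s2 <- min(dogSigmaHighNm / nmpp, sigCap)
  enh <- EBImage::gblur(inv, sigma = s1) - EBImage::gblur(inv, sigma = s2)
  rng <- range(enh)
  empty <- list(labels = matrix(0L, nrow(inv), ncol(inv)),
                enhanced = matrix(0, nrow(inv), ncol(inv)), nmPerPx = nmpp)
  if (diff(rng) < 1e-9) return(empty)
  enh <- (enh - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(enh), range = c(0, 1), levels = 256)
  mask <- enh > th
  if (!any(mask)) return(empty)
  mask <- EBImage::fillHull(EBImage::Image(mask))
  ext <- max(1L, round(minSeedSepNm / nmpp / 4))
  lab <- EBImage::watershed(EBImage::Image(enh * EBImage::imageData(mask)),
                            tolerance = watershedTolerance, ext = ext)
  lab <- EBImage::imageData(lab)
  ## drop components touching the field border
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  if (length(border)) lab[lab %in% border] <- 0L
  ## relabel sequentially
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids)) lab[] <- match(lab, c(0L, ids), nomatch = 1L) - 1L
  list(labels = lab, enhanced = enh, nmPerPx = nmpp)
}

#' Measure particle features from a labelled mask
#'
#' Computes, per labelled component: area (pixel count x (nm/px)^2),
#' intensity-weighted centroid on the enhanced image, and the moment-fit
#' ellipse (major/minor axes, eccentricity = sqrt(1 - (minor/major)^2)).
#' Coordinates are continuous nm with pixel centres at (i - 0.5) x nm/px.
#'
#' @param seg segmentation result from [segmentParticles()], or a list with
#'   `labels`, `enhanced`, `nmPerPx`.
#' @return data.frame with columns id, x_nm, y_nm, area_nm2, major_nm,
#'   minor_nm, ecc. Empty mask gives an empty table.
#' @export
extractParticleFeatures <- function(seg) {
  lab <- seg$labels; nmpp <- seg$nmPerPx
  emptyTab <- data.frame(id = integer(), x_nm = numeric(), y_nm = numeric(),
    area_nm2 = numeric(), major_nm = numeric(), minor_nm = numeric(),
    ecc = numeric())
  if (max(lab) == 0L) return(emptyTab)
  sh <- EBImage::computeFeatures.shape(lab)
  mo <- EBImage::computeFeatures.moment(lab, ref = seg$enhanced)
  major <- mo[, "m.majoraxis"] * nmpp
  ecc <- mo[, "m.eccentricity"]
  data.frame(id = seq_len(nrow(sh)),
             x_nm = (mo[, "m.cx"] - 0.5) * nmpp,
             y_nm = (mo[, "m.cy"] - 0.5) * nmpp,
             area_nm2 = sh[, "s.area"] * nmpp^2,
             major_nm = major,
             minor_nm = major * sqrt(pmax(0, 1 - ecc^2)),
             ecc = ecc, row.names = NULL)
}

#' Classify detected particles by size and shape
#'
#' Area < 20 nm^2 is removed as noise; 20 <= area < 65 nm^2 is classed as
#' insulin (6-nm gold); area >= 65 nm^2 is classed as chgb (12-nm gold);
#' then any particle with eccentricity > 0.75 is removed. The result is a
#' partition: every detected particle is exactly one of removed (noise),
#' removed (eccentricity), insulin, or chgb.
#'
#' @param table feature table from [extractParticleFeatures()].
#' @param noiseMaxArea,insulinMaxArea area class boundaries in nm^2
#'   (defaults 20 and 65; boundaries are inclusive on the upper class).
#' @param eccMax maximum allowed eccentricity (default 0.75).
#' @return the table with added columns `class` ("noise", "insulin",
#'   "chgb"), `removed` (logical) and `removalReason` ("noise",
#'   "eccentricity" or NA).
#' @export
classifyParticles <- function(table, noiseMaxArea = 20, insulinMaxArea = 65,
                              eccMax = 0.75) {
  cls <- ifelse(table$area_nm2 < noiseMaxArea, "noise",
                ifelse(table$area_nm2 < insulinMaxArea, "insulin", "chgb"))
  removed <- cls == "noise"
  reason <- ifelse(removed, "noise", NA_character_)
  eccOut <- !removed & table$ecc > eccMax
  removed[eccOut] <- TRUE
  reason[eccOut] <- "eccentricity"
  table$class <- cls
  table$removed <- removed
  table$removalReason <- reason
  table
}

## signed distance of points (n x 2 nm) to one ring polygon:
## positive inside, negative outside
signedDistanceToRing <- function(pts, ring) {
  d <- pointPolylineDistance(pts, ring)
  ifelse(pointInPolygon(pts, ring), d, -d)
}

#' Signed distance from a particle centroid to its granule membrane
#'
#' Minimum Euclidean distance from the centroid to the ring boundary
#' polyline, signed positive inside the granule and negative outside.
#'
#' @param centroid numeric c(x_nm, y_nm) or an n x 2 matrix of centroids.
#' @param ring an n x 2 ring polygon matrix (nm).
#' @return Signed distance(s) in nm.
#' @export
signedMembraneDistance <- function(centroid, ring) {
  pts <- if (is.matrix(centroid)) centroid else matrix(centroid, ncol = 2)
  signedDistanceToRing(pts, ring)
}

#' Assign particles to granule rings
#'
#' A particle belongs to a ring when its centroid lies inside the ring
#' polygon dilated outward by `extensionNm` (i.e. signed distance
#' >= -extensionNm). Particles inside no extended ring get `ring_id` NA and
#' are excluded downstream; a particle inside two extended rings goes to the
#' ring whose boundary is nearest (smallest |signed distance|).
#'
#' @param table classified particle table with columns x_nm, y_nm.
#' @param rings a [GranuleRingSet-class].
#' @param extensionNm outward dilation of each ring (default 20).
#' @return the table with added columns `ring_id` and `d_nm` (signed
#'   distance to the assigned ring; NA when unassigned).
#' @export
assignToRings <- function(table, rings, extensionNm = 20) {
  if (!is(rings, "GranuleRingSet") || length(rings@rings) == 0L)
    stop("no rings supplied")
  n <- nrow(table)
  table$ring_id <- NA_integer_
  table$d_nm <- NA_real_
  if (n == 0L) return(table)
  pts <- cbind(table$x_nm, table$y_nm)
  ## candidate pruning by ring bounding circle
  centers <- t(vapply(rings@rings, colMeans, numeric(2)))
  maxR <- vapply(seq_along(rings@rings), function(j) {
    rg <- rings@rings[[j]]
    sqrt(max((rg[, 1] - centers[j, 1])^2 + (rg[, 2] - centers[j, 2])^2))
  }, numeric(1))
  bestAbs <- rep(Inf, n)
  for (j in seq_along(rings@rings)) {
    near <- which(sqrt((pts[, 1] - centers[j, 1])^2 +
                       (pts[, 2] - centers[j, 2])^2) <=
                  maxR[j] + extensionNm + 5)
    if (!length(near)) next
    d <- signedDistanceToRing(pts[near, , drop = FALSE], rings@rings[[j]])
    inExt <- d >= -extensionNm
    better <- inExt & abs(d) < bestAbs[near]
    upd <- near[better]
    bestAbs[upd] <- abs(d[better])
    table$ring_id[upd] <- rings@ids[j]
    table$d_nm[upd] <- d[better]
  }
  table
}

#' Histogram of signed membrane distances
#'
#' Left-closed 20-nm bins [-20, 0), [0, 20), ... by default. Distances below
#' the lower edge are counted in an explicit underflow bin (attribute
#' `underflow`) and flagged with a warning; total counts (including
#' underflow) conserve the input size.
#'
#' @param distances numeric distances (nm).
#' @param binWidth bin width in nm (> 0, default 20).
#' @param lower lower edge of the first bin (default -20).
#' @return data.frame with columns lower, upper, count; attribute
#'   `underflow` holds the below-range count.
#' @export
distanceHistogram <- function(distances, binWidth = 20, lower = -20) {
  if (binWidth <= 0) stop("binWidth must be > 0")
  d <- distances[is.finite(distances)]
  under <- sum(d < lower)
  if (under > 0)
    warning(under, " distance(s) below the lower edge counted as underflow")
  dIn <- d[d >= lower]
  nBins <- max(1, ceiling((max(dIn, lower + binWidth / 2) - lower) / binWidth))
  edges <- lower + binWidth * (0:nBins)
  idx <- pmin(floor((dIn - lower) / binWidth) + 1L, nBins)
  counts <- tabulate(idx, nbins = nBins)
  out <- data.frame(lower = edges[-length(edges)], upper = edges[-1],
                    count = counts)
  attr(out, "underflow") <- under
  out
}

#' Fraction of labels within the membrane zone
#'
#' Fraction of distances d with lower <= d <= cutoff: the "within 40 nm of
#' the membrane, inside or outside the granule edge" statistic (the lower
#' bound -20 nm is the ring analysis extension).
#'
#' @param distances numeric distances (nm).
#' @param cutoff upper bound (default 40).
#' @param lower lower bound (default -20).
#' @return Fraction in [0, 1] (NaN for empty input).
#' @export
fractionWithinMembraneZone <- function(distances, cutoff = 40, lower = -20) {
  d <- distances[is.finite(distances)]
  mean(d >= lower & d <= cutoff)
}

#' Geometric bounds on gold-label displacement from the membrane
#'
#' Given the label sandwich geometry (primary antibody, gold-conjugated
#' secondary antibody, linker, epitope extension beyond the membrane, gold
#' diameter, bilayer thickness), returns the maximum distances a gold
#' particle reporting a membrane-inserted epitope can sit from the membrane:
#' luminal = (linker + epitope) + both antibodies + gold radius;
#' external = both antibodies - (linker + epitope) + gold radius - bilayer.
#' Default geometry gives (40, 26) nm.
#'
#' @param geom a [LabelGeometry-class].
#' @return named numeric c(luminalMaxNm, externalMaxNm).
#' @export
labelDisplacementBounds <- function(geom = LabelGeometry()) {
  stopifnot(is(geom, "LabelGeometry"))
  ab <- geom@primaryAb + geom@secondaryAb
  reach <- geom@linker + geom@epitopeExtension
  c(luminalMaxNm = reach + ab + geom@goldDiameter / 2,
    externalMaxNm = ab - reach + geom@goldDiameter / 2 - geom@bilayer)
}
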