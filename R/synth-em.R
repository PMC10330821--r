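#' @include AllClasses.R utils.R
NULL

## Render anti-aliased dark disks (gold labels) into an intensity matrix.
## Coverage per pixel is clamp((r - d)/nmPerPx + 0.5, 0, 1), a 1-px smooth
## edge approximating the area fraction of the pixel under the disk.
renderDisks <- function(img, xNm, yNm, rNm, depth, nmPerPx) {
  nx <- nrow(img); ny <- ncol(img)
  for (k in seq_along(xNm)) {
    r <- rNm[k]
    i0 <- max(1L, floor((xNm[k] - r) / nmPerPx) - 1L)
    i1 <- min(nx, ceiling((xNm[k] + r) / nmPerPx) + 2L)
    j0 <- max(1L, floor((yNm[k] - r) / nmPerPx) - 1L)
    j1 <- min(ny, ceiling((yNm[k] + r) / nmPerPx) + 2L)
    if (i0 > i1 || j0 > j1) next
    px <- (i0:i1 - 0.5) * nmPerPx
    py <- (j0:j1 - 0.5) * nmPerPx
    d <- sqrt(outer((px - xNm[k])^2, (py - yNm[k])^2, `+`))
    cov <- pmin(1, pmax(0, (r - d) / nmPerPx + 0.5))
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] - depth * cov
  }
  img
}

## Non-overlapping granule placement: largest-first random sequential
## addition into a square field sized for ~35% packing.
placeGranules <- function(radii, marginNm = 8, maxTries = 300L) {
  n <- length(radii)
  if (n == 0L) return(list(x = numeric(0), y = numeric(0), sideNm = 256))
  sideNm <- max(2 * max(radii) + 80,
                ceiling(sqrt(sum(pi * (radii + 15)^2) / 0.35)))
  ord <- order(radii, decreasing = TRUE)
  x <- y <- numeric(n)
  for (k in ord) {
    r <- radii[k]
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      cx <- runif(1, r + marginNm, sideNm - r - marginNm)
      cy <- runif(1, r + marginNm, sideNm - r - marginNm)
      placed <- ord[seq_len(which(ord == k) - 1L)]
      if (!length(placed) ||
          all(sqrt((x[placed] - cx)^2 + (y[placed] - cy)^2) >
              radii[placed] + r + 6)) {
        x[k] <- cx; y[k] <- cy; ok <- TRUE; break
      }
    }
    if (!ok) stop("granule placement failed: field too crowded")
  }
  list(x = x, y = y, sideNm = sideNm)
}

## Place labels at their drawn membrane distances d (nm) around a granule
## centre with a 2-nm clearance between gold disks. Every drawn distance is
## kept when an angle with free space exists at its radius; a label whose
## radius cannot host it (e.g. several draws within a few nm of the centre)
## is lifted minimally outward in 1-nm steps until space is found, and the
## realized distance is recorded in the truth table. This minimal-lift
## packing keeps labels individually resolvable while distorting the
## distance distribution far less than re-drawing from the model would.
placeLabels <- function(d, cx, cy, R, goldR, occupied) {
  n <- length(d)
  xs <- ys <- numeric(n)
  ## process central labels first so that minimal lifts stay minimal
  ord <- order(R - d)
  for (k in ord) {
    sk <- R - d[k]
    thOff <- runif(1, 0, 2 * pi)
    if (nrow(occupied)) {
      ## resolvability limits measured for the rendering + watershed chain:
      ## equal 6-nm disks split at 7.5-nm centres, equal 12-nm at 13,
      ## mixed at 9.5 (+0.5 safety where asymmetric)
      minSep <- ifelse(abs(occupied[, 3] - goldR) < 1e-9,
                       pmax(2 * goldR + 1.5, 2 * goldR * 13 / 12),
                       occupied[, 3] + goldR + 1)
    } else minSep <- numeric(0)
    placed <- FALSE
    for (lift in seq(0, max(0, R + 20 - sk), by = 0.5)) {
      rho <- sk + lift
      for (th in thOff + 2 * pi * (0:47) / 48) {
        px <- cx + rho * cos(th); py <- cy + rho * sin(th)
        if (!nrow(occupied) ||
            all(sqrt((occupied[, 1] - px)^2 + (occupied[, 2] - py)^2) >
                minSep)) {
          placed <- TRUE; break
        }
      }
      if (placed) break
    }
    if (!placed) {  # cap reached (d floor -20): accept at the drawn radius
      rho <- sk
      px <- cx + rho * cos(thOff); py <- cy + rho * sin(thOff)
    }
    xs[k] <- px; ys[k] <- py; d[k] <- R - rho
    occupied <- rbind(occupied, c(px, py, goldR))
  }
  list(x = xs, y = ys, d = d, occupied = occupied)
}

#' Simulate a calibrated immunogold EM field with ground truth
#'
#' Generates a synthetic high-pressure-frozen immuno-EM field: granules with
#' truncated-normal radii placed without overlap, ring annotations (64-gon
#' circles at each granule boundary), and gold labels rendered as dark
#' anti-aliased disks — 6-nm gold for insulin (core-only, placed at a
#' half-normal offset s from the centre so d = R - s) and 12-nm gold for
#' CHGB (a `shellWeight` : 1-shellWeight mixture of a membrane-proximal
#' truncated-normal shell and the same core model). Label counts per granule
#' are Poisson with mean proportional to (R/98)^2. Every generated label is
#' recorded in a ground-truth table with its class, true centroid and true
#' signed membrane distance. Identical parameters and seed give bit-identical
#' output.
#'
#' @param params an [EMFieldParams-class].
#' @return list with `image` ([Micrograph-class]), `rings`
#'   ([GranuleRingSet-class]), `truth` (data.frame id, class, x_nm, y_nm,
#'   d_nm, ring_id, granule_r_nm) and `params`.
#' @export
makeEMField <- function(params) {
  stopifnot(is(params, "EMFieldParams"))
  validObject(params)
  bg <- 0.75; depth <- 0.45
  emptyTruth <- data.frame(id = integer(), class = character(),
    x_nm = numeric(), y_nm = numeric(), d_nm = numeric(),
    ring_id = integer(), granule_r_nm = numeric())
  ## granule radii and placement from the master substream
  geom <- withSeed(deriveSeed(params@seed, 0L), {
    radii <- rtruncnorm(params@nGranules, params@radiusMeanNm,
      params@radiusSdNm, params@radiusBoundsNm[1], params@radiusBoundsNm[2])
    c(placeGranules(radii), list(radii = radii))
  })
  sidePx <- ceiling(geom$sideNm / params@nmPerPx)
  truth <- list()
  rings <- vector("list", params@nGranules)
  occupied <- matrix(numeric(0), 0, 3)  # global: labels never overlap
  for (g in seq_len(params@nGranules)) {
    R <- geom$radii[g]
    rings[[g]] <- circlePolygon(geom$x[g], geom$y[g], R)
    res <- withSeed(deriveSeed(params@seed, g), {
      scale <- (R / 98)^2
      nC <- rpois(1, params@chgbCountRate * scale)
      nI <- rpois(1, params@insulinCountRate * scale)
      drawShell <- function() rtruncnorm(1, params@shellMeanNm,
        params@shellSdNm, params@shellLowerNm, R)
      drawCore <- function() R - abs(rnorm(1, 0, params@coreOffsetSigmaNm))
      out <- list()
      ## place the small insulin gold first: 6-nm disks pack the crowded
      ## core centre more tightly, minimising distance distortion
      if (nI > 0) {
        dI <- vapply(seq_len(nI), function(i) drawCore(), numeric(1))
        pi_ <- placeLabels(dI, geom$x[g], geom$y[g], R,
                           params@goldDiametersNm[["insulin"]] / 2, occupied)
        occupied <- pi_$occupied
        out$insulin <- data.frame(class = "insulin", x_nm = pi_$x,
                                  y_nm = pi_$y, d_nm = pi_$d)
      }
      if (nC > 0) {
        isShell <- runif(nC) < params@shellWeight
        dC <- ifelse(isShell, vapply(seq_len(nC), function(i) drawShell(),
                                     numeric(1)),
                     vapply(seq_len(nC), function(i) drawCore(), numeric(1)))
        pc <- placeLabels(dC, geom$x[g], geom$y[g], R,
                          params@goldDiametersNm[["chgb"]] / 2, occupied)
        occupied <- pc$occupied
        out$chgb <- data.frame(class = "chgb", x_nm = pc$x, y_nm = pc$y,
                               d_nm = pc$d)
      }
      list(labels = if (length(out)) do.call(rbind, out) else NULL,
           occupied = occupied)
    })
    occupied <- res$occupied
    if (!is.null(res$labels)) {
      res$labels$ring_id <- g
      res$labels$granule_r_nm <- R
      truth[[g]] <- res$labels
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else emptyTruth
  rownames(truth) <- NULL
  if (nrow(truth)) truth <- cbind(id = seq_len(nrow(truth)), truth)
  ## render
  img <- withSeed(deriveSeed(params@seed, params@nGranules + 1L), {
    m <- matrix(bg, sidePx, sidePx)
    if (params@noiseSd > 0)
      m <- m + matrix(rnorm(sidePx * sidePx, 0, params@noiseSd),
                      sidePx, sidePx)
    m
  })
  if (nrow(truth)) {
    rNm <- ifelse(truth$class == "chgb",
                  params@goldDiametersNm[["chgb"]] / 2,
                  params@goldDiametersNm[["insulin"]] / 2)
    img <- renderDisks(img, truth$x_nm, truth$y_nm, rNm, depth,
                       params@nmPerPx)
  }
  img <- pmax(pmin(img, 1), 0)
  mg <- Micrograph(img, nmPerPx = params@nmPerPx,
                   metadata = list(seed = params@seed, generator = "makeEMField"))
  list(image = mg,
       rings = if (params@nGranules > 0) GranuleRingSet(rings)
               else GranuleRingSet(list()),
       truth = truth, params = params)
}

#' Simulate a multi-field immunogold study
#'
#' Splits `nGranules` across `nFields` independent fields (emulating pooling
#' of several independent experiments, as radial distributions are pooled
#' across experiments in practice), each generated by [makeEMField()] with a
#' derived seed.
#'
#' @param params an [EMFieldParams-class] (its `nGranules` is the study
#'   total).
#' @param nFields number of fields to split the granules over (default 3).
#' @return list of per-field results as returned by [makeEMField()].
#' @export
makeEMStudy <- function(params, nFields = 3L) {
  stopifnot(is(params, "EMFieldParams"), nFields >= 1L)
  per <- diff(round(seq(0, params@nGranules, length.out = nFields + 1L)))
  lapply(seq_len(nFields), function(f) {
    pf <- params
    pf@nGranules <- as.integer(per[f])
    pf@seed <- deriveSeed(params@seed, 500000L + f)
    makeEMField(pf)
  })
}

#' Simulate a fluorescence puncta image with known centroids
#'
#' Isolated 2-D Gaussian spots (surface puncta of released granule membrane
#' proteins) on a noisy dark background; spot centres are rejected-sampled to
#' keep a minimum separation of 6 spot sigmas so every punctum is resolvable.
#'
#' @param nPuncta number of spots (>= 0).
#' @param spotSigmaNm Gaussian spot s.d. in nm (default 150, diffraction-
#'   limited confocal scale).
#' @param intensity peak spot intensity above background (default 0.6).
#' @param noiseSd background Gaussian noise s.d. (default 0.02).
#' @param nmPerPx calibration (default 50 nm/px).
#' @param seed integer seed.
#' @return list with `image` ([Micrograph-class]) and `truth` (data.frame
#'   x_nm, y_nm).
#' @export
makePunctaImage <- function(nPuncta, spotSigmaNm = 150, intensity = 0.6,
                            noiseSd = 0.02, nmPerPx = 50, seed = 1) {
  stopifnot(nPuncta >= 0, spotSigmaNm > 0, intensity > 0, noiseSd >= 0)
  sep <- 6 * spotSigmaNm
  sideNm <- max(512 * nmPerPx, ceiling(sqrt(nPuncta * sep^2 / 0.25)))
  sidePx <- ceiling(sideNm / nmPerPx)
  withSeed(deriveSeed(seed, 0L), {
    xs <- ys <- numeric(nPuncta)
    margin <- 4 * spotSigmaNm
    for (k in seq_len(nPuncta)) {
      ok <- FALSE
      for (try in 1:400) {
        px <- runif(1, margin, sideNm - margin)
        py <- runif(1, margin, sideNm - margin)
        if (k == 1L || all(sqrt((xs[seq_len(k - 1L)] - px)^2 +
                                (ys[seq_len(k - 1L)] - py)^2) > sep)) {
          xs[k] <- px; ys[k] <- py; ok <- TRUE; break
        }
      }
      if (!ok) stop("puncta placement failed: field too crowded")
    }
    img <- matrix(0.1, sidePx, sidePx)
    if (noiseSd > 0)
      img <- img + matrix(rnorm(sidePx^2, 0, noiseSd), sidePx, sidePx)
    sPx <- spotSigmaNm / nmPerPx
    for (k in seq_len(nPuncta)) {
      i0 <- max(1L, floor((xs[k] - 4 * spotSigmaNm) / nmPerPx))
      i1 <- min(sidePx, ceiling((xs[k] + 4 * spotSigmaNm) / nmPerPx))
      j0 <- max(1L, floor((ys[k] - 4 * spotSigmaNm) / nmPerPx))
      j1 <- min(sidePx, ceiling((ys[k] + 4 * spotSigmaNm) / nmPerPx))
      px <- (i0:i1 - 0.5) * nmPerPx
      py <- (j0:j1 - 0.5) * nmPerPx
      d2 <- outer((px - xs[k])^2, (py - ys[k])^2, `+`)
      img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] +
        intensity * exp(-d2 / (2 * spotSigmaNm^2))
    }
    img <- pmax(pmin(img, 1), 0)
    list(image = Micrograph(img, nmPerPx = nmPerPx,
                            metadata = list(seed = seed,
                                            generator = "makePunctaImage")),
         truth = data.frame(x_nm = xs, y_nm = ys))
  })
}
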