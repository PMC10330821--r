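#' @include AllClasses.R utils.R
NULL

#' Count fluorescent surface puncta by Laplacian-of-Gaussian blob detection
#'
#' Scale-space blob detection: the image is smoothed at a geometric ladder of
#' sigmas between `minSigmaNm` and `maxSigmaNm`, the scale-normalized
#' Laplacian response (-sigma^2 del^2 G) is computed at each scale, and blob
#' centres are local maxima over space and scale above `threshold`, with
#' non-maximum suppression of detections closer than the detected sigma.
#' Deterministic for fixed parameters.
#'
#' @param img a [Micrograph-class] with bright puncta on a dark background.
#' @param minSigmaNm,maxSigmaNm blob scale range in nm (defaults 100 and
#'   400).
#' @param threshold minimum normalized LoG response (default 0.05).
#' @param nScales number of scales in the ladder (default 5).
#' @return list with `count` and `centroids` (data.frame x_nm, y_nm,
#'   sigma_nm, response).
#' @export
countSurfacePuncta <- function(img, minSigmaNm = 100, maxSigmaNm = 400,
                               threshold = 0.05, nScales = 5) {
  stopifnot(is(img, "Micrograph"), minSigmaNm > 0, maxSigmaNm >= minSigmaNm)
  nmpp <- img@nmPerPx
  x <- img@intensity
  sig <- exp(seq(log(minSigmaNm), log(maxSigmaNm), length.out = nScales))
  lapKernel <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  resp <- array(0, c(nrow(x), ncol(x), nScales))
  for (s in seq_len(nScales)) {
    sPx <- sig[s] / nmpp
    sm <- EBImage::gblur(x, sigma = sPx)
    lap <- EBImage::imageData(EBImage::filter2(sm, lapKernel))
    resp[, , s] <- -sPx^2 * lap
  }
  ## local maxima over 3x3 space and adjacent scales
  peaks <- list()
  for (s in seq_len(nScales)) {
    r <- resp[, , s]
    cand <- which(r > threshold, arr.ind = TRUE)
    if (!nrow(cand)) next
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (i < 2 || j < 2 || i > nrow(r) - 1 || j > ncol(r) - 1) next
      nb <- r[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (r[i, j] < max(nb)) next
      lo <- if (s > 1) resp[i, j, s - 1] else -Inf
      hi <- if (s < nScales) resp[i, j, s + 1] else -Inf
      keep[k] <- r[i, j] >= lo && r[i, j] >= hi
    }
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand))
      peaks[[s]] <- data.frame(x_nm = (cand[, 1] - 0.5) * nmpp,
                               y_nm = (cand[, 2] - 0.5) * nmpp,
                               sigma_nm = sig[s],
                               response = resp[cbind(cand, s)])
  }
  cents <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(x_nm = numeric(), y_nm = numeric(), sigma_nm = numeric(),
               response = numeric())
  ## non-maximum suppression across scales: keep the strongest of any pair
  ## closer than the larger detected sigma
  if (nrow(cents) > 1L) {
    cents <- cents[order(-cents$response), ]
    keep <- rep(TRUE, nrow(cents))
    for (k in 2:nrow(cents)) {
      prev <- which(keep[seq_len(k - 1L)])
      dd <- sqrt((cents$x_nm[prev] - cents$x_nm[k])^2 +
                 (cents$y_nm[prev] - cents$y_nm[k])^2)
      lim <- pmax(cents$sigma_nm[prev], cents$sigma_nm[k]) * 2
      if (any(dd < lim)) keep[k] <- FALSE
    }
    cents <- cents[keep, ]
    rownames(cents) <- NULL
  }
  list(count = nrow(cents), centroids = cents)
}
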