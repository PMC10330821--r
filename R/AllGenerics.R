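#' @include AllClasses.R
NULL

#' Accessors for GranulePhys objects
#'
#' Small accessor family: `intensity()` and `nmPerPx()` read a
#' [Micrograph-class]; `ringAreas()` and `equivalentDiameters()` summarize a
#' [GranuleRingSet-class]; `kd()` and `hillN()` read a [HillFit-class];
#' `mixtureMeans()` reads a [RadialMixtureFit-class].
#'
#' @param object the object to access.
#' @return The corresponding slot or derived summary.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("nmPerPx", function(object) standardGeneric("nmPerPx"))
#' @rdname accessors
#' @export
setGeneric("ringAreas", function(object) standardGeneric("ringAreas"))
#' @rdname accessors
#' @export
setGeneric("equivalentDiameters",
           function(object) standardGeneric("equivalentDiameters"))
#' @rdname accessors
#' @export
setGeneric("kd", function(object) standardGeneric("kd"))
#' @rdname accessors
#' @export
setGeneric("hillN", function(object) standardGeneric("hillN"))
#' @rdname accessors
#' @export
setGeneric("mixtureMeans", function(object) standardGeneric("mixtureMeans"))

#' @rdname accessors
setMethod("intensity", "Micrograph", function(object) object@intensity)
#' @rdname accessors
setMethod("nmPerPx", "Micrograph", function(object) object@nmPerPx)

#' @rdname accessors
setMethod("ringAreas", "GranuleRingSet", function(object)
  vapply(object@rings, polygonArea, numeric(1)))

#' @rdname accessors
setMethod("equivalentDiameters", "GranuleRingSet", function(object)
  2 * sqrt(ringAreas(object) / pi))

#' @rdname accessors
setMethod("kd", "HillFit", function(object) object@kd)
#' @rdname accessors
setMethod("hillN", "HillFit", function(object) object@hillN)
#' @rdname accessors
setMethod("mixtureMeans", "RadialMixtureFit", function(object) object@means)

setMethod("show", "Micrograph", function(object) {
  d <- dim(object@intensity)
  cat("Micrograph:", d[1], "x", d[2], "px @", object@nmPerPx, "nm/px\n")
})

setMethod("show", "GranuleRingSet", function(object) {
  n <- length(object@rings)
  cat("GranuleRingSet with", n, "rings")
  if (n) cat("; mean equivalent diameter",
             round(mean(equivalentDiameters(object)), 1), "nm")
  cat("\n")
})

setMethod("show", "ConductanceFit", function(object) {
  cat(sprintf("ConductanceFit: slope %.1f +/- %.1f pS, Erev %.1f +/- %.1f mV (r2 %.3f, n=%d)\n",
              object@slopePS, object@slopeSePS, object@erevMV,
              object@erevSeMV, object@r2, object@n))
})

setMethod("show", "AmplitudeEstimate", function(object) {
  cat(sprintf("AmplitudeEstimate: <i> = %.2f +/- %.2f pA (%d events)\n",
              object@meanIpA, object@sdPA, object@nEvents))
})

setMethod("show", "InactivationFit", function(object) {
  cat(sprintf("InactivationFit: tau %.3f s, A %.2f pA, C %.2f pA, rmse %.3f%s\n",
              object@tauS, object@amplitudePA, object@offsetPA, object@rmse,
              if (object@flagged) " [non-decaying]" else ""))
})

setMethod("show", "HillFit", function(object) {
  cat(sprintf("HillFit: kD = %.4g, n = %.3g (rss %.4g)\n",
              object@kd, object@hillN, object@rss))
  if (object@nBoot > 0L)
    cat(sprintf("  bootstrap 95%% CI (n=%d): kD [%.4g, %.4g], n [%.3g, %.3g]\n",
                object@nBoot, object@ci["kd", 1], object@ci["kd", 2],
                object@ci["hillN", 1], object@ci["hillN", 2]))
})

setMethod("show", "RadialMixtureFit", function(object) {
  cat(sprintf("RadialMixtureFit: k = %d, logLik %.2f, BIC %.2f%s\n",
              object@k, object@logLik, object@bic,
              if (!object@converged) " [not converged]" else ""))
  for (j in seq_len(object@k))
    cat(sprintf("  comp %d: w %.3f, mean %.1f nm, sd %.1f nm\n",
                j, object@weights[j], object@means[j], object@sds[j]))
  if (object@k == 2L && is.finite(object@separationP))
    cat(sprintf("  separation p = %.3g\n", object@separationP))
})

setMethod("show", "RecordingCondition", function(object) {
  cat("RecordingCondition @", object@temperatureK, "K\n")
  print(object@species, row.names = FALSE)
})
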