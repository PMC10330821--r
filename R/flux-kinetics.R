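#' @include AllClasses.R utils.R
NULL

#' Hill dose-response function
#'
#' Fractional remaining activity under a Hill-type block,
#' I = 1 / (1 + ([L]/k_D)^n). Strictly decreasing in L; I(k_D) = 1/2 for any
#' n; I(0) = 1.
#'
#' @param L ligand concentration(s), >= 0 (units of `kd`).
#' @param kd dissociation constant (> 0).
#' @param n Hill coefficient (> 0).
#' @return Response value(s) in (0, 1].
#' @export
hillResponse <- function(L, kd, n) {
  stopifnot(kd > 0, n > 0, all(L >= 0))
  1 / (1 + (L / kd)^n)
}

hillRss <- function(logp, L, resp) {
  pred <- 1 / (1 + (L / exp(logp[1]))^exp(logp[2]))
  sum((resp - pred)^2)
}

#' Fit a Hill equation to a dose-response table
#'
#' Least-squares fit of I = 1/(1 + ([L]/k_D)^n) over (log k_D, log n), with
#' multiple starts from a log-spaced k_D grid crossed with n in {0.5, 1, 2},
#' bounded to k_D in [1e-6, 1e3] (input units) and n in [0.1, 10]. Responses
#' are clipped to [0, 1.05] before fitting (noise can push normalized values
#' slightly above 1). Optional case-resampling bootstrap confidence
#' intervals.
#'
#' @param table data.frame with columns `ligand` (>= 0) and `response`;
#'   an optional `replicate` column is carried but not used by the fit.
#' @param nBoot number of bootstrap resamples for 95% CIs (0 = none).
#' @param seed bootstrap seed.
#' @return A [HillFit-class].
#' @examples
#' tab <- data.frame(ligand = c(0.1, 0.5, 2), response = hillResponse(c(0.1, 0.5, 2), 0.47, 1))
#' fitHill(tab)
#' @export
fitHill <- function(table, nBoot = 0, seed = 1) {
  stopifnot(is.data.frame(table), all(c("ligand", "response") %in% names(table)))
  L <- table$ligand
  resp <- pmin(pmax(table$response, 0), 1.05)
  if (any(L < 0)) stop("ligand concentrations must be >= 0")
  if (length(unique(L)) < 3L)
    stop("need at least 3 distinct concentrations to fit")
  if (diff(range(resp)) < 1e-12)
    stop("all responses identical: Hill parameters unidentifiable")
  fitOnce <- function(L, resp) {
    pos <- L[L > 0]
    kdGrid <- exp(seq(log(min(pos)), log(max(pos)), length.out = 7))
    starts <- expand.grid(kd = kdGrid, n = c(0.5, 1, 2))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      o <- tryCatch(optim(log(c(starts$kd[i], starts$n[i])), hillRss,
        L = L, resp = resp, method = "L-BFGS-B",
        lower = log(c(1e-6, 0.1)), upper = log(c(1e3, 10)),
        control = list(factr = 10)), error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("Hill fit failed from every start")
    best
  }
  best <- fitOnce(L, resp)
  ci <- matrix(numeric(0), 0, 2)
  if (nBoot > 0) {
    bs <- withSeed(seed, {
      vapply(seq_len(nBoot), function(b) {
        idx <- sample.int(length(L), replace = TRUE)
        exp(fitOnce(L[idx], resp[idx])$par)
      }, numeric(2))
    })
    ci <- rbind(kd = quantile(bs[1, ], c(0.025, 0.975), names = FALSE),
                hillN = quantile(bs[2, ], c(0.025, 0.975), names = FALSE))
    colnames(ci) <- c("lo", "hi")
  }
  new("HillFit", kd = exp(best$par[1]), hillN = exp(best$par[2]),
      rss = best$value, ci = ci, nBoot = as.integer(nBoot),
      seed = as.integer(seed))
}

#' Plateau-amplitude of a flux trace relative to a control
#'
#' The light-scattering flux amplitude is (baseline - plateau) of the trace
#' minus the same quantity for the vehicle control. The baseline is the mean
#' of the pre-trigger window (t < 0); the plateau is the mean of the final
#' 10% of samples. A control amplitude exceeding the signal is clipped to 0
#' with a warning.
#'
#' @param trace,controlTrace data.frames with columns `t_s`, `intensity` on
#'   aligned time bases.
#' @return Non-negative amplitude (same units as intensity).
#' @export
fluxAmplitude <- function(trace, controlTrace) {
  ampOf <- function(tr) {
    stopifnot(all(c("t_s", "intensity") %in% names(tr)))
    pre <- tr$intensity[tr$t_s < 0]
    if (!length(pre)) stop("trace has no pre-trigger (t < 0) baseline window")
    nTail <- max(1L, ceiling(0.1 * nrow(tr)))
    plateau <- mean(tr$intensity[(nrow(tr) - nTail + 1L):nrow(tr)])
    mean(pre) - plateau
  }
  if (!identical(trace$t_s, controlTrace$t_s))
    stop("trace and control must share the same time base")
  amp <- ampOf(trace) - ampOf(controlTrace)
  if (amp < 0) {
    warning("control amplitude exceeds signal; clipping to 0")
    amp <- 0
  }
  amp
}

#' Dose-response table from a simulated or measured flux series
#'
#' Computes [fluxAmplitude()] for every (concentration, replicate) trace
#' against the series control, then normalizes to the zero-inhibitor
#' condition: the [L] = 0 condition when present, otherwise the
#' least-inhibited condition (the concentration with the largest mean
#' amplitude).
#'
#' @param series a flux series as returned by [makeFluxSeries()], or any list
#'   with elements `traces` (concentration, replicate, t_s, intensity) and
#'   `control` (t_s, intensity).
#' @return data.frame with columns ligand, response, replicate.
#' @export
fluxDoseResponse <- function(series) {
  tr <- series$traces
  stopifnot(all(c("concentration", "replicate", "t_s", "intensity") %in%
                  names(tr)))
  keys <- unique(tr[, c("concentration", "replicate")])
  amp <- mapply(function(cc, rr) {
    sub <- tr[tr$concentration == cc & tr$replicate == rr, ]
    fluxAmplitude(sub[, c("t_s", "intensity")], series$control)
  }, keys$concentration, keys$replicate)
  tab <- data.frame(ligand = keys$concentration, response = amp,
                    replicate = keys$replicate)
  means <- tapply(tab$response, tab$ligand, mean)
  ## zero-inhibitor reference: the [L] = 0 condition when present, else the
  ## lowest concentration (the least-inhibited condition by monotonicity)
  ref <- if (any(tab$ligand == 0)) means[["0"]]
         else means[[as.character(min(tab$ligand))]]
  if (ref <= 0) stop("zero-inhibitor amplitude is non-positive")
  tab$response <- pmin(pmax(tab$response / ref, 0), 1.05)
  tab
}
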