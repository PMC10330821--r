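## Shared fixtures. The default immuno-EM study (324 granules, seed 1) is
## expensive (~2 min), so it is generated lazily once and reused by every
## test that needs it.

.fixtures <- new.env(parent = emptyenv())

defaultStudy <- function() {
  if (is.null(.fixtures$study))
    .fixtures$study <- makeEMStudy(EMFieldParams(seed = 1), nFields = 3)
  .fixtures$study
}

defaultReport <- function() {
  if (is.null(.fixtures$report)) {
    study <- defaultStudy()
    .fixtures$report <- runEMPipeline(lapply(study, `[[`, "image"),
                                      lapply(study, `[[`, "rings"))
  }
  .fixtures$report
}

defaultTruth <- function() do.call(rbind, lapply(defaultStudy(), `[[`, "truth"))

## render dark anti-aliased disks on a uniform background
diskMicrograph <- function(xs, ys, diameters, side = 140, noiseSd = 0,
                           seed = 1, nmPerPx = 1) {
  set.seed(seed)
  img <- matrix(0.75, side, side)
  if (noiseSd > 0)
    img <- img + matrix(rnorm(side^2, 0, noiseSd), side, side)
  img <- GranulePhys:::renderDisks(img, xs, ys, diameters / 2, 0.45, nmPerPx)
  Micrograph(pmax(pmin(img, 1), 0), nmPerPx)
}

## match each truth point to its nearest detection; returns match distances
matchTruth <- function(truth, detected) {
  dm <- outer(truth$x_nm, detected$x_nm, "-")^2 +
    outer(truth$y_nm, detected$y_nm, "-")^2
  near <- apply(dm, 1, which.min)
  list(near = near,
       dist = sqrt(dm[cbind(seq_len(nrow(truth)), near)]))
}

## standard 150/30 mM KCl bilayer condition
kclCondition <- function(pCl = 1, pK = 1, temperatureK = 297.1) {
  recordingCondition(ionSpecies("K", +1, 150, 30, pK),
                     ionSpecies("Cl", -1, 150, 30, pCl),
                     temperatureK = temperatureK)
}
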