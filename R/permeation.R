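#' @include AllClasses.R utils.R
NULL

## RT/F in millivolts at temperature T (K)
rtOverF_mV <- function(temperatureK) 1000 * .GAS_R * temperatureK / .FARADAY

#' Nernst equilibrium potential
#'
#' Equilibrium potential of a single ion species across a membrane,
#' E = (RT/zF) ln(C_cis / C_trans), with the trans compartment as the
#' reference side. With this convention a 150/30 mM (cis/trans) KCl gradient
#' gives -41.2 mV for Cl- and +41.2 mV for K+ at 297.1 K.
#'
#' @param z signed valence (nonzero integer).
#' @param concCis,concTrans concentrations on the two sides (> 0; any common
#'   unit).
#' @param temperatureK absolute temperature (K), default 297.1.
#' @return Potential in mV.
#' @examples
#' nernstPotential(-1, 150, 30) # -41.2 mV
#' @export
nernstPotential <- function(z, concCis, concTrans, temperatureK = 297.1) {
  if (z == 0) stop("valence z must be nonzero")
  if (concCis <= 0 || concTrans <= 0)
    stop("concentrations must be strictly positive")
  if (temperatureK <= 0) stop("temperature must be > 0")
  (rtOverF_mV(temperatureK) / z) * log(concCis / concTrans)
}

#' Goldman-Hodgkin-Katz reversal potential
#'
#' Zero-current potential for a set of monovalent permeant species,
#' Erev = (RT/F) ln[(sum_cat P C_cis + sum_an P C_trans) /
#' (sum_cat P C_trans + sum_an P C_cis)]. Reduces exactly to the Nernst
#' potential when only one species is permeant.
#'
#' @param cond a [RecordingCondition-class].
#' @return Reversal potential in mV.
#' @export
ghkReversal <- function(cond) {
  stopifnot(is(cond, "RecordingCondition"))
  sp <- cond@species
  if (any(abs(sp$z) != 1))
    stop("GHK voltage equation supports monovalent species only")
  if (all(sp$relPermeability == 0))
    stop("at least one species must have nonzero permeability")
  cat <- sp$z > 0
  num <- sum(sp$relPermeability[cat] * sp$concCis[cat]) +
    sum(sp$relPermeability[!cat] * sp$concTrans[!cat])
  den <- sum(sp$relPermeability[cat] * sp$concTrans[cat]) +
    sum(sp$relPermeability[!cat] * sp$concCis[!cat])
  if (num <= 0 || den <= 0)
    stop("permeant concentrations give a degenerate GHK quotient")
  rtOverF_mV(cond@temperatureK) * log(num / den)
}

#' Solve a permeability ratio from a measured reversal potential
#'
#' Finds the ratio r = P(target)/P(reference) such that the GHK reversal
#' potential of the condition, with the target's relative permeability set to
#' r times the reference's, reproduces `erevMV`. The GHK potential is strictly
#' monotone in r between the two single-ion Nernst limits, so monotone
#' bisection converges; the result reproduces `erevMV` to 1e-9 mV.
#'
#' @param erevMV measured reversal potential (mV); must lie strictly between
#'   the two single-ion Nernst limits of the template.
#' @param cond a [RecordingCondition-class] template containing both ions.
#' @param targetIon,referenceIon species names in `cond`.
#' @return The permeability ratio (dimensionless).
#' @examples
#' kcl <- recordingCondition(ionSpecies("K", +1, 150, 30),
#'                           ionSpecies("Cl", -1, 150, 30))
#' solvePermeabilityRatio(-40.5, kcl, "Cl", "K")
#' @export
solvePermeabilityRatio <- function(erevMV, cond, targetIon, referenceIon) {
  stopifnot(is(cond, "RecordingCondition"))
  sp <- cond@species
  it <- match(targetIon, sp$name); ir <- match(referenceIon, sp$name)
  if (is.na(it) || is.na(ir)) stop("target/reference ion not in condition")
  evalAt <- function(r) {
    sp2 <- sp
    sp2$relPermeability[it] <- r * sp2$relPermeability[ir]
    ghkReversal(new("RecordingCondition", species = sp2,
                    temperatureK = cond@temperatureK))
  }
  ## single-ion Nernst limits: r -> Inf (target dominates), r -> 0
  eTarget <- nernstPotential(sp$z[it], sp$concCis[it], sp$concTrans[it],
                             cond@temperatureK)
  eRef <- evalAt(0)
  lo <- min(eTarget, eRef); hi <- max(eTarget, eRef)
  if (!(erevMV > lo && erevMV < hi))
    stop(sprintf(
      "erev %.3f mV is not strictly between the Nernst limits [%.3f, %.3f] mV",
      erevMV, lo, hi))
  if (abs(eTarget - eRef) < 1e-12)
    stop("degenerate template: the two single-ion limits coincide")
  rLo <- 0; eLo <- eRef
  rHi <- 1; eHi <- evalAt(1)
  while ((eHi - erevMV) * (eLo - erevMV) > 0) {
    rLo <- rHi; eLo <- eHi
    rHi <- rHi * 2
    eHi <- evalAt(rHi)
    if (rHi > 1e12) stop("erev too close to the target-ion Nernst limit")
  }
  mid <- (rLo + rHi) / 2
  for (i in 1:200) {
    mid <- (rLo + rHi) / 2
    eMid <- evalAt(mid)
    if (abs(eMid - erevMV) < 1e-10) break
    if ((eMid - erevMV) * (eLo - erevMV) <= 0) {
      rHi <- mid
    } else {
      rLo <- mid; eLo <- eMid
    }
  }
  mid
}

#' Per-ion GHK currents and absolute-current shares
#'
#' GHK constant-field current for each species, in the trans-referenced
#' convention (cis = outer bath, trans = inner/pipette side, V the inner
#' potential relative to the bath):
#' I_S = P_S z^2 (F V / RT) (C_trans - C_cis e^(-z FV/RT)) /
#' (1 - e^(-z FV/RT)) (arbitrary common scale; positive = outward), with the
#' analytic limit P_S z^2 (C_trans - C_cis) at V = 0. Shares are
#' |I_S| / sum |I|.
#'
#' @param cond a [RecordingCondition-class] (monovalent species).
#' @param vMV membrane potential (mV).
#' @return data.frame with columns name, current (arbitrary units), share.
#' @export
ghkCurrentShares <- function(cond, vMV) {
  stopifnot(is(cond, "RecordingCondition"), is.finite(vMV))
  sp <- cond@species
  if (any(abs(sp$z) != 1))
    stop("GHK current equation supports monovalent species only")
  if (all(sp$relPermeability == 0) ||
      all(sp$relPermeability * (sp$concCis + sp$concTrans) == 0))
    stop("no permeant species")
  rt <- rtOverF_mV(cond@temperatureK)
  u0 <- vMV / rt
  zu <- sp$z * u0
  flux <- ifelse(abs(zu) < 1e-10,
    (sp$concTrans - sp$concCis) / sp$z,
    u0 * (sp$concTrans - sp$concCis * exp(-zu)) / (1 - exp(-zu)))
  current <- sp$relPermeability * sp$z^2 * flux
  tot <- sum(abs(current))
  share <- if (tot > 0) abs(current) / tot else rep(0, length(current))
  data.frame(name = sp$name, current = current, share = share)
}

#' Number of ions in a volume
#'
#' N = N_A * C * V with Avogadro's number 6.02214076e23.
#'
#' @param concentrationM concentration in mol/L (>= 0).
#' @param volumeL volume in litres (>= 0).
#' @return Expected ion count.
#' @examples
#' ionsInVolume(10e-6, 40e-15) # ~2.4e5 calcium ions in 40 fL at 10 uM
#' @export
ionsInVolume <- function(concentrationM, volumeL) {
  stopifnot(concentrationM >= 0, volumeL >= 0)
  .AVOGADRO * concentrationM * volumeL
}

#' Membrane-disk charging potential
#'
#' Potential reached when `nIons` ions of valence `valence` charge a circular
#' membrane patch of diameter `diskDiameterUm` with specific capacitance
#' `specificCapacitance` (uF/cm^2): V = n |z| e / (C_spec * pi (d/2)^2).
#'
#' @param nIons ion count (>= 0).
#' @param valence signed valence.
#' @param diskDiameterUm disk diameter in micrometres (> 0).
#' @param specificCapacitance membrane specific capacitance in uF/cm^2
#'   (default 1.0).
#' @return Potential in volts.
#' @examples
#' diskChargingPotential(ionsInVolume(10e-6, 40e-15), 2, 4) # ~0.6 V
#' @export
diskChargingPotential <- function(nIons, valence, diskDiameterUm,
                                  specificCapacitance = 1.0) {
  stopifnot(nIons >= 0, diskDiameterUm > 0, specificCapacitance > 0)
  q <- nIons * abs(valence) * .ECHARGE               # coulombs
  areaCm2 <- pi * (diskDiameterUm * 1e-4 / 2)^2      # cm^2
  capF <- specificCapacitance * 1e-6 * areaCm2       # farads
  q / capF
}
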