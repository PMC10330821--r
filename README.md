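# GranulePhys

Quantitative biophysics of dense-core secretory granule (DCSG) anion
channels and the dimorphic granin protein chromogranin B (CHGB), for
cell biologists and channel physiologists who need the measurement chain —
not just the headline numbers — to be reproducible and testable.

DCSG exocytosis delivers anion channels to the cell surface, and CHGB
exists in both a soluble, granule-core form and a membrane-inserted form
that reconstitutes a highly Cl⁻-selective channel. Quantifying that
biology involves four very different analyses, all implemented here:

* **Immunogold EM quantification** — detect 6-nm (insulin) and 12-nm
  (CHGB) gold labels in calibrated micrographs (difference-of-Gaussians
  enhancement → Otsu threshold → hole filling → intensity-seeded
  watershed), classify by area (noise < 20 nm² ≤ insulin < 65 nm² ≤ CHGB)
  and eccentricity (≤ 0.75), assign to annotated granule rings dilated by
  20 nm, and measure the signed distance to the membrane (positive inside).
  Radial distributions are binned at 20 nm and decomposed with a Gaussian
  mixture EM (BIC model choice, Welch-t peak separation). The antibody
  sandwich geometry (two 14.5-nm antibodies, 1-nm linker, 4-nm epitope
  extension, half a gold diameter, 4-nm bilayer) bounds how far a label
  can sit from its epitope: 40 nm luminal, 26 nm external.
* **Selectivity inference** — Nernst potentials, the monovalent
  Goldman–Hodgkin–Katz (GHK) reversal equation
  `Erev = (RT/F)·ln[(Σcat P·C_cis + Σan P·C_trans)/(Σcat P·C_trans + Σan P·C_cis)]`,
  a bisection solver for permeability ratios such as P_Cl/P_K, per-ion GHK
  current shares, and the exocytosis charge-balance estimates
  (N = N_A·C·V ions; disk charging V = n|z|e / (C_spec·π(d/2)²)).
* **Channel records** — OLS current–voltage fits (slope in pS,
  Erev = −b₀/b₁), chord conductance I/(V−Erev), channel counting,
  half-amplitude threshold idealization, dwell-weighted unitary currents,
  single-exponential inactivation fits, whole-cell current-change rates,
  and Welch t comparisons with Bonferroni adjustment.
* **Flux kinetics** — plateau-amplitude normalization of valinomycin-
  triggered light-scattering traces and Hill fits
  `I = 1/(1 + ([L]/k_D)^n)` with multi-start log-parameter least squares
  and bootstrap CIs.

Every stage has a seeded synthetic-data generator (`makeEMField`,
`makeChannelTrace`, `makeMacroscopicSweeps`, `makeFluxSeries`,
`makeWholeCellSession`, `makePunctaImage`) that emulates the raw-data
modality and records ground truth, so recovery and bias are tested rather
than assumed. See the vignette (`vignettes/granule-quantification.Rmd`)
for the models, defaults and numerical choices.

## Worked example

Infer anion selectivity from a bilayer recording in 150/30 mM KCl:

```r
library(GranulePhys)

nernstPotential(-1, 150, 30)          # Cl- equilibrium potential
#> [1] -41.20499

kcl <- recordingCondition(ionSpecies("K",  +1, 150, 30, 1),
                          ionSpecies("Cl", -1, 150, 30, 1))
solvePermeabilityRatio(-40.5, kcl, "Cl", "K")
#> [1] 171.7267

fitLinearIV(data.frame(v_mV = c(-40.5, 0), i_pA = c(0, 24.3)))
#> ConductanceFit: slope 600.0 +/- 0.0 pS, Erev -40.5 +/- 0.0 mV (r2 1.000, n=2)
estimateChannelCount(600, 110)
#> [1] 5
```

A measured reversal of −40.5 mV, ~1 mV from the Cl⁻ Nernst limit, implies
P_Cl/P_K in the hundreds (the exact value is ill-conditioned this close to
the limit — treat it as "well above 100"). The 600-pS macroscopic chord
conductance at a 110-pS unitary conductance suggests ~5 channels.

Run the full synthetic immunogold study and its analysis:

```r
study  <- makeEMStudy(EMFieldParams(seed = 1), nFields = 3)
report <- runEMPipeline(lapply(study, `[[`, "image"),
                        lapply(study, `[[`, "rings"))
round(report$summary[c("meanEquivalentDiameterNm", "fracChgbWithinZone",
                       "proximalPeakNm", "insulinPeakNm")], 3)
#> meanEquivalentDiameterNm       fracChgbWithinZone           proximalPeakNm
#>                  194.003                    0.400                   23.957
#>            insulinPeakNm
#>                  111.073
```

324 granules (mean equivalent diameter ~194 nm) yield a bimodal CHGB
distance distribution — a membrane-proximal component near 24 nm holding
~40% of CHGB labels within −20…40 nm of the membrane — while insulin stays
deep in the core (mono-modal, ~111 nm), the dimorphism signature this
pipeline exists to quantify.

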