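---
title: "Quantitative models behind GranulePhys"
author: "GranulePhys authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative models behind GranulePhys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GranulePhys)
```

GranulePhys bundles the quantitative analyses used to characterize anion
channels of dense-core secretory granules (DCSGs) and the dimorphic
(soluble plus membrane-bound) chromogranin B (CHGB) protein: immunogold
electron-microscopy quantification of where labels sit relative to the
granule membrane, equilibrium and Goldman–Hodgkin–Katz (GHK) selectivity
math, single-channel and macroscopic current analysis, and Hill-equation
fitting of flux-assay inhibition. Because raw wet-lab data of this kind are
rarely redistributable, every analysis stage is paired with a seeded
synthetic-data generator that emulates the corresponding raw-data modality
and records ground truth, so the whole pipeline is testable end to end.

This vignette explains the models, the defaults and why they were chosen,
the numerical choices, and what the synthetic data do and do not emulate.

## Electrodiffusion: Nernst, GHK and permeability ratios

For a single permeant ion of valence $z$,
$E = \frac{RT}{zF}\ln\frac{C_\mathrm{cis}}{C_\mathrm{trans}}$, with the
trans compartment taken as the reference ("inner") side. This is the unique
sign convention under which a 150/30 mM (cis/trans) KCl gradient gives
$-41.2$ mV for Cl$^-$ and $+41.2$ mV for K$^+$, the values used to verify
bilayer solutions.

**Temperature.** Recordings at "room temperature" are nominally 20 °C, but
$\pm 41.2$ mV for a five-fold gradient implies $RT/F \approx 25.6$ mV, i.e.
about 24 °C. The default is therefore $T = 297.1$ K, and every function
takes $T$ explicitly so either convention can be used.

For several monovalent species the GHK voltage equation gives

$$E_\mathrm{rev} = \frac{RT}{F}\,
\ln\frac{\sum_\mathrm{cat} P\,C_\mathrm{cis} + \sum_\mathrm{an} P\,C_\mathrm{trans}}
        {\sum_\mathrm{cat} P\,C_\mathrm{trans} + \sum_\mathrm{an} P\,C_\mathrm{cis}}.$$

`solvePermeabilityRatio()` inverts this relation for one unknown ratio by
monotone bisection (the quotient is strictly monotone in the ratio between
the two single-ion Nernst limits), converging to $10^{-10}$ mV and refusing
reversal potentials at or beyond the limits. Divalent species are rejected
by the voltage solver rather than approximated; the charge-balance
estimates (`ionsInVolume()`, `diskChargingPotential()`) handle valence
explicitly.

A caution the package inherits from the data: a measured reversal potential
~1 mV away from the Cl$^-$ Nernst limit makes the solved
$P_\mathrm{Cl}/P_\mathrm{K}$ numerically fragile (it moves by factors over
a few degrees of temperature). The package therefore treats "$\sim$130" as
a lower-bound statement (well above 100 at 297.1 K), and tests it as such.

## Single-channel and whole-cell records

Unitary currents are estimated by half-amplitude threshold idealization:
samples are split at baseline $+$ amplitude/2, dwells shorter than a
2-sample minimum are merged (shortest first), and the unitary current is
the dwell-weighted open-minus-closed mean. The baseline defaults to the
mode of the all-points histogram. Subconductance levels are deliberately
out of scope: the idealizer is two-level.

Current–voltage series are fit by ordinary least squares with
$E_\mathrm{rev} = -b_0/b_1$; chord conductance $I/(V - E_\mathrm{rev})$ is
exposed separately from the fitted slope because channel counting uses the
chord value (600 pS of macroscopic chord conductance at a 110-pS unitary
conductance suggests ~5 channels; counts are rounded half away from zero).
Inactivation sweeps are fit as $I(t) = A e^{-t/\tau} + C$ with $A, C$
profiled in closed form for each $\tau$ and $\tau$ optimized on a log
scale, which is exact on noiseless input; non-decaying sweeps are flagged
rather than rejected. Group comparison uses a two-sided Welch $t$
(robust to unequal variances; the equal-variance choice is not documented
in this field's reports) with Bonferroni adjustment as a conservative,
pluggable default.

## Flux assays and Hill inhibition

Light-scattering flux traces are summarized by plateau amplitude: baseline
(pre-trigger mean) minus plateau (mean of the final 10% of samples),
corrected by the vehicle control and normalized to the zero-inhibitor
condition — amplitude rather than initial rate, matching the percent-block
presentation of such assays. Dose–response tables are fit to
$I = 1/(1 + ([L]/k_D)^n)$ by least squares over $(\log k_D, \log n)$ with a
multi-start grid (log-spaced $k_D$ across the data range crossed with
$n \in \{0.5, 1, 2\}$), bounds $k_D \in [10^{-6}, 10^3]$ input units and
$n \in [0.1, 10]$ for positivity and conditioning, and optional
case-resampling bootstrap CIs. Responses are clipped to $[0, 1.05]$ rather
than discarded, since noise legitimately pushes normalized values slightly
above 1.

When a series lacks an explicit $[L] = 0$ condition the normalization
reference is the lowest concentration. At the default chloride grid
(0.01–10 mM) this inflates responses by about 2% ($1/0.979$), a bias small
against the 10% recovery tolerance but worth knowing about.

## The immunogold pipeline

Micrographs are calibrated intensity fields (nm/px); rings are closed
polygons annotating granule boundaries; all coordinates live in a
continuous nm frame with pixel centres at $(i - 0.5)\times$ nm/px.

Detection proceeds as: contrast inversion; difference-of-Gaussians
band-pass rescaled to $[0,1]$ (a deterministic replacement for a trainable
pixel classifier — synthetic contrast is controlled and no training data
exist); Otsu threshold (256 bins); hole filling; watershed; component
labelling with border components removed. Two numerical choices matter and
were set by simulation against generator truth:

* **High-pass scale 32 nm, not the 12-nm disk size.** Gold labels cluster
  in granule cores. A 12-nm high-pass subtracts a dense cluster's own local
  mean, eroding member disks below the 20-nm$^2$ noise cutoff (detection
  recall dropped to ~92%). At 32 nm clusters pass intact.
* **Watershed on the enhanced intensity, not the distance map.** Touching
  disks merge into blobs whose distance transform has too few maxima; each
  disk retains its own intensity peak, so intensity-seeded watershed
  (tolerance 0.1) splits clusters correctly. With both choices, detection
  recall and classification accuracy are ~100% on noiseless and
  default-noise fields.

Classification applies the standard area classes — below 20 nm$^2$ noise,
20–65 nm$^2$ insulin (6-nm gold), at or above 65 nm$^2$ CHGB (12-nm gold);
65 nm$^2$ exactly is CHGB, 20 nm$^2$ exactly insulin — then removes
eccentricity $> 0.75$, with eccentricity
$\sqrt{1 - (\mathrm{minor}/\mathrm{major})^2}$ from the second-moment
ellipse. Particles are assigned to the ring (dilated outward by 20 nm)
containing their centroid; a particle inside two dilated rings goes to the
nearer boundary (the annotation practice this operationalizes was a manual
"clearly outside" judgment, so the tie-break is ours). Signed membrane
distance is the minimum distance to the boundary polyline, positive inside
— the only sign convention under which "the $-20$ to 0 nm bin" means
outside the granule edge. "Within 40 nm of the membrane, inside or
outside" is $-20 \le d \le 40$, bounded below by the 20-nm analysis
extension.

Distance histograms use left-closed 20-nm bins from $-20$ nm with an
explicit, flagged underflow bin so counts are conserved. Radial
distributions are decomposed with a hand-rolled one-dimensional Gaussian
mixture EM (quantile-split start plus seeded random restarts, $10^{-8}$
log-likelihood tolerance, 500-iteration cap, BIC $= -2\ell + (3k-1)\ln n$
for model choice) because the per-iteration likelihood trace and the
peak-separation test (Welch $t$ between posterior-assigned subgroups) are
part of the reported statistics; component standard deviations are floored
at 5% of the pooled s.d. — distances are measured at ~1-px resolution, so
narrower components are degenerate likelihood spikes, not structure.
Whether the original histogram peaks were fitted or read off is not
documented; mixture EM is the defensible estimator and is cross-checked
against an independent implementation in the tests.

Confocal puncta are counted by scale-normalized Laplacian-of-Gaussian blob
detection over a geometric scale ladder with non-maximum suppression —
deterministic, so repeated runs give identical centroids.

## The synthetic study and its calibration

`makeEMField()` emulates a high-pressure-frozen immuno-EM field: granule
radii follow a truncated normal (mean 90 nm, s.d. 40 nm, bounds 40–220 nm,
giving a 196-nm mean diameter); label counts per granule are Poisson with
mean proportional to $(R/98)^2$, which is what reconciles a 196-nm mean
diameter with core distance peaks above 98 nm; CHGB labels mix a
membrane-proximal shell (truncated normal, mean 25 nm, s.d. 16 nm, lower
bound $-20$ nm, weight 0.48) with a core population placed at a
half-normal offset $s$ from the centre ($d = R - s$, so truncation at the
centre is automatic); insulin is core-only with 6-nm gold. The default
study is 324 granules split over 3 fields (mirroring pooling over three
independent experiments), rendered at 1 nm/px with anti-aliased dark disks
on 2%-noise background and written as 16-bit TIFF.

Two generator parameters are pure calibration — the per-granule label
densities and the core offset scale; the source protocols say only that
label density was "kept low". They were set by simulating the full
pipeline and requiring it to reproduce the reference summary statistics
(~40% of CHGB within the membrane zone, proximal peak ~25 nm, insulin peak
~117 nm, 196-nm mean diameter): insulin 4 labels per 98-nm granule, CHGB
3, core offset s.d. 6 nm. A physical constraint drives the core offset
value: rendered 6-nm disks cannot sit closer than ~7.5 nm and remain
individually resolvable, so labels drawn onto the same central spot must
be displaced. The generator handles collisions by **minimal outward lift**
(0.5-nm radial steps, 48 candidate angles, keeping every drawn distance
that has free space at its radius and recording the realized distance in
the truth table), which distorts the distance marginals far less than
re-drawing from the model; the residual distortion is bounded in the tests
(realized insulin mean within 3.5 nm of the placement model).

Determinism: one master seed; per-granule and per-trace substreams are
derived by index, so identical parameters and seed give bit-identical
images, tables and traces. The caller's RNG state is saved and restored.

What the synthetic fields do *not* emulate: stain granularity and ice
texture, 70-nm section geometry (labels are drawn in the 2-D plane), and
multi-state subconductance gating. Passing tests therefore demonstrate
that the measurement chain is unbiased on data that satisfy the generative
assumptions — not that those assumptions hold for any particular real
micrograph.

The electrophysiology generators follow the same pattern:
`makeChannelTrace()` simulates independent two-state channels
(exponential dwells, optional irreversible inactivation at rate $1/\tau$,
so the ensemble mean decays as $e^{-t/\tau}$), with current
$N_\mathrm{open}\, g (V - E_\mathrm{rev})/1000$ pA plus Gaussian noise;
`makeWholeCellSession()` grows conductance as a compound-Poisson staircase
(fusion events per depolarizing pulse only in the presence of calcium,
~0.2 nS per event, reaching tens of nS over a 300-s session) and zeroes
the anionic driving-force term when extracellular chloride is removed;
`makeFluxSeries()` produces scattering decays
$1 - A\,(1 - e^{-t/\tau_\mathrm{flux}})$ with a 20-s pre-trigger baseline,
a run to $12\,\tau$ so plateaus are complete, replicate-level Hill-response
jitter plus per-sample instrument noise (one `noiseSd` knob, default
0.02), and a zero-amplitude vehicle control.

## Problem sizes and runtime

The default acceptance-scale run uses the full 324-granule study
(~3,600-px fields, about two minutes of compute), 8-concentration
3-replicate flux series, 1,000-condition electrodiffusion property sweeps,
and 100-seed recovery loops for amplitudes and $k_D$; these sizes give
standard errors comfortably inside the tolerances being tested while
keeping a complete run on one CPU in minutes.

## Known limitations

* The GHK machinery is monovalent-only by design; divalent block/permeation
  and anomalous mole-fraction effects are out of scope.
* The permeability-ratio solver inherits the ill-conditioning of reversal
  potentials near a Nernst limit; treat extreme ratios as bounds.
* The idealizer assumes two conductance levels; records with
  subconductance states will bias the unitary estimate toward the dominant
  level.
* Flux normalization without a true zero-inhibitor condition carries a
  small (~2%) scale bias.
* Synthetic micrographs place labels in 2-D; real section geometry
  compresses distances slightly.
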