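Package: GranulePhys
Title: Quantitative Biophysics of Dense-Core Secretory Granule Anion Channels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis toolkit for dense-core secretory granule
    (DCSG) biology: an immunogold electron-microscopy pipeline that detects
    gold labels, classifies them by size, and measures signed distances to
    annotated granule membranes with Gaussian-mixture decomposition of the
    radial distributions; Nernst and Goldman-Hodgkin-Katz selectivity
    inference with a permeability-ratio solver; single-channel and macroscopic
    current analysis (I-V fits, half-amplitude idealization, unitary currents,
    inactivation kinetics); Hill-equation fitting of chloride and DIDS block
    from light-scattering flux assays; and seeded synthetic-data generators
    that emulate each raw-data modality with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, EBImage, jsonlite, tiff
Suggests: testthat (>= 3.0.0), mclust, minpack.lm, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Software, CellBiology, Electrophysiology, Visualization
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'channel-records.R'
    'flux-kinetics.R'
    'immunogold.R'
    'io.R'
    'mixture.R'
    'permeation.R'
    'pipeline.R'
    'puncta.R'
    'synth-em.R'
    'synth-flux.R'
    'synth-traces.R'
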