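Package: tubeaniso
Title: Quantification of Anisotropic Junctional Protein Accumulation in
    Epithelial Tubes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the anisotropic accumulation of junctional
    proteins (such as Crumbs) in tubular epithelia imaged by confocal
    microscopy. Implements orientation-based classification of cell
    junctions into longitudinal and transverse classes, fixed-width band
    measurement of junctional fluorescence per unit length and per-embryo
    anisotropy ratio statistics; unrolling of curved 3D tubes onto a 2D
    plane (isotropic resampling, two-pass medial-axis straightening, ring
    radial projection) with apical cell area and orientation morphometry;
    FRAP recovery-curve normalization and single-exponential fitting
    (mobile fraction, half-time), average fits, kymographs and
    translation drift correction; and tube-level morphometrics. A
    ground-truthed synthetic generator of tubular-epithelium image stacks
    and FRAP traces makes every analysis stage verifiable without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization
RoxygenNote: 7.3.3
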