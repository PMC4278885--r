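Package: mfassay
Title: Molecular Force Assay Simulation and Ratiometric Fluorescence Quantification
Version: 0.1.0
Authors@R:
    person("MFA", "Maintainers", email = "mfassay@example.org", role = c("aut", "cre"))
Description: Tools for the DNA-based Molecular Force Assay (MFA) used to compare
    the mechanical strength of a protein-protein bond against a DNA reference
    duplex loaded in series. Provides Bell-model rupture kinetics under a linear
    force ramp (analytic first-rupture probabilities plus a kinetic Monte Carlo
    oracle), a catalog of DNA reference duplexes (shear/zipper geometry, propynyl
    base substitution, hairpin polyamide ligands) mapped to characteristic
    rupture forces, a seeded generator of synthetic four-channel fluorescence
    spot images with ground truth, the pixel-by-pixel Normalized Fluorescence
    quantification with Gaussian histogram fitting, replicate aggregation and
    condition comparison, and a reproducible simulate/quantify/compare pipeline
    with a packaged demonstration configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
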