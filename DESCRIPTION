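Package: desmoquant
Title: Quantification of Desmosome Hyperadhesion from Imaging and Force Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Image- and force-spectroscopy-based quantification of desmosomal
    adhesion in epithelial monolayers. Implements line-scan measurement of
    junctional versus cytoplasmic fluorescence, an irregularity score for
    membrane staining, skeleton-based keratin network density (filament
    bundles and bundle junctions per area), analysis of atomic force
    microscopy force-distance curves and adhesion maps (contact point,
    unbinding events, unbinding force, step position, binding frequency and
    junctional distribution coefficient), and fragment counting for dispase
    dissociation assays. Every estimator ships with a matched synthetic-data
    generator with machine-readable ground truth, plus the statistical
    comparisons (Student's t, exact Mann-Whitney, one-way ANOVA with
    Bonferroni correction) used to compare conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
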