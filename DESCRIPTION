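Package: twinephys
Title: Quantitative Phenotyping of iPSC-Derived Dentate Gyrus Neurons
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for the cellular-phenotyping endpoints used
    to compare iPSC-derived dentate gyrus granule-like neurons across clinical
    groups: intrinsic excitability and spike-shape features from current-clamp
    step protocols, sodium/potassium current-voltage curves from voltage-clamp
    sweeps, spontaneous EPSC event detection, Poisson-surprise burst and
    network-burst analysis of multi-electrode array recordings, Sholl and
    branch morphometry on SWC reconstructions, the accompanying statistical
    layer (KS normality, t tests, one-way ANOVA with Tukey-Kramer multiple
    comparisons, two-way ANOVA), and DEG-by-GWAS-catalog gene-set
    intersection. A seeded synthetic-data module generates every input the
    pipeline consumes -- conductance-based model neurons, Poisson EPSC trains,
    bursty spike trains, branched morphologies and DEG tables -- so the whole
    analysis is testable end to end without access to patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
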