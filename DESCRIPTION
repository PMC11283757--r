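Package: capitax
Title: Quantitative Analysis of Microcapillary Chemotaxis Assays
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify chemotactic responses of swimming microorganisms
    in two-capillary point-source assays. Provides assay-frame geometry and
    region constructors, video tracking (background subtraction, cell
    detection, greedy nearest-neighbour linking), exponential and
    plateau-exponential accumulation-profile fitting to estimate decay
    lengths inside and outside the cue capillary, gated maximum chemotactic
    indices with a rank-test significance gate, trajectory straightness and
    chemokinesis statistics, radiotracer uptake kinetics, and an agent-based
    synthetic assay simulator (diffusing point-source gradient plus swimmers
    with tunable klinotaxis and chemokinesis) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
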