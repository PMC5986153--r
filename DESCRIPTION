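Package: octretina
Title: Retinal Layer Segmentation, Structural Phenotyping and Disease
    Classification for SD-OCT Volumes
Version: 0.1.0
Authors@R:
    person("OCT", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments the twelve retinal layer boundaries of spectral-domain
    optical coherence tomography (SD-OCT) B-scan volumes by shortest-path
    search over a graph of Canny edge-pixel groups, extracts ten clinically
    motivated structural features (hyper-reflective intra-retinal spot volume,
    drusen volume, two boundary-curviness scores and six thickness
    statistics), and classifies eyes as normal, AMD or DME with a repeated
    stratified k-fold cross-validation harness. Ships a phantom generator
    producing volumes with fully known layer geometry and injected pathology
    so that the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    yaml,
    glmnet,
    igraph,
    tools,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
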