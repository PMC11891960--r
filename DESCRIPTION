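Package: acntopo
Type: Package
Title: Topological Analysis of Alveolar Capillary Networks from 3D Segmentations
Version: 1.0.0
Authors@R: person("ACN", "Tools", email = "acntools@example.org",
    role = c("aut", "cre"))
Description: Automated quantitative analysis of sheet-like capillary
    networks, such as the alveolar capillary network, from 3D binary
    segmentation volumes. Provides volume input/output (multipage TIFF and
    MetaImage) with postprocessing (isotropic resampling, hole filling,
    largest-component selection, subregion extraction),
    topology-preserving 3D skeletonization with spatial-graph extraction
    and dead-end pruning, Euler-number and cycle-basis counting of septal
    capillary loops with numerical densities and group comparisons, a
    digital physical disector (island/bridge events) for stereological
    verification, per-slice segmentation evaluation metrics, and a
    synthetic phantom generator with exactly known topology for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
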