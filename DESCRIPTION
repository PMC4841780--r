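Package: spiscreen
Title: Quantitative Analysis of Synthetic Physical Interaction Colony Screens
Version: 0.9.0
Authors@R: person("SPI", "Screen Tools", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for proteome-wide synthetic physical interaction (SPI)
    screening in arrayed yeast colony format. Measures two-dimensional colony
    sizes on a fitted 1536-position grid from scanned plate images, converts
    sizes to log growth ratios against two independent controls, computes
    robust z-scores with a local-median spatial smoothing correction,
    confirms growth-defect candidates by a sequential 16-replicate retest
    procedure with a batchwise false-discovery-rate stopping rule, and
    provides downstream profile analyses: screen-screen Spearman correlation,
    hierarchical centroid-linkage clustering with Cluster 3.0 compatible
    exports, SPI frequency and abundance binning, Fisher/hypergeometric
    enrichment, and interaction-density ranking against a known-interaction
    network. Includes a synthetic-data module (plates, images, annotations,
    networks and 3D fluorescence stacks with planted ground truth) and a 3D
    focus quantification routine with dilated-ring background subtraction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
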