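Package: circuitdiff
Title: Comparative Connectomics, Calcium Response Scoring, and Behavioral
    Quantification for Perturbed Mechanosensory Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compare wild-type and perturbed (laterally shifted or
    developmentally silenced) mechanosensory circuits reconstructed at
    synaptic resolution. Implements grouped synapse counts, synaptic input
    fractions (whole-neuron, dendritic, or subvolume-restricted), synapse
    densities per cable length, partner ranking with strong/weak classes,
    left-right homolog conservation probabilities, fold changes and
    cross-volume comparisons; mediolateral node and synapse density
    profiles with sliding-window counting and loess smoothing;
    exploration-area ratios and thresholded membrane-distribution
    profiles; stimulus-locked delta-F/F0 calcium response scoring with
    baseline-band trial rejection; windowed behavior probability and
    duration statistics with coverage and collision filters; the
    statistical tests these stages delegate to; and seeded synthetic-data
    generators with recorded ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
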