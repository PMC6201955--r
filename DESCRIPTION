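Package: cogmap
Title: Population Imaging Analysis of Multimodal Sensory Encoding in the
    Crustacean Commissural Ganglion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for voltage-sensitive-dye population imaging
    of the crab commissural ganglion under chemosensory (IV), mechanosensory
    (VCN) and bimodal stimulation: optical spike detection from fluorescence
    traces (polynomial drift removal, per-neuron high-pass tuning,
    median-based thresholding), per-neuron sensory-response classification
    and frequency-ratio distributions, Pearson-coherence functional
    connectivity graphs with density and global efficiency, spatial
    distribution statistics (hull-normalized distances, angular variance),
    an additive-expectation rule engine for bimodal congruency, and pyloric
    motor-pattern quantification.  A synthetic-data generator with known
    ground truth stands in for raw imaging and electrophysiology data so
    that every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    signal,
    igraph
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
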