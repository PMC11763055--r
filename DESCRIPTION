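Package: avsmotion
Title: Dendritic-Neuron Artificial Visual System for Motion Direction Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A biomimetic artificial visual system that detects the direction of
    object motion between two RGB frames. The pipeline mirrors the early visual
    pathway: cone-cell channel separation, bipolar/horizontal-cell On-Off
    binarisation of temporal and spatial intensity changes, a learnable
    dendritic ganglion neuron (sigmoid synapses, multiplicative branches,
    summing membrane, sigmoid soma) per channel and direction, and a fixed
    lateral-geniculate-nucleus stage that requires joint activation of all
    three colour channels. Includes a synthetic moving-object dataset
    generator, a gradient-descent trainer with an exact analytic backward pass
    verified against finite differences, cross-configuration and
    train/test-ratio experiment protocols, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
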