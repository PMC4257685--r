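Package: vnsnet
Title: Hierarchical Neural-Network Simulation of Vagal Nerve Stimulation and Heart-Rate Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-interval simulator of a three-level hierarchical neural
    network (cardiac, intrathoracic, central) controlling heart rate through
    sympathetic, indirect parasympathetic and direct parasympathetic efferent
    pathways. Implements per-neuron discharge dynamics driven by delayed heart
    rate, blood demand and neighbour networking; first-order efferent drive
    dynamics; continuous within-interval heart-rate relaxation; and an
    intermittent vagal nerve stimulation (VNS) duty-cycle protocol with
    separate indirect (sensitivity-modulation) and direct (motor-pathway gain)
    stimulation mechanisms. Includes a synthetic blood-demand generator,
    scenario presets for the baseline, subthreshold, sympathetic-threshold and
    parasympathetic-threshold stimulation regimes, network activity maps, and
    plain-text exporters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
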