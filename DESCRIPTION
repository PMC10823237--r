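Package: axonmap
Title: Mapping Thalamocortical Monosynaptic Connectivity from
    High-Density Probe Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and characterizing thalamocortical axonal
    waveforms in tangential high-density silicon-probe recordings and for
    inferring monosynaptic connectivity between thalamic axons and cortical
    neurons from spike trains.  Implements multichannel spike-triggered
    waveform extraction with per-ADC sample-time correction, axon versus
    soma classification from rebound duration and spatial spread, axonal
    conduction-speed estimation, jitter-corrected cross-correlogram
    connection detection with spike transmission efficacy, spike-triggered
    axonal footprints on a second probe, receptive-field mapping and
    trial-variability (Fano factor) summaries, and a ground-truth simulator
    (connected Poisson spike trains, somatic and axonal templates, rendered
    flat-binary recordings) that makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
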