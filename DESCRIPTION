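Package: ca1net
Title: Calcium Imaging Analysis of Hippocampal CA1 Network Dynamics During Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for wide-field single-cell calcium
    imaging of hippocampal CA1 during voluntary locomotion on a spherical
    treadmill. Computes linear running speed from two-sensor treadmill
    displacement and segments rest/run bouts with a fuzzy-logic threshold;
    motion-corrects fluorescence video stacks by enhanced cross-correlation and
    extracts ring-background-subtracted, normalized dF/F traces per ROI;
    detects calcium events from low-frequency spectrogram power changes with an
    iterative amplitude-threshold procedure; classifies movement-modulated
    cells and correlated neuron pairs with circular-shift permutation tests on
    binarized event trains; and quantifies state-specific network connectivity
    with a normalized weighted closeness centrality. A synthetic-data module
    generates speed traces, sensor streams, GCaMP-like fluorescence traces and
    toy video stacks with known ground truth so that every stage is testable
    without raw imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
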