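Package: bcinet
Title: Feature-Free Decoding of Motor Intent from Raw EEG with Evolved Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies motor-related brain signals directly from raw
    multichannel time-domain epochs, without hand-crafted features.
    Multilayer perceptrons are trained by a scaled conjugate gradient
    backpropagation augmented with simulated annealing, their hidden-layer
    structure is selected by a genetic algorithm over binary genomes, and
    performance is measured by Cohen's kappa with a large-sample
    significance test.  Includes EMG-based epoch labeling of continuous
    recordings (sliding RMS, threshold, refractory period), readers and
    writers for plain EDF and a self-describing epoch container,
    cross-validation, post-hoc spatial and spectral analysis of trained
    network weights, and seeded synthetic generators for class-conditional
    epochs and continuous EEG+EMG streams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
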