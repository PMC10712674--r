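Package: fsnn
Title: Fractal Spiking Neural Networks for Multichannel EEG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits fractal spiking neural network (SNN) classifiers to
    multichannel EEG. Raw recordings are converted to temporal-spectral-spatial
    feature matrices (band-limited power spectral density and differential
    entropy over sliding windows), re-weighted by per-channel multi-head
    self-attention, and passed through a fractal block of spiking neurons whose
    synapse and reset dynamics are second-order infinite-impulse-response
    filters running along the channel axis. Training uses surrogate gradients
    through the spike nonlinearity and inverted drop-path regularization over
    the fractal sub-paths. Includes cross-validation protocols for
    subject-dependent and leave-one-subject-out evaluation, gradient saliency
    maps, reliability (calibration) tables, and a synthetic EEG generator for
    end-to-end testing without access to restricted EEG databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    yaml,
    stats,
    graphics,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
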