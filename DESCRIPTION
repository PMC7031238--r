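Package: gaitcmc
Title: Gait-Cycle-Resolved Corticomuscular Coherence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Heel-strike-locked electrophysiological analysis of walking:
    temporal gait parameters from footswitch recordings, EEG/EMG conditioning
    (unit-variance normalisation, Butterworth filtering, common average
    reference, bipolar derivations, Hilbert rectification and amplitude
    demodulation), short-time Fourier decomposition of heel-strike-aligned
    epochs, event-related power, inter-trial coherence, corticomuscular
    coherence with parametric z-scoring and confidence masking, event-related
    EMG envelopes, and FDR-controlled band summaries. Includes a synthetic
    gait-record generator with known ground truth so every stage of the
    pipeline is verifiable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
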