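Package: stimfill
Title: Masked-Token Reconstruction of Intracranial EEG Lost to
    Stimulation Blanking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing intracranial EEG (iEEG) signal lost
    during stimulation blanking, when recording amplifiers of responsive
    neurostimulation devices are temporarily disabled. Multichannel
    recordings are reduced to one token per second per channel by
    quantile-binning spectral band power (3- or 4-band schemes), and a
    bidirectional masked-token transformer encoder is trained to
    reconstruct tokens hidden by a mask, mirroring masked language
    modelling. Includes a synthetic iEEG generator with injected blanking
    and amplifier-recovery artifacts, flat-segment artifact detection and
    excision, digit-wise interpolation and uniform-random reconstruction
    baselines, and a tolerance-based evaluation harness reporting mean and
    standard error of per-channel accuracy for 1-10 masked tokens under
    individual and consecutive masking.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
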