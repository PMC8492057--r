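Package: neurosep
Title: Single-Trial Somatosensory Evoked Potential Analysis on Simulated EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of single-trial somatosensory evoked
    potentials (SEPs). Provides a forward-model generator of multichannel
    EEG with an N20-P35 evoked complex whose single-trial gain is driven by
    stimulus intensity and a latent cortical excitability process, alpha-band
    (8-13 Hz) oscillations anti-coupled to excitability, peripheral nerve and
    muscle channels, and a signal-detection-theoretic observer whose response
    criterion tracks excitability. The analysis chain implements
    stimulus-artifact interpolation, zero-phase Butterworth filtering,
    epoching, average re-referencing, template-matching canonical correlation
    analysis (CCA) for single-trial SEP extraction, per-trial feature
    extraction (N20 peak, P15/N140 window means, pre-stimulus alpha envelope,
    CNAP/CMAP amplitudes), signal detection theory estimation with quintile
    bin contrasts and permutation tests, and group-level effect estimation via
    linear mixed-effects models and a two-stage path analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
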