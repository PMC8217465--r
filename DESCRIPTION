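Package: hfoloc
Title: High-Frequency Oscillation Detection and Epileptogenic Zone
    Localization from Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated detection of high-frequency oscillations (ripples,
    80-200 Hz, and fast ripples, 200-500 Hz) in intracranial EEG using a
    zero-phase FIR bandpass, a peak-point-distribution-curve (PPDC)
    baseline with consecutive-peak amplitude thresholds, and a spectral
    discriminator that rejects false oscillations caused by filter
    ringing (Gibbs effect) on sharp transients. Channels are ranked by
    HFO rate and the putative epileptogenic zone is delineated as the
    top-ranked channels covering 72% of fast-ripple events, falling back
    to ripples when no fast ripple is found. Includes slow-wave-segment
    selection by delta-band power, bipolar montage construction, EDF and
    delimited-text I/O, a synthetic iEEG generator with a ground-truth
    event ledger, and the clinical concordance statistics used to relate
    marked regions to surgical outcome (RatioChann, exact Fisher and
    Wilcoxon rank-sum tests, cross-modality consistency,
    sensitivity/specificity bookkeeping).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
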