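Package: fpas
Title: Fast Periodic Auditory Stimulation: Stimulus Engineering and
    Frequency-Tagged EEG Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for auditory frequency-tagging (oddball steady-state)
    experiments: construction of periodic sound sequences with an embedded
    category at a sub-rate (including frequency-bin scrambling, RMS
    equalization and attentional targets), EEG preprocessing (zero-phase
    Butterworth band-pass, FFT multinotch, decimation, epoching, bad-channel
    interpolation, average reference, integer-cycle resegmentation),
    frequency-domain oddball statistics (single-sided amplitude spectra,
    local-baseline z-scores, significant-harmonic selection,
    baseline-subtracted harmonic summation, SNR spectra, chunked
    individual-subject tests), electrode-level and ROI group statistics,
    signal-detection (d-prime) scoring of voice-detection behavior, and a
    synthetic EEG/audio/behavior generator with recorded ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'acoustics.R'
    'stimgen.R'
    'behavior.R'
    'containers.R'
    'fpas-package.R'
    'groupstats.R'
    'io.R'
    'layout.R'
    'preprocess.R'
    'sequence.R'
    'specanalysis.R'
    'synthetic.R'
    'wav.R'
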