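Package: ptinsulate
Title: Acoustic Characterization and Sound-Insulation Modelling for Venous
    Pulsatile Tinnitus Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the acoustics of venous pulsatile tinnitus
    and the sound-insulation performance of temporal-bone reconstruction
    materials. Provides calibrated sensor-trace analysis (RMS and dB SPL,
    short-time Fourier transform, variational mode decomposition,
    continuous wavelet transform, rank-sum comparison of recording
    segments), impedance-tube transfer-matrix transmission loss and
    absorption with octave-band averaging, mercury-intrusion porosimetry
    reduction via the Washburn equation, a Womersley pulsatile-flow
    surrogate with a cross-validating finite-difference solver, a
    Lighthill quadrupole hydroacoustic source model with A-weighted
    virtual-microphone output, and a multilayer insertion-loss efficacy
    calculator for graft and biomaterial stacks. A synthetic-data module
    generates every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
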