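Package: scosflow
Title: Speckle Contrast Optical Spectroscopy Processing for Cerebral
    Blood Flow and Volume
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for multi-channel speckle contrast optical
    spectroscopy (SCOS) recordings of cerebral hemodynamics: raw squared
    speckle contrast with shot-noise, quantization and camera read/dark
    noise corrections, cerebral blood flow index (CBFI = 1/K_adjusted^2)
    and blood volume index (CBVI, linear and logarithmic) extraction, and
    multi-channel Pearson correlation analysis with threshold-based
    channel grouping. Includes a physics-based dynamic-speckle simulator
    (exponentially decorrelating complex Gaussian field, pupil-filtered
    spatial statistics, exposure integration, full sensor noise model and
    a cardiac-like flow waveform) so every stage of the chain can be
    verified against closed-form speckle visibility theory without
    instrument data. Frame stacks are read and written as multi-page TIFF
    or raw binary with JSON sidecars, and a command-line entry point
    mirrors the instrument's batch acquisition workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
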