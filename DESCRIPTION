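Package: sspdim
Title: Automatic Interference-Subspace Dimension Selection for MEG
    Subspace-Projection Denoising
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for denoising evoked magnetoencephalography (MEG)
    recordings with subspace-projection methods (spatial signal space
    projection, SSP, and its spectral variant, S3P) and for choosing the
    interference-subspace dimension automatically.  The dimension is
    selected by sweeping candidate thresholds and maximising a weighted
    sum of two objectives computed from evoked-state data: a
    time-frequency measure of neural-signal distortion and a
    channel-weighted measure of residual noise power.  Includes a
    synthetic OPM-MEG evoked-data simulator with a spherical-conductor
    radial forward model, equivalent-current-dipole localization, and
    peak/mean-absolute/localization error metrics against simulation
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
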