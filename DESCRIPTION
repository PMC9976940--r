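Package: uesnet
Title: Estimating Upper Esophageal Sphincter Opening Distension from
    Neck Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for non-invasive estimation of the anterior-posterior
    upper esophageal sphincter (UES) opening maximal distension from
    tri-axial high-resolution cervical auscultation (HRCA) accelerometry.
    Implements the four-stage signal cleaning chain (anti-aliased
    decimation, autoregressive device-noise whitening, least-squares
    spline detrending, Meyer-wavelet soft-threshold denoising), the
    videofluoroscopy landmark geometry that produces the C2-C4 normalized
    ground-truth distension ratio, an attention-masked convolutional
    recurrent regression network trained with Adam on mean squared error,
    k-fold cross-validated absolute-percentage-error evaluation, and a
    seeded synthetic swallow simulator with planted ground truth for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    splines,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
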