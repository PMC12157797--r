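Package: colorqr
Title: Color QR Codes and Smartphone Colorimetric Readout of Free Chlorine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates back-compatible Color QR codes that embed colorimetric
    reference patches, detects and rectifies them in photographs, corrects
    scene colors with thin-plate-spline maps fitted on the captured/reference
    patch pairs, extracts assay regions of interest (bromothymol-blue strip
    pads and DPD cuvettes), and converts corrected colors into a free-chlorine
    class (low / acceptable / excess) and a ppm estimate via SVM
    classification and log-linear calibration. Includes a fully labelled
    synthetic scene generator (dye response models, Planckian illuminants
    2500-6500 K, perspective distortion, sensor noise) so that every stage and
    the end-to-end pipeline are testable without a camera.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    png,
    e1071,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
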