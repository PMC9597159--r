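Package: speccal
Title: Physical-Model Wavelength Calibration for Array-Detector Spectrometers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Wavelength calibration of grating spectrometers with array
    detectors based on a closed-form physical model of the dispersion.
    Implements the forward (wavelength to pixel) and inverse (pixel to
    wavelength) grating-equation model for rotated reflection and
    transmission gratings, a hybrid calibration algorithm combining a
    brute-force search over the nonlinear parameters (half-deviation
    angle, effective grating period, grating rotation angle) with a
    nested first-order least-squares fit absorbing the linear ones
    (focal length, pixel pitch, detector centre offset), Lorentzian
    sub-pixel localization of reference-lamp emission peaks, polynomial
    baseline calibrators, error metrics, and all-peaks / leave-one-out /
    leave-half-out evaluation schemes.  A synthetic lamp-spectrum
    generator makes the whole pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
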