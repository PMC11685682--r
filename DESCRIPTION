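Package: savehsi
Title: Spectrum-Aided Visual Enhancement for White-Light Endoscopic Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calibrated reconstruction of per-pixel reflectance spectra from
    8-bit sRGB white-light endoscopic images, and band-selective
    re-illumination that simulates narrow-band imaging (NBI). A 24-patch
    color-checker drives camera correction (polynomial variable expansion and
    least-squares correction matrix), a principal-component basis of patch
    reflectances with a regression conversion matrix turns corrected
    tristimulus values into analog spectra on a 1 nm wavelength grid, and a
    sum-of-Lorentzians illuminant model is fitted by generalized simulated
    annealing to minimize the mean CIEDE2000 difference against 24 reference
    NBI patch colors. Includes a synthetic-fixture generator (checker
    reflectances, broadband illuminant, planted NBI targets, checker mosaic
    and lesion phantom images) so the full pipeline runs without clinical or
    spectrometer data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
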