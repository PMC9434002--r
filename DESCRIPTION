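Package: sdoct
Title: Spectral-Domain OCT Simulation, Reconstruction, and Large-Field Mosaicking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for spectral-domain optical coherence
    tomography (SD-OCT) of gross pathology specimens. Simulates raw
    spectrometer fringes for reflector and layered phantoms under a
    configurable system model (broadband source, line-scan spectrometer,
    dispersion mismatch, shot and read noise), estimates the calibration
    vectors reconstruction needs (background spectrum, uniform-wavenumber
    resampling map, dispersion-compensation phase), runs the five-step
    A-scan reconstruction chain (background subtraction, linear-k
    interpolation, apodization, numerical dispersion compensation, Fourier
    transform), plans serpentine tile scans over a cassette, stitches tile
    volumes into a large-field mosaic, computes en-face depth projections,
    and measures system performance (axial point-spread FWHM, sensitivity
    roll-off, SNR) on reconstructed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    signal,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
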