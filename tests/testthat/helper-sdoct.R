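# Shared fixtures: a small, fast system spec and ideal calibration built
# from noiseless simulation.

test_spec <- function(n_pixels = 512, blur_fwhm = 0, read_noise = 10,
                      dispersion = dispersion_model(),
                      shape = "gaussian", ...) {
  system_spec(
    source = source_spectrum(850, 100, shape = shape),
    spectrometer = spectrometer_model(n_pixels = n_pixels,
                                      blur_fwhm = blur_fwhm,
                                      read_noise = read_noise),
    dispersion = dispersion, ...)
}

# Calibration from the true (noiseless) background and the configured
# wavelength map; zero dispersion phase.
ideal_cal <- function(spec, ...) {
  lam <- pixel_wavelengths(spec$spectrometer)
  bg <- simulate_fringe(phantom(), spec, noise = FALSE, reference_only = TRUE)
  calibration_set(as.numeric(bg), build_k_mapping(lam), lam, ...)
}

mirror_phantom <- function(z_um, r = 0.05) {
  phantom(reflectors = data.frame(z_um = z_um, r = r))
}

zmax_um <- function(spec) max_imaging_depth(spec$spectrometer) * 1000

# Noiseless mirror fringe -> reconstructed A-scan.
mirror_ascan <- function(spec, cal, z_um, r = 0.05, window = "rect",
                         pad = 4, oversample = 8) {
  fr <- simulate_fringe(mirror_phantom(z_um, r), spec, noise = FALSE,
                        oversample = oversample)
  reconstruct_ascan(as.numeric(fr), cal, window = window, pad = pad)
}
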