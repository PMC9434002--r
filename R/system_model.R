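# System model: optical/acquisition parameters and closed-form spec calculators.
#
# Unit conventions used throughout the package:
#   wavelength lambda  nm
#   wavenumber k       rad/um  (k = 2000*pi / lambda_nm)
#   depth z            um, optical single-pass path
#   dispersion a_m     rad/(rad/um)^m, phase terms of order m >= 2 in (k - k0)

#' Broadband source spectrum
#'
#' Describes the light source by its center wavelength, FWHM bandwidth and
#' spectral shape. `power_scale` multiplies the detected counts; the peak
#' background level is set by the simulator (see [simulate_fringe()]).
#'
#' @param center_wavelength Center wavelength lambda0 (nm).
#' @param fwhm_bandwidth FWHM bandwidth (nm).
#' @param shape One of `"gaussian"`, `"flat_top"`, `"tabulated"`.
#' @param power_scale Dimensionless scale on detected counts (default 1).
#' @param envelope For `shape = "tabulated"`, non-negative envelope values
#'   sampled on the spectrometer pixel grid.
#' @return An object of class `source_spectrum`.
#' @export
source_spectrum <- function(center_wavelength = 850, fwhm_bandwidth = 100,
                            shape = c("gaussian", "flat_top", "tabulated"),
                            power_scale = 1, envelope = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(center_wavelength) || center_wavelength <= 0)
    stop("center_wavelength must be > 0")
  if (!is.numeric(fwhm_bandwidth) || fwhm_bandwidth <= 0)
    stop("fwhm_bandwidth must be > 0")
  if (power_scale <= 0) stop("power_scale must be > 0")
  if (shape == "tabulated") {
    if (is.null(envelope) || any(envelope < 0) || all(envelope == 0))
      stop("tabulated shape requires a non-negative, non-zero envelope")
  }
  structure(list(center_wavelength = center_wavelength,
                 fwhm_bandwidth = fwhm_bandwidth,
                 shape = shape, power_scale = power_scale,
                 envelope = envelope),
            class = "source_spectrum")
}

#' Line-scan spectrometer model
#'
#' @param n_pixels Number of camera pixels N (>= 2).
#' @param lambda_min,lambda_max Detected wavelength span endpoints (nm).
#' @param lambda_of_pixel Optional strictly monotone wavelength per pixel
#'   (nm, length `n_pixels`). Default: linear in wavelength from
#'   `lambda_min` to `lambda_max` (grating spectrometer convention).
#' @param blur_fwhm Spectral blur FWHM (nm, >= 0). The default 0.13 nm,
#'   together with pixel boxcar integration, yields a 6-dB amplitude
#'   roll-off near 1.1 mm for the default 2048-pixel 750--930 nm span.
#' @param bit_depth Camera bit depth; full well = 2^bit_depth - 1 counts.
#' @param read_noise Read noise sigma_r (counts RMS).
#' @return An object of class `spectrometer_model`.
#' @export
spectrometer_model <- function(n_pixels = 2048, lambda_min = 750,
                               lambda_max = 930, lambda_of_pixel = NULL,
                               blur_fwhm = 0.13, bit_depth = 12,
                               read_noise = 10) {
  if (n_pixels < 2) stop("n_pixels must be >= 2")
  if (blur_fwhm < 0) stop("blur_fwhm must be >= 0")
  if (read_noise < 0) stop("read_noise must be >= 0")
  if (is.null(lambda_of_pixel)) {
    if (!(lambda_min > 0 && lambda_max > lambda_min))
      stop("require 0 < lambda_min < lambda_max")
    lambda_of_pixel <- seq(lambda_min, lambda_max, length.out = n_pixels)
  } else {
    if (length(lambda_of_pixel) != n_pixels)
      stop("lambda_of_pixel must have length n_pixels")
    d <- diff(lambda_of_pixel)
    if (!(all(d > 0) || all(d < 0)))
      stop("lambda_of_pixel must be strictly monotone")
    lambda_min <- lambda_of_pixel[1]
    lambda_max <- lambda_of_pixel[n_pixels]
  }
  structure(list(n_pixels = as.integer(n_pixels),
                 lambda_min = lambda_min, lambda_max = lambda_max,
                 lambda_of_pixel = lambda_of_pixel,
                 blur_fwhm = blur_fwhm,
                 bit_depth = as.integer(bit_depth),
                 full_well = 2^bit_depth - 1,
                 read_noise = read_noise),
            class = "spectrometer_model")
}

#' Dispersion mismatch model
#'
#' Polynomial phase mismatch phi(k) = sum_{m>=2} a_m (k - k0)^m between the
#' sample and reference arms. Order-0 and order-1 terms are absent by
#' construction: they shift the peak but do not broaden it.
#'
#' @param coefficients Numeric vector `c(a2, a3, ...)` in rad/(rad/um)^m,
#'   first element the quadratic term. May be empty (no mismatch).
#' @param k0 Reference wavenumber (rad/um); `NULL` means the center of the
#'   uniform-k grid of the spectrometer in use.
#' @return An object of class `dispersion_model`.
#' @export
dispersion_model <- function(coefficients = numeric(0), k0 = NULL) {
  if (length(coefficients) && !is.numeric(coefficients))
    stop("coefficients must be numeric")
  structure(list(coefficients = as.numeric(coefficients), k0 = k0),
            class = "dispersion_model")
}

#' Full system specification
#'
#' Single source of truth for all physics: source, spectrometer, dispersion
#' mismatch, scan geometry and tissue index. All simulator, calibration,
#' reconstruction and metrics functions consume this object.
#'
#' @param source A [source_spectrum()].
#' @param spectrometer A [spectrometer_model()].
#' @param dispersion A [dispersion_model()] (default: none).
#' @param na Numerical aperture of the imaging lens, in (0, 1).
#' @param a_line_rate A-line rate (A-lines/s; metadata only).
#' @param a_lines_per_bscan A-lines per B-scan.
#' @param bscans_per_volume B-scans per tile volume.
#' @param tile_fov Lateral field of view of one tile, `c(x, y)` in mm.
#' @param tissue_index Tissue group refractive index (>= 1, default 1.4).
#' @return An object of class `system_spec`.
#' @export
system_spec <- function(source = source_spectrum(),
                        spectrometer = spectrometer_model(),
                        dispersion = dispersion_model(),
                        na = 0.055, a_line_rate = 250e3,
                        a_lines_per_bscan = 1024, bscans_per_volume = 1024,
                        tile_fov = c(5, 5), tissue_index = 1.4) {
  stopifnot(inherits(source, "source_spectrum"),
            inherits(spectrometer, "spectrometer_model"),
            inherits(dispersion, "dispersion_model"))
  if (!(na > 0 && na < 1)) stop("na must be in (0, 1)")
  if (tissue_index < 1) stop("tissue_index must be >= 1")
  if (a_lines_per_bscan < 1 || bscans_per_volume < 1)
    stop("scan counts must be >= 1")
  if (length(tile_fov) != 2 || any(tile_fov <= 0))
    stop("tile_fov must be c(x, y) in mm, both > 0")
  structure(list(source = source, spectrometer = spectrometer,
                 dispersion = dispersion, na = na,
                 a_line_rate = a_line_rate,
                 a_lines_per_bscan = as.integer(a_lines_per_bscan),
                 bscans_per_volume = as.integer(bscans_per_volume),
                 tile_fov = as.numeric(tile_fov),
                 tissue_index = tissue_index),
            class = "system_spec")
}

#' @export
print.system_spec <- function(x, ...) {
  cat("SD-OCT system spec\n")
  cat(sprintf("  source: %g nm center, %g nm FWHM (%s)\n",
              x$source$center_wavelength, x$source$fwhm_bandwidth,
              x$source$shape))
  cat(sprintf("  spectrometer: %d px, %g-%g nm, blur %g nm, %d-bit\n",
              x$spectrometer$n_pixels, x$spectrometer$lambda_min,
              x$spectrometer$lambda_max, x$spectrometer$blur_fwhm,
              x$spectrometer$bit_depth))
  cat(sprintf("  scan: %d A-lines/B-scan x %d B-scans, tile %g x %g mm\n",
              x$a_lines_per_bscan, x$bscans_per_volume,
              x$tile_fov[1], x$tile_fov[2]))
  invisible(x)
}

# ---- wavelength / wavenumber grids -----------------------------------------

#' Wavelength of each spectrometer pixel (nm)
#' @param spectrometer A [spectrometer_model()].
#' @return Numeric vector of length `n_pixels`.
#' @export
pixel_wavelengths <- function(spectrometer) spectrometer$lambda_of_pixel

#' Wavenumber of each spectrometer pixel (rad/um)
#' @inheritParams pixel_wavelengths
#' @return Numeric vector of length `n_pixels`.
#' @export
pixel_wavenumbers <- function(spectrometer) {
  2000 * pi / spectrometer$lambda_of_pixel
}

# Uniform-k grid in ascending-k order (rad/um), shared endpoints with the
# pixel grid. Reconstruction and dispersion vectors live on this grid.
k_uniform_ascending <- function(spectrometer) {
  k <- pixel_wavenumbers(spectrometer)
  seq(min(k[1], k[length(k)]), max(k[1], k[length(k)]),
      length.out = spectrometer$n_pixels)
}

# Mean wavenumber pitch of the uniform-k grid (rad/um)
k_pitch <- function(spectrometer) {
  k <- pixel_wavenumbers(spectrometer)
  abs(k[1] - k[length(k)]) / (spectrometer$n_pixels - 1)
}

# ---- closed-form calculators ----------------------------------------------

#' Source coherence length
#'
#' `lambda0^2 / dlambda`, converted to micrometers. This is the convention
#' under which an 850 nm / 100 nm source has a 7.2 um coherence length; the
#' Gaussian FWHM axial resolution carries its `2 ln2 / pi` factor separately
#' (see [axial_resolution_theory()]).
#'
#' @param lambda0 Center wavelength (nm).
#' @param dlambda FWHM bandwidth (nm).
#' @return Coherence length in um.
#' @export
#' @examples
#' coherence_length(850, 100) # 7.225 um
coherence_length <- function(lambda0, dlambda) {
  if (any(lambda0 <= 0) || any(dlambda <= 0))
    stop("lambda0 and dlambda must be > 0")
  lambda0^2 / dlambda / 1000
}

#' Theoretical axial resolution (Gaussian source)
#'
#' FWHM of the axial point-spread function for a Gaussian source:
#' `(2 ln2 / pi) * lambda0^2 / (dlambda * n)`.
#'
#' @inheritParams coherence_length
#' @param n Refractive index of the medium (>= 1; 1 for air).
#' @return Axial FWHM in um.
#' @export
#' @examples
#' axial_resolution_theory(850, 100)       # 3.19 um in air
#' axial_resolution_theory(850, 100, 1.4)  # tissue-scaled
axial_resolution_theory <- function(lambda0, dlambda, n = 1) {
  if (any(n < 1)) stop("refractive index n must be >= 1")
  (2 * log(2) / pi) * coherence_length(lambda0, dlambda) / n
}

#' Theoretical lateral resolution (Gaussian beam)
#'
#' Diffraction-limited lateral spot FWHM `0.37 * lambda0 / NA`.
#'
#' @inheritParams coherence_length
#' @param na Numerical aperture, in (0, 1).
#' @return Lateral FWHM in um.
#' @export
lateral_resolution_theory <- function(lambda0, na) {
  if (any(lambda0 <= 0)) stop("lambda0 must be > 0")
  if (any(na <= 0) || any(na >= 1)) stop("na must be in (0, 1)")
  0.37 * lambda0 / na / 1000
}

#' Maximum (Nyquist) imaging depth
#'
#' `pi / (2 * dk)` where `dk` is the mean wavenumber pitch of the
#' uniform-k resampled grid spanning the spectrometer's detected range.
#' The deepest alias-free depth of reconstruction.
#'
#' @inheritParams pixel_wavelengths
#' @return Depth in mm.
#' @export
max_imaging_depth <- function(spectrometer) {
  if (spectrometer$n_pixels < 2) stop("n_pixels must be >= 2")
  pi / (2 * k_pitch(spectrometer)) / 1000
}

# Depth-bin pitch of reconstructed A-scans (um per bin), including zero-pad.
depth_pitch_um <- function(spectrometer, pad = 1) {
  max_imaging_depth(spectrometer) * 1000 / (spectrometer$n_pixels / 2) / pad
}

#' Theoretical sensitivity roll-off envelope
#'
#' Amplitude decay (dB, 0 at z = 0) from finite pixel integration (sinc
#' term, rectangular pixel) and spectral blur (Gaussian term):
#' `20 log10( sinc(z * dk) * exp(-2 * sigma_k^2 * z^2) )`
#' with `dk` the pixel pitch in k and `sigma_k` the blur standard deviation
#' in k at the center wavelength. Amplitude (not intensity) decibels.
#'
#' @inheritParams pixel_wavelengths
#' @param z_mm Depth(s), 0 <= z <= [max_imaging_depth()].
#' @return Roll-off in dB (<= 0), same length as `z_mm`.
#' @export
rolloff_envelope_theory <- function(spectrometer, z_mm) {
  zmax <- max_imaging_depth(spectrometer)
  if (any(z_mm < 0) || any(z_mm > zmax + 1e-12))
    stop("z_mm must lie in [0, max_imaging_depth]")
  z <- z_mm * 1000                      # um
  dk <- k_pitch(spectrometer)           # rad/um
  x <- z * dk
  s <- ifelse(x == 0, 1, sin(x) / x)    # pixel boxcar integration
  lam0 <- (spectrometer$lambda_min + spectrometer$lambda_max) / 2
  sigma_k <- spectrometer$blur_fwhm * (2000 * pi / lam0^2) / (2 * sqrt(2 * log(2)))
  g <- exp(-2 * sigma_k^2 * z^2)        # Gaussian spectral blur
  20 * log10(s * g)
}

# Depth (mm) at which the theoretical envelope reaches -6 dB, or NA if it
# never does within the alias-free range.
rolloff_6db_theory <- function(spectrometer) {
  zmax <- max_imaging_depth(spectrometer)
  f <- function(z) rolloff_envelope_theory(spectrometer, z) + 6
  if (f(zmax) > 0) return(NA_real_)
  stats::uniroot(f, c(0, zmax), tol = 1e-9)$root
}

#' Parameter and theory report
#'
#' Tabulates configured system parameters side by side with the computed
#' theory values (coherence length, axial/lateral resolution in air and
#' tissue for the configured index and for n = 1.49, Nyquist depth,
#' theoretical 6-dB roll-off depth).
#'
#' @param spec A [system_spec()].
#' @return A `data.frame` with columns `parameter`, `value`, `unit`.
#' @export
spec_report <- function(spec) {
  src <- spec$source; sp <- spec$spectrometer
  l0 <- src$center_wavelength; dl <- src$fwhm_bandwidth
  n_t <- spec$tissue_index
  z6 <- rolloff_6db_theory(sp)
  rows <- list(
    c("center wavelength",            l0,                                "nm"),
    c("bandwidth (FWHM)",             dl,                                "nm"),
    c("spectrometer span",            paste0(sp$lambda_min, "-", sp$lambda_max), "nm"),
    c("spectrometer pixels",          sp$n_pixels,                       "px"),
    c("A-line rate",                  spec$a_line_rate,                  "Hz"),
    c("A-lines per B-scan",           spec$a_lines_per_bscan,            ""),
    c("numerical aperture",           spec$na,                           ""),
    c("tissue index (configured)",    n_t,                               ""),
    c("coherence length",             round(coherence_length(l0, dl), 3), "um"),
    c("axial resolution, air",        round(axial_resolution_theory(l0, dl), 3), "um"),
    c(sprintf("axial resolution, tissue n=%g", n_t),
      round(axial_resolution_theory(l0, dl, n_t), 3),                    "um"),
    c("axial resolution, tissue n=1.49",
      round(axial_resolution_theory(l0, dl, 1.49), 3),                   "um"),
    c("lateral resolution (theory)",  round(lateral_resolution_theory(l0, spec$na), 3), "um"),
    c("Nyquist imaging depth",        round(max_imaging_depth(sp), 4),   "mm"),
    c("6-dB roll-off depth (theory)", ifelse(is.na(z6), NA, round(z6, 4)), "mm"))
  data.frame(parameter = vapply(rows, `[`, "", 1),
             value = vapply(rows, `[`, "", 2),
             unit = vapply(rows, `[`, "", 3),
             stringsAsFactors = FALSE)
}

# Source spectral envelope evaluated at arbitrary wavelengths (nm), peak 1.
source_envelope <- function(source, spectrometer, lambda) {
  l0 <- source$center_wavelength; dl <- source$fwhm_bandwidth
  switch(source$shape,
    gaussian = exp(-4 * log(2) * ((lambda - l0) / dl)^2),
    flat_top = as.numeric(abs(lambda - l0) <= dl / 2),
    tabulated = {
      env <- source$envelope / max(source$envelope)
      stats::approx(spectrometer$lambda_of_pixel, env, xout = lambda,
                    rule = 2)$y
    })
}

# Dispersion phase phi(k) evaluated at wavenumbers k (rad/um).
dispersion_phase_at <- function(dispersion, k, k0_default) {
  co <- dispersion$coefficients
  if (!length(co)) return(rep(0, length(k)))
  k0 <- if (is.null(dispersion$k0)) k0_default else dispersion$k0
  ph <- 0
  for (m in seq_along(co)) ph <- ph + co[m] * (k - k0)^(m + 1)
  ph
}
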