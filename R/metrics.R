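# System-characterization measurements on reconstructed data: axial PSF
# FWHM, sensitivity roll-off with 6-dB depth, and SNR.

# Peak finding on an A-scan magnitude, ignoring the DC-residual bins.
find_peak <- function(mag, dc_guard = 4) {
  m <- mag
  m[seq_len(min(dc_guard, length(m)))] <- 0
  i <- which.max(m)
  list(index = i, mag = m[i])
}

# Require the main peak to stand >= 6 dB above the next-highest peak
# outside +/- guard bins; returns the peak index or stops.
require_dominant_peak <- function(mag, guard = 10, dc_guard = 4) {
  pk <- find_peak(mag, dc_guard)
  m <- mag
  m[seq_len(min(dc_guard, length(m)))] <- 0
  excl <- pmax(1, pk$index - guard):pmin(length(m), pk$index + guard)
  second <- max(m[-excl])
  if (20 * log10(pk$mag / max(second, .Machine$double.eps)) < 6)
    stop("no dominant peak (< 6 dB above second highest)")
  pk$index
}

#' Measure the axial PSF FWHM of an A-scan
#'
#' Full width at half maximum of the magnitude peak. The peak value and
#' position are refined with a three-point parabola, and the half-maximum
#' crossings are located by linear interpolation between the straddling
#' bins.
#'
#' @param ascan An `ascan` from [reconstruct_ascan()].
#' @param guard Half-width (bins) of the exclusion zone around the main
#'   peak when checking that it stands >= 6 dB above the second peak.
#'   Widen for deliberately broadened peaks (e.g. uncompensated
#'   dispersion).
#' @return FWHM in um. If the width is under 2 depth bins the result
#'   carries attribute `resolution_limited = TRUE`.
#' @export
measure_psf_fwhm <- function(ascan, guard = 10) {
  stopifnot(inherits(ascan, "ascan"))
  mag <- Mod(ascan$values)
  ipk <- require_dominant_peak(mag, guard = guard)
  ref <- parabolic_peak(mag, ipk)
  half <- ref$y / 2

  cross <- function(dir) {
    i <- ipk
    repeat {
      j <- i + dir
      if (j < 1 || j > length(mag)) return(NA_real_)
      if (mag[j] < half)
        return(i + dir * (mag[i] - half) / (mag[i] - mag[j]))
      i <- j
    }
  }
  lo <- cross(-1); hi <- cross(1)
  if (is.na(lo) || is.na(hi)) stop("half-maximum crossing outside depth range")
  fw_bins <- hi - lo
  out <- fw_bins * ascan$pitch_um
  if (fw_bins < 2) attr(out, "resolution_limited") <- TRUE
  out
}

#' Measure the depth of the dominant A-scan peak
#'
#' Depth (um) of the magnitude peak, refined to sub-bin precision with a
#' three-point parabola. Bin 0 is zero depth.
#'
#' @inheritParams measure_psf_fwhm
#' @return Depth in um.
#' @export
measure_peak_depth <- function(ascan) {
  stopifnot(inherits(ascan, "ascan"))
  mag <- Mod(ascan$values)
  ipk <- find_peak(mag)$index
  (parabolic_peak(mag, ipk)$x - 1) * ascan$pitch_um
}

#' Measured sensitivity roll-off curve and 6-dB depth
#'
#' Simulates and reconstructs an identical mirror at each depth and
#' records the peak amplitude decay `20 log10(peak / peak at the
#' shallowest depth)`. The 6-dB depth is found by linear interpolation of
#' the curve. Amplitude decibels, consistent with
#' [rolloff_envelope_theory()].
#'
#' @param spec A [system_spec()] (its spectrometer's blur and the pixel
#'   integration implied by `oversample` set the decay).
#' @param depths_mm Mirror depths (>= 5 values recommended, spanning the
#'   alias-free range); default 12 depths over 5--95% of the Nyquist
#'   depth.
#' @param r Mirror amplitude reflectivity.
#' @param window Apodization used for the measurement.
#' @param oversample Pixel-integration oversampling (1 disables pixel
#'   integration).
#' @param pad Zero-pad factor for peak refinement.
#' @return List: `depths_mm`, `rolloff_db`, `falloff_6db_mm` (`NA` if the
#'   curve never reaches -6 dB), `monotone` (logical).
#' @export
sensitivity_falloff <- function(spec, depths_mm = NULL, r = 0.05,
                                window = "rect", oversample = 8, pad = 2) {
  stopifnot(inherits(spec, "system_spec"))
  sp <- spec$spectrometer
  zmax <- max_imaging_depth(sp)
  if (is.null(depths_mm))
    depths_mm <- seq(0.05, 0.95, length.out = 12) * zmax
  if (length(depths_mm) < 2) stop("need at least 2 depths")
  lam <- pixel_wavelengths(sp)
  bg <- simulate_fringe(phantom(), spec, noise = FALSE, oversample = oversample,
                        reference_only = TRUE)
  cal <- calibration_set(as.numeric(bg), build_k_mapping(lam), lam)
  peaks <- vapply(depths_mm, function(z) {
    ph <- phantom(reflectors = data.frame(z_um = z * 1000, r = r))
    fr <- simulate_fringe(ph, spec, noise = FALSE, oversample = oversample)
    asc <- reconstruct_ascan(as.numeric(fr), cal, window = window, pad = pad)
    mag <- Mod(asc$values)
    parabolic_peak(mag, find_peak(mag)$index)$y
  }, 0)
  db <- 20 * log10(peaks / peaks[1])
  mono <- all(diff(db) <= 0.1)
  if (!mono) warning("roll-off curve not monotone non-increasing")
  z6 <- NA_real_
  below <- which(db <= -6)
  if (length(below)) {
    j <- below[1]
    z6 <- if (j == 1) depths_mm[1] else
      stats::approx(db[(j - 1):j], depths_mm[(j - 1):j], xout = -6)$y
  }
  list(depths_mm = depths_mm, rolloff_db = db, falloff_6db_mm = z6,
       monotone = mono)
}

#' Measure SNR of an A-scan
#'
#' `20 log10(peak magnitude / sd(noise-region magnitude))`.
#'
#' @param ascan An `ascan`.
#' @param noise_region `c(first, last)` depth-bin range used as the noise
#'   floor; must exclude the peak +/- 10 bins.
#' @return SNR in dB. Noiseless input (zero noise sd) returns `Inf` with
#'   attribute `noiseless = TRUE`.
#' @export
measure_snr <- function(ascan, noise_region) {
  stopifnot(inherits(ascan, "ascan"))
  mag <- Mod(ascan$values)
  noise_region <- as.integer(noise_region)
  if (length(noise_region) != 2 || noise_region[1] < 1 ||
      noise_region[2] > length(mag) || noise_region[1] > noise_region[2])
    stop("invalid noise region")
  ipk <- find_peak(mag)$index
  if (noise_region[1] <= ipk + 10 && noise_region[2] >= ipk - 10)
    stop("noise region must exclude the peak +/- 10 bins")
  ns <- stats::sd(mag[noise_region[1]:noise_region[2]])
  if (ns == 0)
    return(structure(Inf, noiseless = TRUE))
  pk <- parabolic_peak(mag, ipk)$y
  20 * log10(pk / ns)
}

#' Full system performance report
#'
#' Simulates the standard characterization measurements under a system
#' spec: axial PSF FWHM of a shallow mirror (air, plus tissue-scaled
#' values for the configured index and for n = 1.49), the sensitivity
#' roll-off curve with its 6-dB depth, and the SNR of a noisy mirror
#' fringe. Deterministic for a given seed.
#'
#' @param spec A [system_spec()].
#' @param seed Seed for the SNR measurement's noise.
#' @param psf_depth_mm Mirror depth for the PSF measurement.
#' @param n_rolloff_depths Number of roll-off sample depths.
#' @return An object of class `performance_report`.
#' @export
performance_report <- function(spec, seed = 1L, psf_depth_mm = 0.3,
                               n_rolloff_depths = 12) {
  stopifnot(inherits(spec, "system_spec"))
  sp <- spec$spectrometer
  lam <- pixel_wavelengths(sp)
  bg <- simulate_fringe(phantom(), spec, noise = FALSE, reference_only = TRUE)
  cal <- calibration_set(as.numeric(bg), build_k_mapping(lam), lam)
  ph <- phantom(reflectors = data.frame(z_um = psf_depth_mm * 1000, r = 0.05))

  fr0 <- simulate_fringe(ph, spec, noise = FALSE)
  asc0 <- reconstruct_ascan(as.numeric(fr0), cal, window = "rect", pad = 4)
  fwhm_air <- as.numeric(measure_psf_fwhm(asc0))

  ro <- sensitivity_falloff(spec, depths_mm = seq(0.05, 0.95,
                            length.out = n_rolloff_depths) *
                              max_imaging_depth(sp))

  frn <- simulate_fringe(ph, spec, noise = TRUE, seed = seed)
  ascn <- reconstruct_ascan(as.numeric(frn), cal, window = "rect")
  nz <- length(ascn$values)
  ipk <- find_peak(Mod(ascn$values))$index
  region <- if (ipk < nz / 2) c(as.integer(nz * 0.7), nz) else
    c(as.integer(nz * 0.05), as.integer(nz * 0.3))
  snr <- measure_snr(ascn, region)

  structure(list(
    axial_fwhm_air_um = fwhm_air,
    axial_fwhm_tissue_um = fwhm_air / spec$tissue_index,
    axial_fwhm_tissue149_um = fwhm_air / 1.49,
    tissue_index = spec$tissue_index,
    falloff_6db_mm = ro$falloff_6db_mm,
    rolloff_curve = data.frame(depth_mm = ro$depths_mm, db = ro$rolloff_db),
    snr_db = as.numeric(snr),
    snr_noiseless = isTRUE(attr(snr, "noiseless")),
    theory = list(
      axial_fwhm_um = axial_resolution_theory(spec$source$center_wavelength,
                                              spec$source$fwhm_bandwidth),
      max_depth_mm = max_imaging_depth(sp),
      falloff_6db_mm = rolloff_6db_theory(sp)),
    seed = seed), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("SD-OCT performance report\n")
  cat(sprintf("  axial FWHM: %.3f um (air), %.3f um (tissue n=%g), %.3f um (n=1.49)\n",
              x$axial_fwhm_air_um, x$axial_fwhm_tissue_um, x$tissue_index,
              x$axial_fwhm_tissue149_um))
  cat(sprintf("  6-dB roll-off: %.3f mm (theory %.3f mm)\n",
              x$falloff_6db_mm, x$theory$falloff_6db_mm))
  cat(sprintf("  SNR: %.1f dB%s\n", x$snr_db,
              if (x$snr_noiseless) " [noiseless]" else ""))
  invisible(x)
}
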