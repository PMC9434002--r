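# Build an ascan object directly from magnitudes (for estimator tests).
synthetic_ascan <- function(mag, pitch_um = 1) {
  structure(list(values = complex(real = mag), pitch_um = pitch_um,
                 n = 2L * length(mag), pad = 1L, window = "rect",
                 flags = list()), class = "ascan")
}

test_that("PSF FWHM measurement recovers a known Gaussian width", {
  z <- seq_len(512)
  for (sigma in c(3, 7.5, 20)) {
    mag <- exp(-0.5 * ((z - 201.3) / sigma)^2)
    fw <- measure_psf_fwhm(synthetic_ascan(mag, pitch_um = 0.7),
                           guard = 8 * sigma)
    expect_lt(abs(fw - 2.3548 * sigma * 0.7) / (2.3548 * sigma * 0.7), 0.02)
  }
  # single-bin impulse: flagged resolution-limited, at most one bin wide
  imp <- rep(0, 128); imp[40] <- 1
  fw <- measure_psf_fwhm(synthetic_ascan(imp))
  expect_true(isTRUE(attr(fw, "resolution_limited")))
  expect_lte(as.numeric(fw), 1)
  # two comparable peaks: no dominant peak
  two <- rep(0.001, 256); two[60] <- 1; two[180] <- 0.9
  expect_error(measure_psf_fwhm(synthetic_ascan(two)), "dominant")
})

test_that("simulated mirror FWHM agrees with the axial-resolution theory", {
  spec <- test_spec(n_pixels = 2048)
  cal <- ideal_cal(spec)
  fw <- measure_psf_fwhm(mirror_ascan(spec, cal, 400))
  theory <- axial_resolution_theory(850, 100, 1)
  expect_lt(abs(fw - theory) / theory, 0.10)
})

test_that("roll-off is flat without decay mechanisms and matches theory
          with them", {
  # no blur, no pixel integration, uniform-k sampling: no decay mechanism
  n <- 1024
  k <- seq(2000 * pi / 930, 2000 * pi / 750, length.out = n)
  spec0 <- system_spec(spectrometer = spectrometer_model(
    n_pixels = n, lambda_of_pixel = 2000 * pi / rev(k), blur_fwhm = 0))
  ro0 <- sensitivity_falloff(spec0, oversample = 1)
  expect_lt(max(abs(ro0$rolloff_db)), 0.1)
  # pixel integration + blur: 6-dB depth within 5% of the closed form
  spec <- test_spec(n_pixels = 1024, blur_fwhm = 0.26)
  ro <- sensitivity_falloff(spec, oversample = 8)
  expect_true(ro$monotone)
  z6_th <- sdoct:::rolloff_6db_theory(spec$spectrometer)
  expect_false(is.na(ro$falloff_6db_mm))
  expect_lt(abs(ro$falloff_6db_mm - z6_th) / z6_th, 0.05)
})

test_that("SNR measurement matches noise propagation through the DFT", {
  # uniform-k spectrometer (identity k map), rect window: the A-scan noise
  # magnitude is Rayleigh with sd = sigma_r * sqrt(2) * sqrt((4-pi)/2)
  n <- 1024
  k <- seq(2000 * pi / 930, 2000 * pi / 750, length.out = n)
  lam_k <- 2000 * pi / rev(k)
  sigma_r <- 15
  spec <- system_spec(
    spectrometer = spectrometer_model(n_pixels = n, lambda_of_pixel = lam_k,
                                      blur_fwhm = 0, read_noise = sigma_r))
  lam <- pixel_wavelengths(spec$spectrometer)
  bg <- simulate_fringe(phantom(), spec, noise = FALSE, oversample = 1)
  cal <- calibration_set(as.numeric(bg), build_k_mapping(lam), lam)
  ph <- mirror_phantom(300, r = 0.02)
  fr0 <- simulate_fringe(ph, spec, noise = FALSE, oversample = 1)
  peak0 <- max(Mod(reconstruct_ascan(as.numeric(fr0), cal,
                                     window = "rect")$values[-(1:4)]))
  predicted <- 20 * log10(peak0 / (sigma_r * sqrt(2) * sqrt((4 - pi) / 2)))
  nz <- n / 2
  hits <- 0L
  for (s in 1:12) {
    fr <- simulate_fringe(ph, spec, seed = s, oversample = 1,
                          shot_noise = FALSE)   # known read noise only
    asc <- reconstruct_ascan(as.numeric(fr), cal, window = "rect")
    snr <- measure_snr(asc, c(as.integer(nz * 0.6), nz))
    if (abs(snr - predicted) <= 1) hits <- hits + 1L
  }
  expect_gte(hits, 10)                 # ~95% of seeds within 1 dB
})

test_that("SNR scales by +20 dB per tenfold reflectivity", {
  spec <- test_spec(read_noise = 8)
  cal <- ideal_cal(spec)
  nz <- spec$spectrometer$n_pixels / 2
  region <- c(as.integer(nz * 0.6), nz)
  snrs <- vapply(c(0.002, 0.02), function(r) {
    fr <- simulate_fringe(mirror_phantom(150, r = r), spec, seed = 21,
                          shot_noise = FALSE)   # signal-independent floor
    measure_snr(reconstruct_ascan(as.numeric(fr), cal, window = "rect"),
                region)
  }, 0)
  expect_lt(abs((snrs[2] - snrs[1]) - 20), 1)
})

test_that("noiseless input is flagged as infinite SNR and regions are
          validated", {
  mag <- rep(0, 256); mag[30] <- 1
  asc <- synthetic_ascan(mag)
  snr <- measure_snr(asc, c(150, 250))
  expect_true(is.infinite(snr))
  expect_true(isTRUE(attr(snr, "noiseless")))
  expect_error(measure_snr(asc, c(25, 45)), "exclude the peak")
  expect_error(measure_snr(asc, c(0, 40)), "invalid noise region")
})

test_that("full-loop parameter recovery over random (z, r, a2) triples", {
  cal_base <- ideal_cal(test_spec())
  pitch <- sdoct:::depth_pitch_um(test_spec()$spectrometer)
  withr::with_seed(17, {
    for (trial in 1:10) {
      zs <- sort(runif(2, 100, 0.8 * zmax_um(test_spec())))
      while (diff(zs) < 60) zs[2] <- runif(1, 100, 0.8 * zmax_um(test_spec()))
      rs <- sample(c(0.06, 0.02))
      a2 <- runif(1, 2, 10)
      spec_d <- test_spec(dispersion = dispersion_model(a2))
      # calibrate on a dedicated mirror fringe, then reconstruct the pair
      frm <- simulate_fringe(mirror_phantom(250), spec_d, noise = FALSE)
      est <- estimate_dispersion_phase(as.numeric(frm), cal_base)
      expect_lt(abs(est$coefficients[["a2"]] - a2) / a2, 0.05)
      cal <- cal_base
      cal$dispersion_phase <- est$phase
      ph <- phantom(reflectors = data.frame(z_um = zs, r = rs))
      fr <- simulate_fringe(ph, spec_d, noise = FALSE)
      asc <- reconstruct_ascan(as.numeric(fr), cal, window = "rect", pad = 4)
      mag <- Mod(asc$values)
      zbins <- (seq_along(mag) - 1) * asc$pitch_um
      depths_hat <- peaks <- numeric(2)
      for (j in 1:2) {
        i <- which(abs(zbins - zs[j]) < 40)
        peaks[j] <- max(mag[i])
        depths_hat[j] <- zbins[i][which.max(mag[i])]
      }
      expect_true(all(abs(depths_hat - zs) <= pitch / 2))
      expect_equal(order(peaks), order(rs))     # amplitude rank preserved
    }
  })
})

test_that("performance reports are deterministic and self-consistent", {
  spec <- test_spec(blur_fwhm = 0.52, read_noise = 10,
                    n_pixels = 512)
  r1 <- performance_report(spec, seed = 5)
  r2 <- performance_report(spec, seed = 5)
  r1$rolloff_curve <- r2$rolloff_curve <- NULL
  expect_identical(unclass(r1), unclass(r2))
  expect_equal(r1$axial_fwhm_tissue_um, r1$axial_fwhm_air_um / 1.4)
  expect_equal(r1$axial_fwhm_tissue149_um, r1$axial_fwhm_air_um / 1.49)
  r3 <- performance_report(spec, seed = 5)
  expect_identical(r3$rolloff_curve, performance_report(spec, seed = 5)$rolloff_curve)
  expect_lte(r1$falloff_6db_mm, max_imaging_depth(spec$spectrometer))
  expect_true(is.finite(r1$snr_db))
})
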