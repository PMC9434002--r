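test_that("reconstruction is linear and zero maps to zero", {
  spec <- test_spec()
  n <- spec$spectrometer$n_pixels
  lam <- pixel_wavelengths(spec$spectrometer)
  cal0 <- calibration_set(rep(0, n), build_k_mapping(lam), lam)
  z <- reconstruct_ascan(rep(0, n), cal0, window = "hann")
  expect_true(all(Mod(z$values) == 0))
  # scaling the fringe scales every magnitude (zero background)
  fr <- as.numeric(simulate_fringe(mirror_phantom(250), spec, noise = FALSE))
  a1 <- reconstruct_ascan(fr, cal0)
  a3 <- reconstruct_ascan(3 * fr, cal0)
  expect_equal(Mod(a3$values), 3 * Mod(a1$values), tolerance = 1e-12)
  expect_error(reconstruct_ascan(fr[-1], cal0), "length")
  expect_error(reconstruct_ascan(replace(fr, 3, NA), cal0), "NA")
})

test_that("a noiseless mirror PSF matches the Gaussian closed form", {
  spec <- test_spec(n_pixels = 2048)
  cal <- ideal_cal(spec)
  asc <- mirror_ascan(spec, cal, 500)
  expect_lt(abs(measure_peak_depth(asc) - 500),
            sdoct:::depth_pitch_um(spec$spectrometer) / 2)
  fwhm <- measure_psf_fwhm(asc)
  expect_lt(abs(fwhm - axial_resolution_theory(850, 100)) /
              axial_resolution_theory(850, 100), 0.10)
})

test_that("A-scan contract: one-sided length and depth pitch", {
  spec <- test_spec()
  cal <- ideal_cal(spec)
  n <- spec$spectrometer$n_pixels
  asc <- mirror_ascan(spec, cal, 200, pad = 1)
  expect_length(asc$values, n / 2)
  expect_equal(asc$pitch_um,
               max_imaging_depth(spec$spectrometer) * 1000 / (n / 2))
  # the last alias-free bin sits within one pixel of the Nyquist depth
  expect_lt(abs((n / 2) * asc$pitch_um - zmax_um(spec)), asc$pitch_um)
})

test_that("volume reconstruction maps columns independently", {
  spec <- test_spec()
  cal <- ideal_cal(spec)
  tl <- simulate_tile(mirror_phantom(220), spec, seed = 1, noise = FALSE,
                      bscans = 3, alines = 5)$tile
  vol <- reconstruct_volume(tl, cal, tile_fov = spec$tile_fov)
  n <- spec$spectrometer$n_pixels
  expect_equal(dim(vol$magnitude), c(3, 5, n / 2))
  # identical raw columns give identical A-scans
  for (b in 2:3) expect_equal(vol$magnitude[b, , ], vol$magnitude[1, , ])
  # quadrant-footprint tile: depth map matches truth in every covered column
  ph <- phantom(reflectors = data.frame(z_um = 330, r = 0.05,
                                        bscan_min = 1, bscan_max = 2,
                                        aline_min = 2, aline_max = 4))
  tl2 <- simulate_tile(ph, spec, seed = 1, noise = FALSE, bscans = 3,
                       alines = 5)$tile
  vol2 <- reconstruct_volume(tl2, cal, window = "rect")
  pitch <- vol2$pitch$z_um
  for (b in 1:2) for (a in 2:4) {
    ipk <- which.max(vol2$magnitude[b, a, -(1:4)]) + 4
    expect_lt(abs((ipk - 1) * pitch - 330), pitch)
  }
})

test_that("the five steps run in canonical order (golden regression)", {
  spec <- test_spec(dispersion = dispersion_model(6))
  cal <- ideal_cal(spec)
  fr <- as.numeric(simulate_fringe(mirror_phantom(260), spec, seed = 42))
  est <- estimate_dispersion_phase(fr, cal)
  cal$dispersion_phase <- est$phase
  asc <- reconstruct_ascan(fr, cal, window = "hann")
  mag <- Mod(asc$values)
  # frozen from a reference run of the canonical order
  expect_equal(which.max(mag), 136)
  expect_equal(max(mag) / sum(mag), 0.110241051, tolerance = 1e-6)
  # permuting steps (apodize before resampling) changes the output
  w <- sdoct:::apod_window("hann", length(fr))
  asc_perm <- reconstruct_ascan((fr - cal$background) * w +
                                  cal$background, cal, window = "rect")
  expect_gt(max(abs(Mod(asc_perm$values) - mag)), 1e-3 * max(mag))
})

test_that("windowed spectral energy equals A-scan energy (Parseval)", {
  spec <- test_spec()
  cal <- ideal_cal(spec)
  fr <- as.numeric(simulate_fringe(mirror_phantom(180), spec, seed = 7))
  asc <- reconstruct_ascan(fr, cal, window = "hann")
  # independent analytic signal: one-sided spectrum assembled by hand
  x <- sdoct:::to_ascending_k(
    sdoct:::resample_at(fr - cal$background, cal$k_map, "cubic"), cal)
  xw <- x * sdoct:::apod_window("hann", length(x))
  X <- fft(xw)
  n <- length(xw)
  X[(n / 2 + 1):n] <- 0                # positive-depth bins only
  X[2:(n / 2)] <- 2 * X[2:(n / 2)]
  a_ind <- fft(X, inverse = TRUE) / n
  expect_equal(sum(Mod(asc$values)^2), sum(Mod(a_ind)^2),
               tolerance = 1e-10)
})

test_that("apodization trades side lobes for main-lobe width", {
  # flat-top source filling the whole detected span, on a uniform-k
  # spectrometer: the apodization window alone shapes the PSF, so window
  # theory applies directly
  n <- 512
  k <- seq(2000 * pi / 930, 2000 * pi / 750, length.out = n)
  spec <- system_spec(
    source = source_spectrum(840, 180, shape = "flat_top"),
    spectrometer = spectrometer_model(n_pixels = n,
                                      lambda_of_pixel = 2000 * pi / rev(k),
                                      blur_fwhm = 0))
  cal <- ideal_cal(spec)
  asc_h <- mirror_ascan(spec, cal, 250, window = "hann", oversample = 1)
  asc_r <- mirror_ascan(spec, cal, 250, window = "rect", oversample = 1)
  expect_lt(measure_psf_fwhm(asc_r), measure_psf_fwhm(asc_h))
  mag <- Mod(asc_h$values)
  ipk <- which.max(mag)
  # first local minima bracket the main lobe; beyond them: side lobes
  right <- ipk + which(diff(mag[ipk:length(mag)]) > 0)[1] - 1
  left <- ipk - which(diff(rev(mag[1:ipk])) > 0)[1] + 1
  side <- max(mag[c(5:left, right:length(mag))])
  expect_lte(20 * log10(side / mag[ipk]), -31)
})

test_that("log compression normalizes, clips, and handles zero volumes", {
  v <- array(c(10, 1, 0.001, 0.1), dim = c(1, 2, 2))
  db <- log_compress(v, dynamic_range = 40)
  expect_equal(max(db), 0)                 # global maximum at 0 dB
  expect_equal(db[1, 2, 1], -20)           # magnitude = max/10 -> -20 dB
  expect_equal(db[1, 1, 2], -40)           # below floor -> clipped
  expect_error(log_compress(v, dynamic_range = 0), "> 0")
  z <- log_compress(array(0, dim = c(2, 2, 2)), 60)
  expect_true(all(z == -60))
})
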