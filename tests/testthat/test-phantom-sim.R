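test_that("empty phantom with zero noise is the pure reference background", {
  spec <- test_spec()
  sp <- spec$spectrometer
  fr <- simulate_fringe(phantom(), spec, noise = FALSE, oversample = 1)
  lam <- pixel_wavelengths(sp)
  s_abs <- sp$full_well * exp(-4 * log(2) * ((lam - 850) / 100)^2)
  expect_equal(as.numeric(fr), 0.9 * s_abs, tolerance = 1e-12)
  expect_false(attr(fr, "saturated"))
})

test_that("a noiseless mirror reconstructs at its true depth", {
  spec <- test_spec()
  cal <- ideal_cal(spec)
  asc <- mirror_ascan(spec, cal, z_um = 300)
  pitch_native <- asc$pitch_um * asc$pad
  expect_lt(abs(measure_peak_depth(asc) - 300), pitch_native / 2)
})

test_that("two mirrors with 2:1 amplitudes reconstruct in 2:1 ratio", {
  spec <- test_spec()
  cal <- ideal_cal(spec)
  ph <- phantom(reflectors = data.frame(z_um = c(120, 260),
                                        r = c(0.06, 0.03)))
  # point sampling: no pixel-integration roll-off between the two depths
  fr <- simulate_fringe(ph, spec, noise = FALSE, oversample = 1)
  asc <- reconstruct_ascan(as.numeric(fr), cal, window = "rect", pad = 4)
  mag <- Mod(asc$values)
  z <- (seq_along(mag) - 1) * asc$pitch_um
  p1 <- max(mag[abs(z - 120) < 20])
  p2 <- max(mag[abs(z - 260) < 20])
  expect_lt(abs(p1 / p2 - 2), 0.02 * 2)
})

test_that("tile simulation is bit-identical for the same seed", {
  spec <- test_spec()
  ph <- mirror_phantom(200)
  t1 <- simulate_tile(ph, spec, seed = 11, bscans = 3, alines = 6,
                      n_reference = 4)
  t2 <- simulate_tile(ph, spec, seed = 11, bscans = 3, alines = 6,
                      n_reference = 4)
  expect_identical(t1$tile$counts, t2$tile$counts)
  expect_identical(t1$tile$reference, t2$tile$reference)
  t3 <- simulate_tile(ph, spec, seed = 12, bscans = 3, alines = 6,
                      n_reference = 4)
  expect_false(identical(t1$tile$counts, t3$tile$counts))
})

test_that("reflector footprints are local: only covered columns differ", {
  spec <- test_spec()
  ph <- phantom(reflectors = data.frame(z_um = 200, r = 0.05,
                                        bscan_min = 5, bscan_max = 5,
                                        aline_min = 10, aline_max = 20))
  tl <- simulate_tile(ph, spec, seed = 1, noise = FALSE, bscans = 6,
                      alines = 24)$tile
  bg <- simulate_tile(phantom(), spec, seed = 1, noise = FALSE, bscans = 6,
                      alines = 24)$tile
  d <- abs(tl$counts - bg$counts)
  differs <- apply(d, c(1, 2), max) > 1e-9
  want <- matrix(FALSE, 6, 24)
  want[5, 10:20] <- TRUE
  expect_identical(differs, want)
})

test_that("shot-noise variance scales linearly with mean counts", {
  # read noise off; variance of repeated background pixels ~ mean counts
  spec <- test_spec(read_noise = 0)
  tl <- simulate_tile(phantom(), spec, seed = 42, bscans = 1, alines = 1,
                      n_reference = 300)$tile
  m <- colMeans(tl$reference)
  v <- apply(tl$reference, 2, stats::var)
  keep <- m > 50                       # avoid the clipped-at-zero tails
  fit <- stats::lm(v[keep] ~ m[keep])
  expect_lt(abs(stats::coef(fit)[2] - 1), 0.1)
})

test_that("counts clip at full well and raise the saturation flag", {
  spec <- test_spec()
  spec$source$power_scale <- 3
  fr <- simulate_fringe(mirror_phantom(100, r = 0.3), spec, seed = 1)
  expect_true(all(fr <= spec$spectrometer$full_well))
  expect_true(attr(fr, "saturated"))
})

test_that("layered scattering medium raises magnitude inside the layer", {
  spec <- test_spec()
  cal <- ideal_cal(spec)
  lay <- data.frame(top_um = 150, thickness_um = 150, density = 0.5,
                    mean_amp = 0.03, amp_spread = 0.01)
  tl <- simulate_tile(phantom(layers = lay), spec, seed = 5, bscans = 1,
                      alines = 16)$tile
  vol <- reconstruct_volume(tl, cal, window = "hann")
  z <- (seq_len(dim(vol$magnitude)[3]) - 1) * vol$pitch$z_um
  inside <- mean(vol$magnitude[, , z > 160 & z < 290])
  outside <- mean(vol$magnitude[, , z > 320 & z < 450])
  expect_gt(inside, outside)
})

test_that("reflectors beyond the Nyquist depth error unless allowed", {
  spec <- test_spec()
  deep <- zmax_um(spec) + 50
  expect_error(simulate_fringe(mirror_phantom(deep), spec, noise = FALSE),
               "Nyquist")
  expect_warning(simulate_fringe(mirror_phantom(deep), spec, noise = FALSE,
                                 allow_aliasing = TRUE), "alias")
})

test_that("autocorrelation terms appear only when enabled", {
  spec <- test_spec()
  cal <- ideal_cal(spec)
  ph <- phantom(reflectors = data.frame(z_um = c(250, 330), r = 0.15))
  rec <- function(auto) {
    fr <- simulate_fringe(ph, spec, noise = FALSE,
                          include_autocorrelation = auto)
    Mod(reconstruct_ascan(as.numeric(fr), cal, window = "rect")$values)
  }
  pitch <- sdoct:::depth_pitch_um(spec$spectrometer)
  bin_ac <- round(80 / pitch) + 1      # z1 - z2 = 80 um
  expect_gt(rec(TRUE)[bin_ac] / rec(FALSE)[bin_ac], 10)
})

test_that("phantom validation rejects bad geometry", {
  expect_error(phantom(reflectors = data.frame(z_um = -1, r = 0.5)), ">= 0")
  expect_error(phantom(reflectors = data.frame(z_um = 1, r = 1.5)), "0, 1")
  expect_error(phantom(layers = data.frame(top_um = c(0, 50),
                                           thickness_um = c(100, 10),
                                           density = 1, mean_amp = 0.1,
                                           amp_spread = 0)), "overlap")
})

test_that("cassette datasets honor the plan and per-quadrant truth", {
  spec <- test_spec(tile_fov = c(2, 2))
  plan <- plan_snake_scan(4, 4, tile_fov = c(2, 2), overlap = 0)
  depths <- c(100, 200, 300, 400)
  rf <- data.frame(z_um = depths, r = 0.05,
                   x_min = c(0, 2, 0, 2) + 0.5, x_max = c(0, 2, 0, 2) + 1.5,
                   y_min = c(0, 0, 2, 2) + 0.5, y_max = c(0, 0, 2, 2) + 1.5)
  ds <- generate_cassette_dataset(cassette_phantom(rf), spec, plan,
                                  seed = 3, bscans = 4, alines = 8,
                                  noise = FALSE)
  expect_length(ds$tiles, 4)
  cal <- ideal_cal(spec)
  for (t in ds$tiles) {
    idx <- t$tile$tile_index
    want_z <- depths[(idx[1] - 1) * 2 + idx[2]]
    mid <- t$tile$counts[2, 4, ]
    asc <- reconstruct_ascan(mid, cal, window = "rect", pad = 4)
    expect_lt(abs(measure_peak_depth(asc) - want_z),
              sdoct:::depth_pitch_um(spec$spectrometer) / 2)
  }
  # degenerate 1x1 plan equals a single simulate_tile with the derived seed
  plan1 <- plan_snake_scan(2, 2, tile_fov = c(2, 2), overlap = 0)
  rf1 <- rf[1, ]
  ds1 <- generate_cassette_dataset(cassette_phantom(rf1), spec, plan1,
                                   seed = 9, bscans = 4, alines = 8)
  expect_length(ds1$tiles, 1)
  ph1 <- phantom(reflectors = data.frame(z_um = 100, r = 0.05,
                                         bscan_min = 2, bscan_max = 3,
                                         aline_min = 3, aline_max = 6))
  ref <- simulate_tile(ph1, spec, seed = sdoct:::derive_seeds(9, 1),
                       bscans = 4, alines = 8)
  expect_identical(ds1$tiles[[1]]$tile$counts, ref$tile$counts)
  # phantom extent must fit the plan
  expect_error(generate_cassette_dataset(cassette_phantom(rf), spec, plan1,
                                         seed = 1, bscans = 2, alines = 2),
               "extent")
})
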