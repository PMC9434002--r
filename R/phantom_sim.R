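# Phantom definitions and raw-fringe simulation.
#
# The simulator synthesizes the standard SD-OCT interference spectrum on an
# oversampled wavelength grid, applies Gaussian spectral blur, integrates
# over each camera pixel (boxcar), then adds shot noise (Gaussian,
# variance = counts), read noise, and quantization to the camera full well.

#' Reflector / layered phantom (per-tile coordinates)
#'
#' @param reflectors `data.frame` with columns `z_um` (single-pass optical
#'   depth, um), `r` (amplitude reflectivity in `[0, 1]`) and optional
#'   footprint columns `bscan_min`, `bscan_max`, `aline_min`, `aline_max`
#'   (1-based indices; `NA` = whole tile).
#' @param layers Optional `data.frame` describing scattering slabs:
#'   `top_um`, `thickness_um`, `density` (mean scatterers per depth voxel),
#'   `mean_amp`, `amp_spread` (amplitude mean and spread). Layers must be
#'   depth-ordered and non-overlapping.
#' @param refractive_index Phantom group index (informational; depths are
#'   already optical path).
#' @return An object of class `phantom`.
#' @export
phantom <- function(reflectors = NULL, layers = NULL, refractive_index = 1.4) {
  if (!is.null(reflectors)) {
    stopifnot(is.data.frame(reflectors),
              all(c("z_um", "r") %in% names(reflectors)))
    if (any(reflectors$z_um < 0)) stop("reflector depths must be >= 0")
    if (any(reflectors$r < 0 | reflectors$r > 1))
      stop("reflectivity r must be in [0, 1]")
    for (col in c("bscan_min", "bscan_max", "aline_min", "aline_max"))
      if (!col %in% names(reflectors)) reflectors[[col]] <- NA_integer_
  }
  if (!is.null(layers)) {
    stopifnot(is.data.frame(layers),
              all(c("top_um", "thickness_um", "density",
                    "mean_amp", "amp_spread") %in% names(layers)))
    if (nrow(layers) > 1) {
      o <- order(layers$top_um)
      if (!identical(o, seq_len(nrow(layers))))
        stop("layers must be depth-ordered")
      bot <- layers$top_um + layers$thickness_um
      if (any(layers$top_um[-1] < bot[-nrow(layers)]))
        stop("layers must not overlap")
    }
  }
  structure(list(reflectors = reflectors, layers = layers,
                 refractive_index = refractive_index),
            class = "phantom")
}

#' Cassette-level phantom (global millimeter coordinates)
#'
#' Describes reflectors over the whole specimen extent; lateral footprints
#' are axis-aligned boxes in mm. [generate_cassette_dataset()] converts
#' them to per-tile [phantom()] footprints using the scan plan geometry.
#'
#' @param reflectors `data.frame` with columns `z_um`, `r`, `x_min`,
#'   `x_max`, `y_min`, `y_max` (mm; x rightward, y upward from the
#'   lower-left corner of the scanned extent).
#' @param refractive_index Group index (informational).
#' @return An object of class `cassette_phantom`.
#' @export
cassette_phantom <- function(reflectors, refractive_index = 1.4) {
  stopifnot(is.data.frame(reflectors),
            all(c("z_um", "r", "x_min", "x_max", "y_min", "y_max") %in%
                  names(reflectors)))
  if (any(reflectors$z_um < 0)) stop("reflector depths must be >= 0")
  if (any(reflectors$r < 0 | reflectors$r > 1))
    stop("reflectivity r must be in [0, 1]")
  structure(list(reflectors = reflectors, refractive_index = refractive_index),
            class = "cassette_phantom")
}

# Oversampled wavelength grid: `oversample` subsamples per pixel, centered
# on the pixel wavelength, spanning the local pixel pitch (boxcar support).
fine_lambda_grid <- function(spectrometer, oversample) {
  lam <- spectrometer$lambda_of_pixel
  n <- spectrometer$n_pixels
  if (oversample <= 1) return(list(lambda = lam, per_pixel = 1L))
  pitch <- c(diff(lam)[1], diff(lam))
  off <- (seq_len(oversample) - 0.5) / oversample - 0.5
  fine <- as.vector(t(outer(lam, rep(1, oversample)) + outer(pitch, off)))
  list(lambda = fine, per_pixel = as.integer(oversample))
}

# Noiseless detected counts for one column: evaluates the interference
# spectrum on the fine grid, blurs, and integrates per pixel.
ideal_spectrum <- function(reflector_z, reflector_r, spec, rho_r,
                           oversample, reference_only = FALSE,
                           include_autocorrelation = FALSE,
                           extra_phase = NULL) {
  sp <- spec$spectrometer
  fg <- fine_lambda_grid(sp, oversample)
  k <- 2000 * pi / fg$lambda
  s_env <- source_envelope(spec$source, sp, fg$lambda)
  s_abs <- spec$source$power_scale * sp$full_well * s_env
  mod <- rho_r
  if (!reference_only && length(reflector_z)) {
    k0 <- sum(range(pixel_wavenumbers(sp))) / 2
    phi <- dispersion_phase_at(spec$dispersion, k, k0)
    for (i in seq_along(reflector_z)) {
      ph_i <- 2 * k * reflector_z[i] + phi
      if (!is.null(extra_phase)) ph_i <- ph_i + extra_phase[i]
      mod <- mod + 2 * sqrt(rho_r) * reflector_r[i] * cos(ph_i)
    }
    if (include_autocorrelation && length(reflector_z) > 1) {
      for (i in seq_len(length(reflector_z) - 1))
        for (j in (i + 1):length(reflector_z))
          mod <- mod + 2 * reflector_r[i] * reflector_r[j] *
            cos(2 * k * (reflector_z[i] - reflector_z[j]))
    }
  }
  x <- s_abs * mod
  if (sp$blur_fwhm > 0) {
    pitch_nm <- mean(abs(diff(fg$lambda)))
    sigma_samp <- sp$blur_fwhm / (2 * sqrt(2 * log(2))) / pitch_nm
    x <- gaussian_smooth(x, sigma_samp)
  }
  if (fg$per_pixel > 1)
    x <- colMeans(matrix(x, nrow = fg$per_pixel))
  x
}

# Shot noise, read noise and quantization for a counts matrix [N x ncol].
apply_camera_noise <- function(counts, spectrometer, shot_noise = TRUE,
                               read_noise = TRUE, quantize = TRUE) {
  n <- length(counts)
  if (shot_noise)
    counts <- counts + stats::rnorm(n, sd = sqrt(pmax(counts, 0)))
  if (read_noise && spectrometer$read_noise > 0)
    counts <- counts + stats::rnorm(n, sd = spectrometer$read_noise)
  saturated <- FALSE
  if (quantize) {
    counts <- round(counts)
    saturated <- any(counts > spectrometer$full_well)
    counts[counts > spectrometer$full_well] <- spectrometer$full_well
    counts[counts < 0] <- 0
  }
  list(counts = counts, saturated = saturated)
}

# Reflectors of a per-tile phantom visible in column (bscan, aline).
reflectors_in_column <- function(phantom, bscan, aline) {
  rf <- phantom$reflectors
  if (is.null(rf) || !nrow(rf)) return(rf)
  keep <- (is.na(rf$bscan_min) | bscan >= rf$bscan_min) &
    (is.na(rf$bscan_max) | bscan <= rf$bscan_max) &
    (is.na(rf$aline_min) | aline >= rf$aline_min) &
    (is.na(rf$aline_max) | aline <= rf$aline_max)
  rf[keep, , drop = FALSE]
}

# Draw layer scatterers for one column from the current RNG stream.
draw_layer_scatterers <- function(layers, spectrometer) {
  pitch <- depth_pitch_um(spectrometer)
  zs <- numeric(0); rs <- numeric(0); ph <- numeric(0)
  for (i in seq_len(nrow(layers))) {
    lay <- layers[i, ]
    n_sc <- stats::rpois(1, lay$density * lay$thickness_um / pitch)
    if (n_sc == 0) next
    zs <- c(zs, stats::runif(n_sc, lay$top_um, lay$top_um + lay$thickness_um))
    rs <- c(rs, pmin(abs(stats::rnorm(n_sc, lay$mean_amp, lay$amp_spread)), 1))
    ph <- c(ph, stats::runif(n_sc, 0, 2 * pi))
  }
  list(z = zs, r = rs, phase = ph)
}

check_depths_alias_free <- function(z_um, spectrometer, allow_aliasing) {
  zmax <- max_imaging_depth(spectrometer) * 1000
  if (any(z_um > zmax)) {
    if (!allow_aliasing)
      stop(sprintf("reflector beyond Nyquist depth (%.1f um > %.1f um); ",
                   max(z_um), zmax),
           "set allow_aliasing = TRUE to synthesize anyway")
    warning("reflector beyond Nyquist depth: synthesis will alias")
  }
}

#' Simulate one raw spectral fringe
#'
#' Detected camera counts for a single A-line of a [phantom()] under a
#' [system_spec()]: `S(p) * (rho_r + sum_i 2 sqrt(rho_r) r_i cos(2 k z_i +
#' phi_d(k)))` sampled on the pixel grid, followed by spectral blur, pixel
#' boxcar integration, shot noise (variance = counts), read noise, and
#' quantization.
#'
#' @param phantom A [phantom()].
#' @param spec A [system_spec()].
#' @param bscan,aline Column position (1-based), used to resolve reflector
#'   footprints.
#' @param seed Optional seed for this fringe's noise (caller RNG restored).
#' @param noise Logical master switch: apply the camera noise model.
#' @param shot_noise,read_noise,quantize Individual stages of the camera
#'   model (all default on when `noise = TRUE`): shot noise (Gaussian,
#'   variance = counts), read noise (sigma from the spectrometer model),
#'   rounding + clipping to the full well.
#' @param oversample Subsamples per pixel for blur/boxcar synthesis
#'   (1 = point sampling, no pixel integration).
#' @param rho_r Reference-arm power fraction (default 0.9: background peaks
#'   at 0.9 of full well for `power_scale = 1`).
#' @param reference_only Synthesize a shutter reference frame (no sample
#'   light).
#' @param allow_aliasing Permit reflectors beyond the Nyquist depth
#'   (warning + aliased synthesis) instead of an error.
#' @param include_autocorrelation Add sample-sample interference terms.
#' @return Numeric vector of `n_pixels` counts with attribute `saturated`.
#' @export
simulate_fringe <- function(phantom, spec, bscan = 1, aline = 1, seed = NULL,
                            noise = TRUE, oversample = 8, rho_r = 0.9,
                            reference_only = FALSE, allow_aliasing = FALSE,
                            include_autocorrelation = FALSE,
                            shot_noise = TRUE, read_noise = TRUE,
                            quantize = TRUE) {
  stopifnot(inherits(phantom, "phantom"), inherits(spec, "system_spec"))
  with_seed(seed, {
    rf <- if (reference_only) NULL else reflectors_in_column(phantom, bscan, aline)
    z <- if (is.null(rf)) numeric(0) else rf$z_um
    r <- if (is.null(rf)) numeric(0) else rf$r
    extra <- rep(0, length(z))
    if (!reference_only && !is.null(phantom$layers)) {
      sc <- draw_layer_scatterers(phantom$layers, spec$spectrometer)
      z <- c(z, sc$z); r <- c(r, sc$r); extra <- c(extra, sc$phase)
    }
    if (length(z)) check_depths_alias_free(z, spec$spectrometer, allow_aliasing)
    x <- ideal_spectrum(z, r, spec, rho_r, oversample,
                        reference_only = reference_only && !length(z),
                        include_autocorrelation = include_autocorrelation,
                        extra_phase = extra)
    if (noise) {
      res <- apply_camera_noise(x, spec$spectrometer,
                                shot_noise = shot_noise,
                                read_noise = read_noise,
                                quantize = quantize)
      structure(res$counts, saturated = res$saturated)
    } else structure(x, saturated = FALSE)
  })
}

#' Simulate one tile volume with ground truth
#'
#' Rasters [simulate_fringe()] over all B-scan x A-line columns of a tile
#' and appends shutter reference frames. Deterministic for a given seed.
#'
#' @inheritParams simulate_fringe
#' @param stage_xy Stage position of the tile's lower-left corner, mm.
#' @param tile_index `c(row, col)`, 1-based, row 1 = bottom.
#' @param seed Seed for the tile's noise/scatterer stream.
#' @param n_reference Number of shutter reference frames to append.
#' @param bscans,alines Tile raster size; defaults from `spec`.
#' @return A list with elements `tile` (class `raw_tile`: `counts[B, A, N]`,
#'   `reference[n_reference, N]`, stage position, tile index, seed,
#'   saturation flag) and `truth` (class `ground_truth`: reflector table,
#'   true dispersion coefficients, true background spectrum, seed).
#' @export
simulate_tile <- function(phantom, spec, stage_xy = c(0, 0),
                          tile_index = c(1L, 1L), seed = 1L,
                          n_reference = 20, noise = TRUE, oversample = 8,
                          rho_r = 0.9, allow_aliasing = FALSE,
                          include_autocorrelation = FALSE,
                          bscans = NULL, alines = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(spec, "system_spec"))
  B <- as.integer(bscans %||% spec$bscans_per_volume)
  A <- as.integer(alines %||% spec$a_lines_per_bscan)
  N <- spec$spectrometer$n_pixels
  has_layers <- !is.null(phantom$layers)

  counts <- with_seed(seed, {
    cnt <- matrix(0, nrow = N, ncol = B * A)
    cache <- new.env(parent = emptyenv())
    col <- 0L
    for (b in seq_len(B)) for (a in seq_len(A)) {
      col <- col + 1L
      rf <- reflectors_in_column(phantom, b, a)
      z <- if (is.null(rf)) numeric(0) else rf$z_um
      r <- if (is.null(rf)) numeric(0) else rf$r
      extra <- rep(0, length(z))
      if (has_layers) {
        sc <- draw_layer_scatterers(phantom$layers, spec$spectrometer)
        z <- c(z, sc$z); r <- c(r, sc$r); extra <- c(extra, sc$phase)
      }
      if (length(z))
        check_depths_alias_free(z, spec$spectrometer, allow_aliasing)
      key <- paste0("k", paste(format(c(z, r, extra), digits = 12),
                               collapse = ","))
      if (!has_layers && !is.null(cache[[key]])) {
        cnt[, col] <- cache[[key]]
      } else {
        v <- ideal_spectrum(z, r, spec, rho_r, oversample,
                            reference_only = !length(z),
                            include_autocorrelation = include_autocorrelation,
                            extra_phase = extra)
        if (!has_layers) cache[[key]] <- v
        cnt[, col] <- v
      }
    }
    ref <- matrix(rep(ideal_spectrum(numeric(0), numeric(0), spec, rho_r,
                                     oversample, reference_only = TRUE),
                      n_reference), nrow = N)
    saturated <- FALSE
    if (noise) {
      rs <- apply_camera_noise(cnt, spec$spectrometer)
      cnt <- rs$counts
      rr <- apply_camera_noise(ref, spec$spectrometer)
      ref <- rr$counts
      saturated <- rs$saturated || rr$saturated
    }
    list(cnt = cnt, ref = ref, saturated = saturated)
  })

  arr <- array(0, dim = c(B, A, N))
  col <- 0L
  for (b in seq_len(B)) for (a in seq_len(A)) {
    col <- col + 1L
    arr[b, a, ] <- counts$cnt[, col]
  }
  bg_true <- ideal_spectrum(numeric(0), numeric(0), spec, rho_r, oversample,
                            reference_only = TRUE)
  tile <- structure(list(counts = arr, reference = t(counts$ref),
                         stage_xy = as.numeric(stage_xy),
                         tile_index = as.integer(tile_index),
                         seed = seed, saturated = counts$saturated,
                         rho_r = rho_r),
                    class = "raw_tile")
  truth <- structure(list(reflectors = phantom$reflectors,
                          layers = phantom$layers,
                          dispersion = spec$dispersion,
                          background = bg_true, seed = seed),
                     class = "ground_truth")
  list(tile = tile, truth = truth)
}

#' @export
print.raw_tile <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "raw tile [%d B-scans x %d A-lines x %d px], tile (%d,%d), stage (%g, %g) mm%s\n",
    d[1], d[2], d[3], x$tile_index[1], x$tile_index[2],
    x$stage_xy[1], x$stage_xy[2], if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Simulate a full serpentine cassette dataset
#'
#' Generates one raw tile per scan-plan cell from a [cassette_phantom()],
#' with per-tile seeds derived from one global seed and a ground-truth
#' reflector table in stitched (global) coordinates.
#'
#' @param phantom A [cassette_phantom()].
#' @param spec A [system_spec()].
#' @param plan A [plan_snake_scan()] covering the phantom extent.
#' @param seed Global seed; per-tile streams are derived from it.
#' @param bscans,alines Tile raster size; defaults from `spec`.
#' @param ... Passed to [simulate_tile()].
#' @return List with `tiles` (list of `simulate_tile()` results in visit
#'   order), `truth_global` (reflector table in mm + depth um), `plan`,
#'   `seed`.
#' @export
generate_cassette_dataset <- function(phantom, spec, plan, seed = 1L,
                                      bscans = NULL, alines = NULL, ...) {
  stopifnot(inherits(phantom, "cassette_phantom"),
            inherits(plan, "scan_plan"))
  rf <- phantom$reflectors
  if (nrow(rf)) {
    if (any(rf$x_min < 0) || any(rf$y_min < 0) ||
        any(rf$x_max > plan$width_mm) || any(rf$y_max > plan$height_mm))
      stop("phantom extent exceeds scan plan extent")
  }
  B <- as.integer(bscans %||% spec$bscans_per_volume)
  A <- as.integer(alines %||% spec$a_lines_per_bscan)
  fov <- plan$tile_fov
  stride <- fov - plan$overlap
  seeds <- derive_seeds(seed, nrow(plan$order))
  tiles <- vector("list", nrow(plan$order))
  for (i in seq_len(nrow(plan$order))) {
    r <- plan$order$row[i]; c <- plan$order$col[i]
    x0 <- (c - 1) * stride[1]; y0 <- (r - 1) * stride[2]
    xa <- x0 + (seq_len(A) - 0.5) * fov[1] / A   # A-line centers, mm
    yb <- y0 + (seq_len(B) - 0.5) * fov[2] / B   # B-scan centers, mm
    loc <- NULL
    for (j in seq_len(nrow(rf))) {
      ai <- which(xa >= rf$x_min[j] & xa <= rf$x_max[j])
      bi <- which(yb >= rf$y_min[j] & yb <= rf$y_max[j])
      if (!length(ai) || !length(bi)) next
      loc <- rbind(loc, data.frame(
        z_um = rf$z_um[j], r = rf$r[j],
        bscan_min = min(bi), bscan_max = max(bi),
        aline_min = min(ai), aline_max = max(ai)))
    }
    ph <- phantom(reflectors = loc,
                  refractive_index = phantom$refractive_index)
    tiles[[i]] <- simulate_tile(ph, spec, stage_xy = c(x0, y0),
                                tile_index = c(r, c), seed = seeds[i],
                                bscans = B, alines = A, ...)
  }
  list(tiles = tiles, truth_global = rf, plan = plan, seed = seed)
}
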