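# Calibration: background spectrum, uniform-k resampling map, and
# dispersion-compensation phase estimated from shutter frames and a mirror
# fringe.

#' Calibration set
#'
#' Everything reconstruction consumes besides raw counts. The resampling
#' map `k_map` gives, for each sample of a grid uniform in wavenumber
#' (same endpoint order as the pixel grid), the fractional source-pixel
#' index to interpolate at; it is strictly increasing with
#' `k_map[1] = 0` and `k_map[N] = N - 1` (0-based indices).
#' `dispersion_phase` is stored on the ascending-k uniform grid and has no
#' order-0/1 component.
#'
#' @param background Background spectrum (counts, length N).
#' @param k_map Resampling map from [build_k_mapping()].
#' @param lambda_of_pixel Pixel wavelength map used to build `k_map` (nm).
#' @param dispersion_phase Phase vector on the ascending-k uniform grid
#'   (radians, length N); default zero.
#' @param interpolation `"cubic"` (spline, default) or `"linear"`.
#' @param provenance Free-form list recording how pieces were estimated.
#' @return An object of class `calibration_set`.
#' @export
calibration_set <- function(background, k_map, lambda_of_pixel,
                            dispersion_phase = NULL,
                            interpolation = c("cubic", "linear"),
                            provenance = list()) {
  interpolation <- match.arg(interpolation)
  n <- length(background)
  stopifnot(length(k_map) == n, length(lambda_of_pixel) == n)
  if (any(diff(k_map) <= 0)) stop("k_map must be strictly increasing")
  if (abs(k_map[1]) > 1e-9 || abs(k_map[n] - (n - 1)) > 1e-9)
    stop("k_map endpoints must be 0 and N-1")
  if (is.null(dispersion_phase)) dispersion_phase <- rep(0, n)
  stopifnot(length(dispersion_phase) == n)
  k_px <- 2000 * pi / lambda_of_pixel
  # uniform-k target grid in pixel order; ascending flag for recon
  k_target <- seq(k_px[1], k_px[n], length.out = n)
  structure(list(background = as.numeric(background),
                 k_map = as.numeric(k_map),
                 lambda_of_pixel = as.numeric(lambda_of_pixel),
                 k_target = k_target,
                 flip = k_target[1] > k_target[n],
                 dispersion_phase = as.numeric(dispersion_phase),
                 interpolation = interpolation,
                 provenance = provenance),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("calibration set: N = %d, %s resampling, dispersion %s\n",
              length(x$background), x$interpolation,
              if (any(x$dispersion_phase != 0)) "estimated" else "zero"))
  invisible(x)
}

#' Estimate the background spectrum from shutter reference frames
#'
#' Per-pixel mean across reference (sample-blocked) frames.
#'
#' @param reference_frames Matrix of spectra, one frame per column
#'   (`N x M`), or a single spectrum vector.
#' @return Background spectrum, length N.
#' @export
estimate_background <- function(reference_frames) {
  if (is.null(reference_frames) || length(reference_frames) == 0)
    stop("need at least one reference frame")
  if (is.matrix(reference_frames)) rowMeans(reference_frames)
  else as.numeric(reference_frames)
}

#' Build the uniform-k resampling map
#'
#' Fractional source-pixel indices (0-based) such that sampling the raw
#' spectrum at them yields samples uniform in wavenumber `k = 2 pi /
#' lambda` between the grid endpoints. Invariant under uniform scaling of
#' the wavelength map.
#'
#' @param lambda_of_pixel Strictly monotone wavelength per pixel (nm).
#' @return Numeric vector of fractional indices, strictly increasing, with
#'   endpoints 0 and N-1.
#' @export
build_k_mapping <- function(lambda_of_pixel) {
  n <- length(lambda_of_pixel)
  if (n < 2) stop("need at least 2 pixels")
  d <- diff(lambda_of_pixel)
  if (!(all(d > 0) || all(d < 0)))
    stop("lambda_of_pixel must be strictly monotone")
  k_px <- 2000 * pi / lambda_of_pixel
  k_target <- seq(k_px[1], k_px[n], length.out = n)
  km <- stats::approx(k_px, seq(0, n - 1), xout = k_target)$y
  km[1] <- 0; km[n] <- n - 1
  km
}

# Resample a pixel-order spectrum at fractional indices (0-based). The
# cubic path first upsamples 4x by FFT zero padding, which suppresses the
# interpolation error on high-frequency (deep-reflector) fringes.
resample_at <- function(x, k_map, interpolation = "cubic") {
  n <- length(x)
  if (interpolation == "cubic") {
    U <- 4L
    xu <- fft_upsample(x, U)
    fine <- (seq_len(n * U) - 1) / U
    stats::splinefun(fine, xu, method = "natural")(k_map)
  } else stats::approx(seq(0, n - 1), x, xout = k_map)$y
}

# Put a resampled (pixel-order) vector into ascending-k order.
to_ascending_k <- function(x, cal) if (cal$flip) rev(x) else x

#' Estimate the dispersion-compensation phase from a mirror fringe
#'
#' Analytic-signal method: the background-subtracted fringe is resampled
#' to uniform k, its analytic phase extracted and unwrapped, the linear
#' component removed, and the residual fit with a polynomial of order
#' `order` in `(k - k0)` with `k0` at the grid center, weighted by the
#' fringe envelope. The returned phase vector contains only terms of
#' order >= 2.
#'
#' @param mirror_fringe Raw spectrum (counts, length N) of a single
#'   dominant reflector.
#' @param cal A [calibration_set()] providing background and `k_map`.
#' @param order Polynomial order of the fit (default 3).
#' @return List with `phase` (length-N vector on the ascending-k grid),
#'   `coefficients` (named `a2`, `a3`, ... in rad/(rad/um)^m), `k0`
#'   (rad/um), and `residual_rms` (radians).
#' @export
estimate_dispersion_phase <- function(mirror_fringe, cal, order = 3) {
  stopifnot(inherits(cal, "calibration_set"))
  n <- length(cal$background)
  if (length(mirror_fringe) != n) stop("fringe length does not match calibration")
  if (order < 2) stop("order must be >= 2")
  x <- mirror_fringe - cal$background
  xs <- to_ascending_k(resample_at(x, cal$k_map, cal$interpolation), cal)

  # dominant-peak gate on a quick dispersion-free reconstruction
  a0 <- analytic_signal(xs)
  mag <- Mod(stats::fft(a0))[seq_len(n %/% 2)]
  mag[1:3] <- 0                        # DC residual
  ipk <- which.max(mag)
  # guard wide enough that a strongly dispersed (smeared) single mirror
  # still passes, while a genuine second reflector farther out fails
  guard <- max(10L, length(mag) %/% 8L)
  excl <- pmax(1, ipk - guard):pmin(length(mag), ipk + guard)
  second <- max(mag[-excl])
  if (20 * log10(mag[ipk] / max(second, .Machine$double.eps)) < 6)
    stop("not a mirror fringe: no dominant peak (>= 6 dB above second)")

  k_asc <- seq(min(cal$k_target), max(cal$k_target), length.out = n)
  k0 <- (k_asc[1] + k_asc[n]) / 2
  w <- Mod(a0); w <- w / max(w)
  # phase is only meaningful where the fringe envelope has support; noise
  # in the spectral tails causes spurious unwrap jumps that would bias the
  # polynomial fit over the whole grid
  sup <- range(which(w >= 0.1))
  idx <- sup[1]:sup[2]
  ph <- signal::unwrap(Arg(a0[idx]))
  dk <- k_asc - k0
  X <- stats::poly(dk, degree = order, raw = TRUE)
  fit <- stats::lm.wfit(cbind(1, X[idx, , drop = FALSE]), ph, w = w[idx])
  co <- fit$coefficients
  a_m <- co[-(1:2)]                    # orders >= 2
  names(a_m) <- paste0("a", seq_along(a_m) + 1)
  phase <- as.numeric(X[, -1, drop = FALSE] %*% a_m)
  rss <- sqrt(stats::weighted.mean(fit$residuals^2, w[idx]))
  list(phase = phase, coefficients = a_m, k0 = k0, residual_rms = rss)
}

#' One-shot calibration from a simulated or acquired tile
#'
#' Background from the tile's reference frames, the k map from the
#' spectrometer's wavelength map, and (optionally) the dispersion phase
#' from a designated mirror-fringe column of the tile.
#'
#' @param tile A `raw_tile` (see [simulate_tile()]).
#' @param spec The [system_spec()] the tile was acquired under.
#' @param dispersion_column `c(bscan, aline)` of a single-mirror column to
#'   estimate dispersion from, `"mean"` to average every column of the
#'   tile first (a calibration tile images one mirror, so averaging
#'   suppresses camera noise), or `NULL` to leave the phase at zero.
#' @param order Polynomial order for dispersion estimation.
#' @param interpolation Resampling interpolator (`"cubic"` or `"linear"`).
#' @return A [calibration_set()].
#' @export
calibrate <- function(tile, spec, dispersion_column = NULL, order = 3,
                      interpolation = "cubic") {
  stopifnot(inherits(tile, "raw_tile"), inherits(spec, "system_spec"))
  if (dim(tile$counts)[3] != spec$spectrometer$n_pixels)
    stop(sprintf("tile has %d spectral pixels but the spec says %d",
                 dim(tile$counts)[3], spec$spectrometer$n_pixels))
  bg <- estimate_background(t(tile$reference))
  lam <- pixel_wavelengths(spec$spectrometer)
  km <- build_k_mapping(lam)
  cal <- calibration_set(bg, km, lam, interpolation = interpolation,
                         provenance = list(
                           background = sprintf("mean of %d reference frames",
                                                nrow(tile$reference)),
                           k_map = "from configured wavelength map",
                           seed = tile$seed))
  if (!is.null(dispersion_column)) {
    fr <- if (identical(dispersion_column, "mean"))
      apply(tile$counts, 3, mean)
    else tile$counts[dispersion_column[1], dispersion_column[2], ]
    est <- estimate_dispersion_phase(fr, cal, order = order)
    cal$dispersion_phase <- est$phase
    cal$provenance$dispersion <- list(
      column = dispersion_column, order = order,
      coefficients = est$coefficients, residual_rms = est$residual_rms)
  }
  cal
}
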