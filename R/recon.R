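# Five-step A-scan reconstruction: background subtraction, linear-k
# interpolation, apodization, numerical dispersion compensation (on the
# analytic signal), Fourier transform.

# Apodization window on the uniform-k grid.
apod_window <- function(name = c("hann", "gaussian", "rect"), n) {
  name <- match.arg(name)
  switch(name,
    hann = 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)),
    gaussian = exp(-0.5 * ((seq_len(n) - (n + 1) / 2) / (n / 6))^2),
    rect = rep(1, n))
}

#' Reconstruct one A-scan from a raw spectrum
#'
#' Executes the five processing steps in canonical order:
#' 1. subtract the calibration background;
#' 2. resample at the uniform-k map (`cal$k_map`);
#' 3. multiply by the apodization window;
#' 4. multiply the analytic signal by `exp(-i * dispersion_phase)`;
#' 5. unitary discrete Fourier transform, keeping the positive-depth half.
#'
#' @param raw Raw spectrum (counts, length N).
#' @param cal A [calibration_set()].
#' @param window Apodization: `"hann"` (default), `"gaussian"`, `"rect"`.
#' @param pad Zero-pad factor (integer >= 1). The default 1 returns the
#'   native N/2 depth bins; larger values interpolate the depth axis for
#'   sub-bin peak metrology and scale the depth pitch accordingly.
#' @return An object of class `ascan`: complex `values` (length
#'   `pad * N / 2`), `pitch_um` (um per depth bin), `n` (native bins),
#'   `pad`, `window`, and `flags`.
#' @export
reconstruct_ascan <- function(raw, cal, window = "hann", pad = 1) {
  stopifnot(inherits(cal, "calibration_set"))
  n <- length(cal$background)
  if (length(raw) != n) stop("raw spectrum length does not match calibration")
  if (anyNA(raw)) stop("raw spectrum contains NA")
  pad <- as.integer(pad)
  if (pad < 1) stop("pad must be >= 1")

  x <- raw - cal$background                                   # 1
  xs <- resample_at(x, cal$k_map, cal$interpolation)          # 2
  xs <- to_ascending_k(xs, cal)
  w <- apod_window(window, n)
  xw <- xs * w                                                # 3
  a <- analytic_signal(xw) * exp(-1i * cal$dispersion_phase)  # 4
  if (pad > 1) a <- c(a, complex(real = rep(0, n * (pad - 1))))
  A <- stats::fft(a) / sqrt(length(a))                        # 5
  values <- A[seq_len(length(a) %/% 2)]

  dk <- abs(cal$k_target[1] - cal$k_target[n]) / (n - 1)
  pitch <- pi / (n * pad * dk)   # um per bin; = z_max / (N/2) at pad = 1
  structure(list(values = values, pitch_um = pitch, n = as.integer(n),
                 pad = pad, window = window,
                 flags = list(saturated = isTRUE(attr(raw, "saturated")))),
            class = "ascan")
}

#' @export
print.ascan <- function(x, ...) {
  cat(sprintf("A-scan: %d depth bins, %.4f um/bin (pad %d, %s window)\n",
              length(x$values), x$pitch_um, x$pad, x$window))
  invisible(x)
}

#' Reconstruct a full tile volume
#'
#' Applies [reconstruct_ascan()] to every column of a raw tile and
#' assembles the magnitude volume with physical voxel pitches.
#'
#' @param tile A `raw_tile` (see [simulate_tile()]).
#' @param cal A [calibration_set()].
#' @param window Apodization window name.
#' @param tile_fov Lateral field of view `c(x, y)` in mm (for voxel pitch).
#' @return An object of class `oct_volume`: `magnitude[B, A, N/2]` linear
#'   amplitude, `pitch` (x, y in mm/voxel; z in um/voxel), `tile_index`,
#'   `stage_xy`, and processing `provenance`.
#' @export
reconstruct_volume <- function(tile, cal, window = "hann",
                               tile_fov = c(5, 5)) {
  stopifnot(inherits(tile, "raw_tile"), inherits(cal, "calibration_set"))
  d <- dim(tile$counts)
  B <- d[1]; A <- d[2]; n <- d[3]
  if (n != length(cal$background))
    stop("tile pixel count does not match calibration")
  nz <- n %/% 2
  mag <- array(0, dim = c(B, A, nz))
  pitch_um <- NA_real_
  for (b in seq_len(B)) for (a in seq_len(A)) {
    asc <- reconstruct_ascan(tile$counts[b, a, ], cal, window = window)
    mag[b, a, ] <- Mod(asc$values)
    pitch_um <- asc$pitch_um
  }
  structure(list(magnitude = mag,
                 pitch = list(x_mm = tile_fov[1] / A, y_mm = tile_fov[2] / B,
                              z_um = pitch_um),
                 tile_index = tile$tile_index, stage_xy = tile$stage_xy,
                 provenance = list(window = window,
                                   interpolation = cal$interpolation,
                                   calibration = cal$provenance,
                                   saturated = tile$saturated)),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf(
    "OCT volume [%d x %d x %d], pitch %.4g x %.4g mm, %.3f um depth\n",
    d[1], d[2], d[3], x$pitch$x_mm, x$pitch$y_mm, x$pitch$z_um))
  invisible(x)
}

#' Log compression for display
#'
#' `20 log10(magnitude / max)`, clipped to `[-dynamic_range, 0]` dB. An
#' all-zero input maps to `-dynamic_range` everywhere.
#'
#' @param volume An `oct_volume`, `mosaic_volume`, or numeric array of
#'   linear magnitudes.
#' @param dynamic_range Displayed dynamic range in dB (> 0).
#' @return Same shape as the input, values in dB. For classed inputs, the
#'   object is returned with its array replaced and `display = "dB"`
#'   recorded in provenance.
#' @export
log_compress <- function(volume, dynamic_range = 60) {
  if (dynamic_range <= 0) stop("dynamic_range must be > 0")
  arr <- if (inherits(volume, "oct_volume")) volume$magnitude
         else if (inherits(volume, "mosaic_volume")) volume$magnitude
         else volume
  m <- max(arr)
  db <- if (m == 0) array(-dynamic_range, dim = dim(arr) %||% length(arr))
        else pmax(20 * log10(pmax(arr, 0) / m), -dynamic_range)
  db <- pmin(db, 0)
  if (m == 0) db[] <- -dynamic_range
  if (is.array(arr)) dim(db) <- dim(arr)
  if (inherits(volume, c("oct_volume", "mosaic_volume"))) {
    volume$magnitude <- db
    volume$provenance$display <- sprintf("dB (range %g)", dynamic_range)
    volume
  } else db
}
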