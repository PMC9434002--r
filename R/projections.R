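# En-face Z-projection statistics, B-scan extraction, and image export.

volume_array <- function(volume) {
  if (inherits(volume, c("oct_volume", "mosaic_volume"))) volume$magnitude
  else if (is.array(volume) && length(dim(volume)) == 3) volume
  else stop("expected an oct_volume, mosaic_volume, or 3-D array")
}

#' En-face depth projection
#'
#' Collapses a volume along depth with one of five statistics. `std` is
#' the population standard deviation (descriptive statistic of the full
#' depth window). Projections operate on the values as given (linear
#' magnitude by default; pass a [log_compress()]ed volume for dB-domain
#' projections).
#'
#' @param volume An `oct_volume`, `mosaic_volume`, or `[Y, X, Z]` array.
#' @param statistic One of `"maximum"`, `"sum"`, `"average"`, `"median"`,
#'   `"std"` (aliases `"max"`, `"avg"`, `"mean"`, `"sd"` accepted).
#' @param depth_window `c(first, last)` depth-bin range (1-based,
#'   inclusive); default the full depth.
#' @return An object of class `projection_image`: `values[Y, X]`,
#'   `statistic`, `depth_window`, `mm_per_pixel`, `transform`.
#' @export
z_project <- function(volume, statistic = "average", depth_window = NULL) {
  arr <- volume_array(volume)
  aliases <- c(max = "maximum", avg = "average", mean = "average", sd = "std")
  if (statistic %in% names(aliases)) statistic <- aliases[[statistic]]
  if (!statistic %in% c("maximum", "sum", "average", "median", "std"))
    stop("unknown statistic: ", statistic)
  nz <- dim(arr)[3]
  if (is.null(depth_window)) depth_window <- c(1L, nz)
  depth_window <- as.integer(depth_window)
  if (length(depth_window) != 2 || depth_window[1] < 1 ||
      depth_window[2] > nz || depth_window[1] > depth_window[2])
    stop("invalid depth window")
  sub <- arr[, , depth_window[1]:depth_window[2], drop = FALSE]
  d <- dim(sub)
  m <- matrix(sub, nrow = d[1] * d[2], ncol = d[3])
  v <- switch(statistic,
    maximum = apply(m, 1, max),
    sum     = rowSums(m),
    average = rowMeans(m),
    median  = apply(m, 1, stats::median),
    std     = {
      mu <- rowMeans(m)
      sqrt(rowMeans((m - mu)^2))
    })
  pitch <- if (inherits(volume, c("oct_volume", "mosaic_volume")))
    c(x = volume$pitch$x_mm, y = volume$pitch$y_mm) else c(x = NA, y = NA)
  structure(list(values = matrix(v, d[1], d[2]), statistic = statistic,
                 depth_window = depth_window, mm_per_pixel = pitch,
                 transform = "none"),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("%s projection [%d x %d], depth bins %d-%d\n", x$statistic,
              d[1], d[2], x$depth_window[1], x$depth_window[2]))
  invisible(x)
}

#' Extract a cross-sectional B-scan
#'
#' @param volume An `oct_volume`, `mosaic_volume`, or `[Y, X, Z]` array.
#' @param axis `"fast"` (a stored B-scan: fixed slow index, lateral = fast
#'   axis) or `"slow"` (re-sliced across B-scans: fixed fast index).
#' @param index Slice index (1-based).
#' @return Matrix `[Z, lateral]` (depth on the vertical axis) with
#'   attributes `pitch_lateral_mm` and `pitch_z_um` when available.
#' @export
extract_bscan <- function(volume, axis = c("fast", "slow"), index = 1) {
  axis <- match.arg(axis)
  arr <- volume_array(volume)
  d <- dim(arr)
  lim <- if (axis == "fast") d[1] else d[2]
  if (index < 1 || index > lim) stop("B-scan index out of range")
  img <- if (axis == "fast") t(arr[index, , ]) else t(arr[, index, ])
  if (inherits(volume, c("oct_volume", "mosaic_volume"))) {
    attr(img, "pitch_lateral_mm") <- if (axis == "fast")
      volume$pitch$x_mm else volume$pitch$y_mm
    attr(img, "pitch_z_um") <- volume$pitch$z_um
  }
  img
}

#' Export an image to PNG or TIFF
#'
#' @param image A `projection_image`, matrix, or 2-D array.
#' @param path Output file; format from the extension (`.png` or
#'   `.tif`/`.tiff`).
#' @param bit_depth 8 (PNG/TIFF) or 16 (TIFF only).
#' @param rescale `"percentile"` (default; clips at the given quantiles),
#'   `"minmax"`, or `"none"` (values must already be in `[0, 1]`).
#' @param probs Percentile pair for `rescale = "percentile"`.
#' @return The path, invisibly.
#' @export
export_image <- function(image, path, bit_depth = 8,
                         rescale = c("percentile", "minmax", "none"),
                         probs = c(0.01, 0.99)) {
  rescale <- match.arg(rescale)
  v <- if (inherits(image, "projection_image")) image$values else image
  v <- as.matrix(v)
  if (rescale != "none") {
    rng <- if (rescale == "percentile")
      stats::quantile(v, probs, names = FALSE) else range(v)
    if (diff(rng) == 0) {
      warning("constant image: rescaling to mid-gray")
      v[] <- 0.5
    } else {
      v <- pmin(pmax((v - rng[1]) / (rng[2] - rng[1]), 0), 1)
    }
  }
  # image rows are Y ascending from the bottom; raster files count rows
  # from the top, so flip for display
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bit_depth != 8) stop("PNG export is 8-bit; use TIFF for 16-bit")
    png::writePNG(v, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(v, path, bits.per.sample = as.integer(bit_depth))
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Five-statistic projection panel
#'
#' Computes the maximum, sum, average, median and standard-deviation
#' projections over the same depth window, rescales each independently,
#' and writes them side by side into one image for gross-level review.
#'
#' @inheritParams z_project
#' @param path Output PNG/TIFF file.
#' @param gap Pixel gap between panels.
#' @return The path, invisibly.
#' @export
projection_panel <- function(volume, path, depth_window = NULL, gap = 4) {
  stats_ <- c("maximum", "sum", "average", "median", "std")
  imgs <- lapply(stats_, function(s) {
    p <- z_project(volume, s, depth_window)$values
    rng <- stats::quantile(p, c(0.01, 0.99), names = FALSE)
    if (diff(rng) == 0) matrix(0.5, nrow(p), ncol(p))
    else pmin(pmax((p - rng[1]) / diff(rng), 0), 1)
  })
  ny <- nrow(imgs[[1]])
  sep <- matrix(1, ny, gap)
  panel <- imgs[[1]]
  for (i in 2:length(imgs)) panel <- cbind(panel, sep, imgs[[i]])
  export_image(panel, path, rescale = "none")
}
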