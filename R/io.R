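# File formats: raw tiles and volumes as multi-page TIFF + JSON sidecar,
# plans/calibrations/manifests as JSON. Every container carries a format
# version tag; readers refuse unknown versions.

TILE_FORMAT <- "sdoct-tile-1"
VOLUME_FORMAT <- "sdoct-volume-1"
PLAN_FORMAT <- "sdoct-plan-1"
CAL_FORMAT <- "sdoct-calibration-1"
MANIFEST_FORMAT <- "sdoct-manifest-1"

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

read_json_file <- function(path, expect_format) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, expect_format))
    stop(sprintf("unsupported format version in %s: %s (expected %s)",
                 path, x$format %||% "<missing>", expect_format))
  x
}

#' Write / read a raw tile
#'
#' Counts and reference frames are stored as 16-bit multi-page TIFF (one
#' page per B-scan; reference frames as one page), metadata as a JSON
#' sidecar. Integer counts round-trip bit-exactly.
#'
#' @param tile A `raw_tile`.
#' @param path_base Path without extension; writes `<base>.tif`,
#'   `<base>_ref.tif`, `<base>.json`.
#' @return `path_base`, invisibly.
#' @export
write_tile <- function(tile, path_base) {
  stopifnot(inherits(tile, "raw_tile"))
  d <- dim(tile$counts)
  pages <- lapply(seq_len(d[1]), function(b) tile$counts[b, , ] / 65535)
  tiff::writeTIFF(pages, paste0(path_base, ".tif"), bits.per.sample = 16L)
  tiff::writeTIFF(tile$reference / 65535, paste0(path_base, "_ref.tif"),
                  bits.per.sample = 16L)
  write_json_file(list(format = TILE_FORMAT, dim = d,
                       n_reference = nrow(tile$reference),
                       stage_xy = tile$stage_xy,
                       tile_index = tile$tile_index, seed = tile$seed,
                       saturated = tile$saturated, rho_r = tile$rho_r),
                  paste0(path_base, ".json"))
  invisible(path_base)
}

#' @rdname write_tile
#' @export
read_tile <- function(path_base) {
  meta <- read_json_file(paste0(path_base, ".json"), TILE_FORMAT)
  pages <- tiff::readTIFF(paste0(path_base, ".tif"), all = TRUE)
  d <- as.integer(meta$dim)
  counts <- array(0, dim = d)
  for (b in seq_len(d[1])) counts[b, , ] <- round(pages[[b]] * 65535)
  ref <- round(tiff::readTIFF(paste0(path_base, "_ref.tif")) * 65535)
  structure(list(counts = counts, reference = ref,
                 stage_xy = as.numeric(meta$stage_xy),
                 tile_index = as.integer(meta$tile_index),
                 seed = meta$seed, saturated = isTRUE(meta$saturated),
                 rho_r = meta$rho_r),
            class = "raw_tile")
}

#' Write / read a reconstructed volume
#'
#' Linear magnitude stored as 32-bit float multi-page TIFF (one page per
#' B-scan), normalized by its maximum; the scale, pitches and provenance
#' go to a JSON sidecar. Round-trip is exact to 32-bit float
#' representation.
#'
#' @param volume An `oct_volume` or `mosaic_volume`.
#' @param path_base Path without extension; writes `<base>.tif` and
#'   `<base>.json`.
#' @return `path_base`, invisibly.
#' @export
write_volume <- function(volume, path_base) {
  arr <- volume_array(volume)
  scale <- max(arr)
  if (scale == 0) scale <- 1
  pages <- lapply(seq_len(dim(arr)[1]), function(b) arr[b, , ] / scale)
  tiff::writeTIFF(pages, paste0(path_base, ".tif"), bits.per.sample = 32L)
  meta <- list(format = VOLUME_FORMAT, dim = dim(arr), scale = scale,
               pitch = volume$pitch, provenance = volume$provenance)
  if (inherits(volume, "oct_volume")) {
    meta$kind <- "tile"
    meta$tile_index <- volume$tile_index
    meta$stage_xy <- volume$stage_xy
  } else {
    meta$kind <- "mosaic"
    meta$provenance_map <- volume$provenance_map
    meta$plan <- unclass_plan(volume$plan)
  }
  write_json_file(meta, paste0(path_base, ".json"))
  invisible(path_base)
}

#' @rdname write_volume
#' @export
read_volume <- function(path_base) {
  meta <- read_json_file(paste0(path_base, ".json"), VOLUME_FORMAT)
  pages <- tiff::readTIFF(paste0(path_base, ".tif"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(meta$dim)
  arr <- array(0, dim = d)
  for (b in seq_len(d[1])) arr[b, , ] <- pages[[b]] * meta$scale
  pitch <- lapply(meta$pitch, as.numeric)
  if (identical(meta$kind, "mosaic")) {
    structure(list(magnitude = arr, pitch = pitch,
                   provenance_map = meta$provenance_map,
                   plan = plan_from_list(meta$plan),
                   provenance = meta$provenance),
              class = "mosaic_volume")
  } else {
    structure(list(magnitude = arr, pitch = pitch,
                   tile_index = as.integer(meta$tile_index),
                   stage_xy = as.numeric(meta$stage_xy),
                   provenance = meta$provenance),
              class = "oct_volume")
  }
}

unclass_plan <- function(plan) {
  list(rows = plan$rows, cols = plan$cols, tile_fov = plan$tile_fov,
       overlap = plan$overlap, origin = plan$origin, order = plan$order,
       width_mm = plan$width_mm, height_mm = plan$height_mm)
}

plan_from_list <- function(l) {
  structure(list(rows = as.integer(l$rows), cols = as.integer(l$cols),
                 tile_fov = as.numeric(l$tile_fov), overlap = l$overlap,
                 origin = l$origin, order = as.data.frame(l$order),
                 width_mm = l$width_mm, height_mm = l$height_mm),
            class = "scan_plan")
}

#' Write / read a scan plan as JSON
#' @param plan A [plan_snake_scan()].
#' @param path JSON file path.
#' @return The path (write) or a `scan_plan` (read).
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "scan_plan"))
  write_json_file(c(list(format = PLAN_FORMAT), unclass_plan(plan)), path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  plan_from_list(read_json_file(path, PLAN_FORMAT))
}

#' Write / read a calibration set as JSON
#' @param cal A [calibration_set()].
#' @param path JSON file path.
#' @return The path (write) or a `calibration_set` (read).
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_set"))
  write_json_file(list(format = CAL_FORMAT, background = cal$background,
                       k_map = cal$k_map,
                       lambda_of_pixel = cal$lambda_of_pixel,
                       dispersion_phase = cal$dispersion_phase,
                       interpolation = cal$interpolation,
                       provenance = cal$provenance), path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- read_json_file(path, CAL_FORMAT)
  calibration_set(as.numeric(x$background), as.numeric(x$k_map),
                  as.numeric(x$lambda_of_pixel),
                  as.numeric(x$dispersion_phase),
                  interpolation = x$interpolation,
                  provenance = x$provenance)
}

#' Write and verify an artifact manifest
#'
#' The manifest lists every artifact the pipeline produced with MD5
#' checksums of its files, plus the configuration echo and seed, so a run
#' is reproducible from the manifest alone.
#'
#' @param artifacts List of entries, each `list(type =, files = <paths>)`.
#' @param config The run configuration (echoed verbatim).
#' @param seed Global seed of the run.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(artifacts, config, seed, path) {
  root <- normalizePath(dirname(path), winslash = "/")
  arts <- lapply(artifacts, function(a) {
    sums <- tools::md5sum(a$files)
    rel <- sub(paste0("^", root, "/"), "",
               normalizePath(a$files, winslash = "/"))
    list(type = a$type,
         files = lapply(seq_along(a$files), function(i)
           list(path = rel[i], md5 = unname(sums[i]))))
  })
  m <- list(format = MANIFEST_FORMAT, seed = seed, config = config,
            artifacts = arts)
  write_json_file(m, path)
  invisible(m)
}

#' @rdname write_manifest
#' @param dir Directory holding the manifest's files.
#' @export
verify_manifest <- function(path, dir = dirname(path)) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(m$format, MANIFEST_FORMAT))
    stop("unsupported manifest format: ", m$format %||% "<missing>")
  for (a in m$artifacts) {
    for (fl in a$files) {
      f <- file.path(dir, fl$path)
      if (!file.exists(f)) stop("manifest file missing: ", fl$path)
      if (!identical(unname(tools::md5sum(f)), fl$md5))
        stop("checksum mismatch: ", fl$path)
    }
  }
  invisible(TRUE)
}
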