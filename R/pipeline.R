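# End-to-end pipeline: simulate -> calibrate -> reconstruct -> stitch ->
# project -> report, with a manifest of all artifacts.

#' Build / validate a run configuration
#'
#' A run configuration fully determines a pipeline run: system spec,
#' cassette phantom, scan-plan parameters, processing flags, output
#' directory and one global seed (expanded internally into per-stage
#' streams). Accepts a list or a YAML file path. Any referenced file
#' (e.g. a `phantom: <path>` entry) must exist at validation time.
#'
#' @param x A named list or path to a YAML file.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    x <- yaml::read_yaml(x)
  }
  stopifnot(is.list(x))
  for (f in c("out_dir", "plan", "phantom")) {
    if (is.null(x[[f]])) stop("config missing required field: ", f)
  }
  x$seed <- as.integer(x$seed %||% 1L)
  if (is.character(x$phantom)) {
    if (!file.exists(x$phantom)) stop("phantom file not found: ", x$phantom)
    x$phantom <- yaml::read_yaml(x$phantom)
  }
  x$processing <- x$processing %||% list()
  x$processing$window <- x$processing$window %||% "hann"
  x$processing$dynamic_range <- x$processing$dynamic_range %||% 60
  x$processing$overlap_policy <- x$processing$overlap_policy %||% "crop"
  x$processing$projections <- x$processing$projections %||%
    c("maximum", "sum", "average", "median", "std")
  structure(x, class = c("run_config", "list"))
}

spec_from_list <- function(l) {
  if (is.null(l)) return(system_spec())
  src <- do.call(source_spectrum, l$source %||% list())
  sp <- do.call(spectrometer_model, l$spectrometer %||% list())
  di <- do.call(dispersion_model, l$dispersion %||% list())
  args <- l[setdiff(names(l), c("source", "spectrometer", "dispersion"))]
  args <- lapply(args, function(a) if (is.list(a)) unlist(a) else a)
  do.call(system_spec, c(list(source = src, spectrometer = sp,
                              dispersion = di), args))
}

cassette_phantom_from_list <- function(l) {
  rf <- l$reflectors
  if (!is.data.frame(rf)) {
    rf <- if (is.list(rf) && length(rf) && is.list(rf[[1]]))
      do.call(rbind, lapply(rf, as.data.frame))   # list of rows
    else as.data.frame(rf)                        # list of columns (YAML)
  }
  cassette_phantom(rf, refractive_index = l$refractive_index %||% 1.4)
}

#' Demo run configuration
#'
#' A small 2 x 2 cassette with one mirror per quadrant at a distinct
#' depth: the standard end-to-end smoke/determinism scenario.
#'
#' @param out_dir Output directory for the run.
#' @param seed Global seed.
#' @return A `run_config`.
#' @export
demo_run_config <- function(out_dir, seed = 1L) {
  fov <- 2
  depths <- c(100, 200, 300, 400)   # um, one per quadrant
  qx <- c(0, 1, 0, 1); qy <- c(0, 0, 1, 1)
  rf <- data.frame(z_um = depths, r = 0.05,
                   x_min = qx * fov + 0.5, x_max = qx * fov + 1.5,
                   y_min = qy * fov + 0.5, y_max = qy * fov + 1.5)
  run_config(list(
    seed = seed, out_dir = out_dir,
    spec = list(spectrometer = list(n_pixels = 512),
                a_lines_per_bscan = 32, bscans_per_volume = 8,
                tile_fov = c(fov, fov)),
    phantom = list(reflectors = rf),
    plan = list(width_mm = 2 * fov, height_mm = 2 * fov,
                overlap = 0, origin = "lower-right"),
    calibration = list(mirror_z_um = 250, n_reference = 20)))
}

#' Run the full pipeline
#'
#' Executes all stages in order -- simulate the cassette tiles and a
#' calibration mirror tile, estimate the calibration set, reconstruct
#' every tile, stitch the mosaic, compute the five en-face projections,
#' measure system performance -- and writes every artifact plus a
#' manifest with MD5 checksums. Idempotent for a fixed seed.
#'
#' @param config A [run_config()] (or list / YAML path accepted by it).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  spec <- stage("config", spec_from_list(cfg$spec))
  seeds <- derive_seeds(cfg$seed, 3)
  artifacts <- list()
  add <- function(type, files)
    artifacts[[length(artifacts) + 1]] <<- list(type = type, files = files)

  plan <- stage("plan", do.call(plan_snake_scan, c(
    cfg$plan[setdiff(names(cfg$plan), "overlap")],
    list(tile_fov = spec$tile_fov, overlap = cfg$plan$overlap %||% 0))))
  plan_path <- file.path(out, "plan.json")
  write_plan(plan, plan_path)
  add("plan", plan_path)

  ph <- stage("phantom", cassette_phantom_from_list(cfg$phantom))
  ds <- stage("simulate", generate_cassette_dataset(ph, spec, plan,
                                                    seed = seeds[1]))
  tile_dir <- file.path(out, "tiles")
  dir.create(tile_dir, showWarnings = FALSE)
  for (t in ds$tiles) {
    base <- file.path(tile_dir, sprintf("tile_%d_%d", t$tile$tile_index[1],
                                        t$tile$tile_index[2]))
    write_tile(t$tile, base)
    add("tile", paste0(base, c(".tif", "_ref.tif", ".json")))
  }

  cal <- stage("calibrate", {
    mz <- cfg$calibration$mirror_z_um %||%
      (0.3 * max_imaging_depth(spec$spectrometer) * 1000)
    mir <- phantom(reflectors = data.frame(z_um = mz, r = 0.05))
    mt <- simulate_tile(mir, spec, seed = seeds[2], bscans = 2,
                        alines = 16,
                        n_reference = cfg$calibration$n_reference %||% 20)
    calibrate(mt$tile, spec, dispersion_column = "mean")
  })
  cal_path <- file.path(out, "calibration.json")
  write_calibration(cal, cal_path)
  add("calibration", cal_path)

  vol_dir <- file.path(out, "volumes")
  dir.create(vol_dir, showWarnings = FALSE)
  volumes <- stage("reconstruct", lapply(ds$tiles, function(t)
    reconstruct_volume(t$tile, cal, window = cfg$processing$window,
                       tile_fov = spec$tile_fov)))
  for (v in volumes) {
    base <- file.path(vol_dir, sprintf("volume_%d_%d", v$tile_index[1],
                                       v$tile_index[2]))
    write_volume(v, base)
    add("volume", paste0(base, c(".tif", ".json")))
  }

  mosaic <- stage("stitch", stitch_tiles(volumes, plan,
                                         policy = cfg$processing$overlap_policy))
  mos_base <- file.path(out, "mosaic")
  write_volume(mosaic, mos_base)
  add("mosaic", paste0(mos_base, c(".tif", ".json")))

  stage("project", for (s in cfg$processing$projections) {
    p <- file.path(out, sprintf("projection_%s.png", s))
    export_image(z_project(mosaic, s), p)
    add("projection", p)
  })

  report <- stage("report", performance_report(spec, seed = seeds[3]))
  rep_path <- file.path(out, "report.json")
  write_json_file(list(
    format = "sdoct-report-1",
    axial_fwhm_air_um = report$axial_fwhm_air_um,
    axial_fwhm_tissue_um = report$axial_fwhm_tissue_um,
    axial_fwhm_tissue149_um = report$axial_fwhm_tissue149_um,
    falloff_6db_mm = report$falloff_6db_mm,
    snr_db = report$snr_db,
    rolloff_curve = report$rolloff_curve,
    theory = report$theory, seed = report$seed), rep_path)
  add("report", rep_path)

  manifest <- write_manifest(artifacts, unclass(cfg), cfg$seed,
                             file.path(out, "manifest.json"))
  invisible(manifest)
}
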