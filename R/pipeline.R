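#' Default end-to-end pipeline configuration
#'
#' Builds the configuration list consumed by [run_pipeline()].  All defaults
#' mirror the package's reference protocol: a 128-element, 1 mm-pitch
#' aperture, 1540 m/s, one transmit element per scanline, 5 MHz pulse
#' sampled at 40 MHz, whole-trace peak search in simulation mode (marker
#' gate 9--24 mm in experimental mode), APR threshold 5 samples,
#' Savitzky--Golay delay-curve window 21 / order 2, dynamic range
#' [-60, 0] dB.
#'
#' @param phantom phantom kind (see [marker_phantom()]) or a [phantom()].
#' @param shape geometry shape: `"flat"`, `"arc"`, `"polyline"`.
#' @param radius arc radius (mm), for `shape = "arc"`.
#' @param n_elements,pitch aperture layout.
#' @param center_frequency,fractional_bandwidth,fs pulse parameters.
#' @param sound_speed m/s.
#' @param mode APR mode, `"simulation"` or `"experimental"`.
#' @param gate `NULL` (whole trace) or a [gate_window()].
#' @param reference APR reference scanline (see [apr()]); the pipeline
#'   default `"strongest"` anchors the aligned image at the marker's true
#'   depth for the scanline nearest the marker.
#' @param threshold APR round-2 increment clamp (samples).
#' @param floor_db dynamic-range floor (dB).
#' @param noise_level,seed optional additive noise and its seed.
#' @return a named list of class `"flexbeam_config"`.
#' @export
flexbeam_config <- function(phantom = "center_point",
                            shape = "flat", radius = NULL,
                            n_elements = 128L, pitch = 1,
                            center_frequency = 5e6,
                            fractional_bandwidth = 0.6, fs = 40e6,
                            sound_speed = 1540,
                            mode = "simulation", gate = NULL,
                            reference = "strongest", threshold = 5,
                            floor_db = -60,
                            noise_level = 0, seed = NULL) {
  structure(list(phantom = phantom, shape = shape, radius = radius,
                 n_elements = as.integer(n_elements), pitch = pitch,
                 center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth, fs = fs,
                 sound_speed = sound_speed, mode = mode, gate = gate,
                 reference = reference, threshold = threshold,
                 floor_db = floor_db, noise_level = noise_level,
                 seed = seed),
            class = "flexbeam_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar fields map one-to-one onto [flexbeam_config()] arguments; a
#' `gate: [z_min, z_max]` entry becomes a [gate_window()].
#'
#' @param path YAML file path.
#' @return a `flexbeam_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  y <- yaml::read_yaml(path)
  if (!is.null(y$gate)) y$gate <- gate_window(y$gate[[1]], y$gate[[2]])
  do.call(flexbeam_config, y)
}

#' Run the full simulate -> APR -> beamform -> evaluate pipeline
#'
#' Simulates RF channel data from the configured phantom and geometry,
#' fits the APR delay curves, reconstructs the APR B-mode image, computes
#' the geometry-aware DAS ground-truth image, and evaluates the standard
#' metrics.  With `out_dir` set, all artifacts (RF container, delay CSV,
#' PNG images, metrics CSV) are written together with a JSON manifest of
#' MD5 file hashes.
#'
#' @param config a [flexbeam_config()] (or YAML path).
#' @param out_dir optional output directory.
#' @return An object of class `"flexbeam_run"`: list with `rf`, `fit`
#'   ([apr()] object), `apr_image`, `gt_image` (`bmode_image`s), `metrics`
#'   (one-row data.frame), `config`, and `manifest` (when written).
#' @export
run_pipeline <- function(config = flexbeam_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "flexbeam_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  geom <- stage("geometry",
    array_geometry(config$shape, config$n_elements, config$pitch,
                   radius = config$radius))
  ph <- stage("phantom",
    if (inherits(config$phantom, "phantom")) config$phantom
    else marker_phantom(config$phantom, seed = config$seed))
  pulse <- gauss_pulse(config$center_frequency, config$fractional_bandwidth,
                       config$fs)
  rf <- stage("simulate",
    simulate_rf(ph, geom, pulse, config$sound_speed,
                noise_level = config$noise_level, seed = config$seed))
  fit <- stage("apr",
    apr(rf, gate = config$gate, reference = config$reference,
        mode = config$mode, threshold = config$threshold))
  img_apr <- stage("beamform_apr", beamform_apr(rf, fit, config$floor_db))
  img_gt <- stage("beamform_das", beamform_das(rf, floor_db = config$floor_db))
  # ground-truth delay curve for the first marker, for the delay-error row
  mk <- ph[which.max(ph$amplitude), ]
  gt_total <- oracle_delays(geom, c(mk$x, mk$z), config$fs,
                            config$sound_speed,
                            reference = fit$reference_scanline)$round1
  metrics <- stage("metrics",
    metrics_report(img_apr, reference = img_gt, opt_xz = c(mk$x, mk$z),
                   delays = fit$round1, gt_delays = round(gt_total)))
  run <- structure(list(rf = rf, fit = fit, apr_image = img_apr,
                        gt_image = img_gt, metrics = metrics,
                        config = config, manifest = NULL),
                   class = "flexbeam_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_rf(rf, file.path(out_dir, "rf"))
    write_delays(fit, file.path(out_dir, "delays.csv"))
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    ok_png <- requireNamespace("png", quietly = TRUE)
    if (ok_png) {
      write_image_png(img_apr, file.path(out_dir, "apr.png"))
      write_image_png(img_gt, file.path(out_dir, "ground_truth.png"))
    }
    files <- c("rf.f32", "rf.json", "delays.csv", "metrics.csv",
               if (ok_png) c("apr.png", "ground_truth.png"))
    paths <- file.path(out_dir, files)
    manifest <- list(files = files,
                     md5 = unname(tools::md5sum(paths)))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = FALSE, digits = NA),
               file.path(out_dir, "manifest.json"))
    run$manifest <- manifest
  }
  run
}

#' @export
print.flexbeam_run <- function(x, ...) {
  cat("flexbeam pipeline run\n")
  cat("  phantom:", if (is.character(x$config$phantom)) x$config$phantom
      else "custom", "  geometry:", x$rf$geometry$shape, "\n")
  print(x$fit)
  cat("  metrics:\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
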