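#' Write / read RF channel data (raw float32 + JSON sidecar)
#'
#' The package's RF container is a pair of files: `<path>.f32` holding the
#' sample tensor as little-endian float32 in column-major
#' `[n_samples, n_elements, n_scanlines]` order, and `<path>.json` holding
#' the acquisition metadata `{fs_hz, t0_s, c_mps, dims, tx_map,
#' geometry_json?}`.  The round trip is lossless at float32 precision.
#'
#' @param rf an `rf_data` object.
#' @param path base path (without extension).
#' @return `write_rf`: the base path, invisibly.  `read_rf`: an `rf_data`.
#' @export
write_rf <- function(rf, path) {
  stopifnot(inherits(rf, "rf_data"))
  con <- file(paste0(path, ".f32"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rf$data), con, size = 4L, endian = "little")
  meta <- list(fs_hz = rf$fs, t0_s = rf$t0, c_mps = rf$sound_speed,
               dims = dim(rf$data), tx_map = rf$tx_map)
  if (!is.null(rf$geometry))
    meta$geometry_json <- jsonlite::fromJSON(geometry_to_json(rf$geometry))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_rf
#' @export
read_rf <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing metadata sidecar: ", meta_path)
  meta <- jsonlite::fromJSON(meta_path)
  required <- c("fs_hz", "t0_s", "c_mps", "dims", "tx_map")
  missing_keys <- setdiff(required, names(meta))
  if (length(missing_keys) > 0)
    stop("RF container format error: missing metadata key(s) ",
         paste(missing_keys, collapse = ", "))
  dims <- as.integer(meta$dims)
  con <- file(paste0(path, ".f32"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = prod(dims), size = 4L, endian = "little")
  if (length(x) != prod(dims))
    stop("RF container format error: sample count does not match dims")
  geom <- if (!is.null(meta$geometry_json))
    geometry_from_json(jsonlite::toJSON(meta$geometry_json,
                                        auto_unbox = TRUE, digits = NA))
  else NULL
  structure(list(data = array(x, dims), fs = meta$fs_hz, t0 = meta$t0_s,
                 sound_speed = meta$c_mps, tx_map = as.integer(meta$tx_map),
                 geometry = geom),
            class = "rf_data")
}

#' Write / read an APR delay curve as CSV
#'
#' Long format with one row per (scanline, element):
#' `scanline, element, round1, round2, total`.
#'
#' @param fit an [apr()] fit.
#' @param path CSV file path.
#' @return `write_delays`: `path`, invisibly; `read_delays`: a data.frame.
#' @export
write_delays <- function(fit, path) {
  stopifnot(inherits(fit, "apr"))
  n_sc <- nrow(fit$total); n_el <- ncol(fit$total)
  df <- data.frame(scanline = rep(seq_len(n_sc), n_el),
                   element = rep(seq_len(n_el), each = n_sc),
                   round1 = rep(fit$round1, n_el),
                   round2 = as.vector(fit$round2),
                   total = as.vector(fit$total))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_delays
#' @export
read_delays <- function(path) utils::read.csv(path)

#' Export a B-mode image as 8-bit grayscale PNG
#'
#' Maps the dB pixels linearly from `[floor_db, 0]` to `[0, 1]` gray.
#' Requires the `png` package.
#'
#' @param image a `bmode_image`.
#' @param path PNG file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  stopifnot(inherits(image, "bmode_image"))
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  floor_db <- image$dynamic_range[1]
  g <- (image$pixels - floor_db) / (0 - floor_db)
  g <- pmin(pmax(g, 0), 1)
  png::writePNG(g, path)
  invisible(path)
}
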