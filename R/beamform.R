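#' Envelope detection via the analytic signal
#'
#' Returns the magnitude of the analytic signal (FFT method: negative
#' frequencies zeroed, positive doubled), the slowly varying amplitude of
#' the RF oscillation.
#'
#' @param trace numeric vector (or matrix: envelope per column).
#' @return nonnegative envelope, same shape.
#' @export
envelope <- function(trace) {
  n <- if (is.matrix(trace)) nrow(trace) else length(trace)
  if (n < 2L) return(abs(trace))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  if (is.matrix(trace)) {
    Mod(stats::mvfft(stats::mvfft(trace) * h, inverse = TRUE) / n)
  } else {
    Mod(stats::fft(stats::fft(trace) * h, inverse = TRUE) / n)
  }
}

#' Logarithmic compression to decibels
#'
#' Maps a linear-scale envelope image to `20 log10(x / max(x))`, clipped
#' below at `floor_db`.
#'
#' @param image_linear nonnegative numeric array with at least one positive
#'   value.
#' @param floor_db dynamic-range floor in dB (default -60).
#' @return dB-scale array, maximum 0 dB, minimum `floor_db`.
#' @export
log_compress <- function(image_linear, floor_db = -60) {
  m <- max(image_linear)
  if (m <= 0) stop("degenerate input: no positive value to normalize to 0 dB")
  db <- 20 * log10(pmax(image_linear / m, 10^((floor_db - 20) / 20)))
  pmax(db, floor_db)
}

new_bmode_image <- function(pixels, x_mm, z_mm, floor_db, provenance) {
  structure(list(pixels = pixels, x_mm = x_mm, z_mm = z_mm,
                 dynamic_range = c(floor_db, 0), provenance = provenance),
            class = "bmode_image")
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %d x %d px (%s), x [%.1f, %.1f] mm, z [%.1f, %.1f] mm, [%g, 0] dB\n",
              nrow(x$pixels), ncol(x$pixels), x$provenance,
              min(x$x_mm), max(x$x_mm), min(x$z_mm), max(x$z_mm),
              x$dynamic_range[1]))
  invisible(x)
}

#' @export
plot.bmode_image <- function(x, main = x$provenance, ...) {
  # depth increases downward, grayscale dB map
  graphics::image(x$x_mm, x$z_mm, t(x$pixels), ylim = rev(range(x$z_mm)),
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "lateral x (mm)", ylab = "depth z (mm)",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

scanline_x_positions <- function(rf) {
  if (!is.null(rf$geometry)) rf$geometry$element_x[rf$tx_map]
  else {
    # shape-blind data: nominal 1 mm-pitch flat layout
    x <- (seq_along(rf$tx_map) - 1); x - mean(x)
  }
}

depth_axis_mm <- function(rf) {
  n <- dim(rf$data)[1]
  rf$sound_speed * (rf$t0 + (seq_len(n) - 1) / rf$fs) / 2 * 1000
}

#' APR beamforming: delayed summation B-mode reconstruction
#'
#' Applies the fitted APR delays, sums across the element dimension to one
#' trace per scanline, envelope-detects, log-compresses and clips.  The
#' delays are constant along depth (fixed-focus behaviour: the alignment is
#' exact at the marker depth and approximate elsewhere).  Image columns are
#' the scanlines; rows are RF sample depths `z = c (t0 + n / fs) / 2`.
#'
#' @param rf an `rf_data` object.
#' @param delay_curve an [apr()] fit, per-scanline vector or
#'   n_scanlines x n_elements delay matrix (samples).
#' @param floor_db dynamic-range floor (default -60 dB).
#' @return a `bmode_image` (provenance `"apr"`).
#' @export
beamform_apr <- function(rf, delay_curve, floor_db = -60) {
  stopifnot(inherits(rf, "rf_data"))
  if (max(abs(range(rf$data))) == 0) stop("degenerate input: all-zero RF data")
  rfd <- apply_delays(rf, delay_curve)
  n_sa <- dim(rfd$data)[1]
  n_sc <- dim(rfd$data)[3]
  summed <- vapply(seq_len(n_sc),
                   function(s) rowSums(matrix(rfd$data[, , s], nrow = n_sa)),
                   numeric(n_sa))
  env <- envelope(summed)
  new_bmode_image(log_compress(env, floor_db),
                  scanline_x_positions(rf), depth_axis_mm(rf),
                  floor_db, "apr")
}

#' Geometry-aware delay-and-sum reference beamformer
#'
#' Conventional DAS with known element positions: for each focal point on a
#' scanline's axis the exact two-way time of flight to every element is
#' applied and the channels summed, followed by envelope detection and log
#' compression.  `focus = "dynamic"` (default) recomputes delays at every
#' depth sample; `focus = "fixed"` computes integer-sample receive delays
#' once at `focus_depth` and applies them as constant shifts (comparable to
#' what peak-alignment delays achieve).
#'
#' @param rf an `rf_data` object.
#' @param geometry an [array_geometry()]; defaults to `rf$geometry`.
#' @param focus `"dynamic"` or `"fixed"`.
#' @param focus_depth focal depth in mm for `focus = "fixed"`.
#' @param grid_x lateral positions (mm) of the image columns' vertical axes;
#'   default the transmit elements' lateral positions.
#' @param floor_db dynamic-range floor (default -60 dB).
#' @param interp channel resampling for dynamic focusing: `"spline"`
#'   (default; cubic, accurate at a few samples per wavelength) or
#'   `"linear"` (faster).
#' @return a `bmode_image` (provenance `"das_groundtruth"`).
#' @export
beamform_das <- function(rf, geometry = rf$geometry,
                         focus = c("dynamic", "fixed"), focus_depth = NULL,
                         grid_x = NULL, floor_db = -60,
                         interp = c("spline", "linear")) {
  stopifnot(inherits(rf, "rf_data"))
  focus <- match.arg(focus)
  interp <- match.arg(interp)
  if (is.null(geometry))
    stop("DAS requires a geometry (rf carries none and none was supplied)")
  stopifnot(inherits(geometry, "array_geometry"))
  if (max(abs(range(rf$data))) == 0) stop("degenerate input: all-zero RF data")
  dims <- dim(rf$data)
  n_sa <- dims[1]; n_el <- dims[2]; n_sc <- dims[3]
  fs <- rf$fs; t0 <- rf$t0; c0 <- rf$sound_speed
  t_axis <- t0 + (seq_len(n_sa) - 1) / fs
  z_grid <- pmax(c0 * t_axis / 2 * 1000, 1e-6)
  if (is.null(grid_x)) grid_x <- geometry$element_x[rf$tx_map]
  if (length(grid_x) != n_sc) stop("grid_x must have one entry per scanline")
  summed <- matrix(0, n_sa, n_sc)
  for (s in seq_len(n_sc)) {
    txe <- rf$tx_map[s]
    pts <- cbind(rep(grid_x[s], n_sa), z_grid)
    acc <- numeric(n_sa)
    if (focus == "dynamic") {
      for (e in seq_len(n_el)) {
        tau <- tof(geometry, txe, e, pts, c0)
        if (interp == "spline") {
          y <- stats::spline(t_axis, rf$data[, e, s], xout = tau,
                             method = "fmm")$y
          y[tau < t_axis[1] | tau > t_axis[n_sa]] <- 0
          acc <- acc + y
        } else {
          acc <- acc + stats::approx(t_axis, rf$data[, e, s], xout = tau,
                                     yleft = 0, yright = 0)$y
        }
      }
    } else {
      if (is.null(focus_depth)) stop("focus = 'fixed' requires focus_depth")
      pf <- c(grid_x[s], focus_depth)
      tau_tx <- tof(geometry, txe, txe, pf, c0)
      for (e in seq_len(n_el)) {
        d <- as.integer(round((tau_tx - tof(geometry, txe, e, pf, c0)) * fs))
        tr <- rf$data[, e, s]
        y <- numeric(n_sa)
        if (d > 0) y[(d + 1):n_sa] <- tr[1:(n_sa - d)]
        else if (d < 0) y[1:(n_sa + d)] <- tr[(1 - d):n_sa]
        else y <- tr
        acc <- acc + y
      }
    }
    summed[, s] <- acc
  }
  env <- envelope(summed)
  new_bmode_image(log_compress(env, floor_db), grid_x, depth_axis_mm(rf),
                  floor_db, "das_groundtruth")
}

#' Locate the brightest pixel of a B-mode image
#'
#' @param image a `bmode_image`.
#' @return list with `x` and `z` (mm) and `value` (dB) of the global
#'   maximum.
#' @export
image_peak <- function(image) {
  stopifnot(inherits(image, "bmode_image"))
  ij <- which(image$pixels == max(image$pixels), arr.ind = TRUE)[1, ]
  list(x = image$x_mm[ij[2]], z = image$z_mm[ij[1]],
       value = image$pixels[ij[1], ij[2]])
}

#' Locate multiple lateral intensity peaks
#'
#' Finds local maxima of the per-column maximum-intensity profile,
#' separated by at least `min_separation_mm`, and returns the `n` brightest
#' ordered from left to right.  In APR-aligned images the markers sit at
#' the reference scanline's peak depth, so supplying `z_center` (with
#' `z_band`) restricts the search to that depth band and excludes
#' summation artifacts at other depths.
#'
#' @param image a `bmode_image`.
#' @param n number of peaks to return.
#' @param min_separation_mm minimum lateral separation between peaks (mm).
#' @param z_center optional depth (mm) around which to search.
#' @param z_band half-width (mm) of the search band (default 1.5 mm, a few
#'   axial pulse lengths: aligned marker peaks sit within a couple of
#'   samples of the reference depth).
#' @return data.frame with columns `x`, `z` (mm) and `value` (dB), one row
#'   per detected peak, ordered by `x`.
#' @export
image_peaks <- function(image, n = 2L, min_separation_mm = 5,
                        z_center = NULL, z_band = 1.5) {
  stopifnot(inherits(image, "bmode_image"))
  px <- image$pixels
  if (!is.null(z_center)) {
    rows <- which(abs(image$z_mm - z_center) <= z_band)
    if (length(rows) == 0) stop("empty depth band")
    px <- px[rows, , drop = FALSE]
  } else rows <- seq_len(nrow(image$pixels))
  prof <- apply(px, 2L, max)
  ord <- order(prof, decreasing = TRUE)
  sel <- integer(0)
  for (j in ord) {
    if (length(sel) >= n) break
    if (all(abs(image$x_mm[j] - image$x_mm[sel]) >= min_separation_mm))
      sel <- c(sel, j)
  }
  sel <- sel[order(image$x_mm[sel])]
  pk_rows <- vapply(sel, function(j) rows[which.max(px[, j])], integer(1))
  data.frame(x = image$x_mm[sel], z = image$z_mm[pk_rows],
             value = prof[sel])
}
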