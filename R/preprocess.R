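#' Depth gate window
#'
#' A pulse-echo depth band used to restrict normalization and peak search to
#' the marker region.  Depths are converted to sample indices with the
#' pulse-echo convention `n = round((2 z / c - t0) * fs) + 1`.
#'
#' @param z_min,z_max gate bounds in mm, `0 <= z_min < z_max`.  The default
#'   9--24 mm brackets an assistant structure of ~17 mm height sitting on
#'   the skin.
#' @return an object of class `"gate_window"`.
#' @export
gate_window <- function(z_min = 9, z_max = 24) {
  if (!is.numeric(z_min) || !is.numeric(z_max) || z_min < 0 || z_min >= z_max)
    stop("require 0 <= z_min < z_max")
  structure(list(z_min = z_min, z_max = z_max), class = "gate_window")
}

#' Convert a gate window to sample indices
#' @param gate a [gate_window()], or `NULL` for the whole trace.
#' @param fs sampling rate (Hz).
#' @param sound_speed m/s.
#' @param n_samples trace length.
#' @param t0 time of sample 1 (s).
#' @return integer vector of sample indices inside the gate.
#' @export
gate_samples <- function(gate, fs, sound_speed, n_samples, t0 = 0) {
  if (is.null(gate)) return(seq_len(n_samples))
  stopifnot(inherits(gate, "gate_window"))
  lo <- round((2 * gate$z_min / 1000 / sound_speed - t0) * fs) + 1
  hi <- round((2 * gate$z_max / 1000 / sound_speed - t0) * fs) + 1
  lo <- max(1L, as.integer(lo)); hi <- min(n_samples, as.integer(hi))
  if (lo > hi) stop("gate window is empty within the trace")
  lo:hi
}

#' Global RF normalization
#'
#' Divides the whole channel-data tensor by its maximum absolute sample, the
#' routine first normalization step before peak alignment.
#'
#' @param rf an `rf_data` object (or a bare numeric array).
#' @return the normalized object (max |sample| = 1).
#' @export
normalize_global <- function(rf) {
  x <- if (inherits(rf, "rf_data")) rf$data else rf
  m <- max(abs(range(x)))   # max |sample| without an abs() copy
  if (m == 0) stop("degenerate input: all samples are zero")
  if (inherits(rf, "rf_data")) { rf$data <- x / m; rf } else x / m
}

#' Gated RF normalization
#'
#' After routine global normalization, divides the tensor by the maximum
#' absolute sample inside a depth gate around the marker, so that the marker
#' echo (rather than a deeper, possibly stronger echo) has unit amplitude.
#'
#' @param rf an `rf_data` object.
#' @param gate a [gate_window()]; default 9--24 mm.
#' @return the normalized `rf_data` (max |sample| inside the gate = 1).
#' @export
normalize_gated <- function(rf, gate = gate_window()) {
  stopifnot(inherits(rf, "rf_data"))
  rf <- normalize_global(rf)
  idx <- gate_samples(gate, rf$fs, rf$sound_speed, dim(rf$data)[1], rf$t0)
  m <- max(abs(range(rf$data[idx, , , drop = FALSE])))
  if (m == 0) stop("degenerate input: gate band is all zero")
  rf$data <- rf$data / m
  rf
}

#' Smooth a single trace
#'
#' RF-trace smoothing used before peak detection.  The default is a
#' moving average (odd window, centred, edges shrunk); Savitzky--Golay is
#' available as an alternative.  `window = 1` is the identity.
#'
#' @param trace numeric vector.
#' @param method `"moving_average"` or `"savitzky_golay"`.
#' @param window odd integer, `1 <= window <= length(trace)`.
#' @param order polynomial order for Savitzky--Golay (default 2).
#' @return smoothed trace, same length.
#' @export
smooth_trace <- function(trace, method = c("moving_average", "savitzky_golay"),
                         window = 9L, order = 2L) {
  method <- match.arg(method)
  n <- length(trace)
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 1L || window > n)
    stop("window must be odd and within [1, length(trace)]")
  if (window == 1L) return(trace)
  if (method == "moving_average") {
    h <- window %/% 2L
    cs <- cumsum(c(0, trace))
    lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  } else {
    as.numeric(signal::sgolayfilt(trace, p = order, n = window))
  }
}

#' Savitzky--Golay smoothing of a delay curve
#'
#' Re-smooths a per-scanline delay curve along the scanline axis with a
#' Savitzky--Golay polynomial filter.  The default window of 21 is the
#' nearest odd value to the nominal window of 20 scanlines (a symmetric
#' filter needs an odd window); the default polynomial order is 2.
#'
#' @param curve numeric vector of per-scanline delays (samples).
#' @param window odd integer window, `<= length(curve)`; default 21.
#' @param order polynomial order; default 2.
#' @return smoothed curve, same length (not rounded).
#' @export
smooth_delay_curve <- function(curve, window = 21L, order = 2L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (length(curve) < window)
    stop("curve shorter than the smoothing window")
  as.numeric(signal::sgolayfilt(as.numeric(curve), p = order, n = window))
}
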