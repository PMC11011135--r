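#' Gaussian-modulated excitation pulse
#'
#' The simulator's pulse-echo waveform: a Gaussian-windowed cosine
#' `exp(-t^2 / (2 sigma_t^2)) * cos(2 pi f0 t)`.  The temporal width is set
#' from the -6 dB fractional bandwidth `bw = fractional_bandwidth * f0`
#' through `sigma_f = bw / (2 sqrt(2 log 2))`, `sigma_t = 1 / (2 pi sigma_f)`.
#'
#' @param center_frequency f0 in Hz (default 5 MHz).
#' @param fractional_bandwidth -6 dB fractional bandwidth, in (0, 2);
#'   default 0.6.
#' @param fs sampling rate in Hz (default 40 MHz); must exceed twice the
#'   centre frequency.
#' @return An object of class `"pulse"`: list with the parameters above plus
#'   `sigma_t` (s).
#' @export
gauss_pulse <- function(center_frequency = 5e6, fractional_bandwidth = 0.6,
                        fs = 40e6) {
  if (fractional_bandwidth <= 0 || fractional_bandwidth >= 2)
    stop("fractional_bandwidth must be in (0, 2)")
  if (fs <= 2 * center_frequency)
    stop("fs must exceed twice the centre frequency (Nyquist)")
  sigma_f <- fractional_bandwidth * center_frequency / (2 * sqrt(2 * log(2)))
  structure(list(center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth,
                 fs = fs, sigma_t = 1 / (2 * pi * sigma_f)),
            class = "pulse")
}

#' Evaluate the pulse waveform at given times
#' @param pulse a [gauss_pulse()].
#' @param t times in seconds (0 = pulse centre).
#' @return waveform samples.
#' @export
pulse_waveform <- function(pulse, t) {
  exp(-t^2 / (2 * pulse$sigma_t^2)) * cos(2 * pi * pulse$center_frequency * t)
}

#' Scatterer phantom
#'
#' A phantom is a set of point scatterers, each with a lateral position `x`
#' (mm), depth `z` (mm, > 0: scatterers lie below the aperture), a
#' dimensionless reflection amplitude, and an optional label
#' (`"marker"` or `"background"`).  Anechoic regions are represented by the
#' absence of scatterers, hypoechoic regions by reduced amplitudes.
#'
#' @param x,z scatterer positions in mm.
#' @param amplitude reflectivities (recycled).
#' @param label per-scatterer tags (recycled).
#' @return A `data.frame` of class `"phantom"` with columns
#'   `x`, `z`, `amplitude`, `label`.
#' @export
phantom <- function(x, z, amplitude = 1, label = "marker") {
  if (length(x) != length(z)) stop("x and z must have equal length")
  if (any(z <= 0)) stop("all scatterer depths must be > 0 (below the aperture)")
  if (any(!is.finite(amplitude))) stop("amplitudes must be finite")
  structure(data.frame(x = x, z = z,
                       amplitude = rep_len(amplitude, length(x)),
                       label = rep_len(label, length(x)),
                       stringsAsFactors = FALSE),
            class = c("phantom", "data.frame"))
}

#' Standard marker phantoms
#'
#' The package's stock phantoms mimicking an assistant structure with
#' embedded fiducial markers:
#' \describe{
#'   \item{`"center_point"`}{one point target at (0, 30) mm.}
#'   \item{`"two_points"`}{point targets at (-30, 30) and (30, 30) mm.}
#'   \item{`"right_point"`}{one point target at (30, 30) mm.}
#'   \item{`"scatter_cloud"`}{`n` seeded uniform background scatterers over
#'     `x_range` by `z_range`, with a circular target region (centre
#'     `target_xz`, radius `target_radius` mm) whose scatterers have their
#'     amplitude scaled by `target_contrast` (0 = anechoic, between 0 and 1
#'     = hypoechoic).}
#' }
#'
#' @param kind one of `"center_point"`, `"two_points"`, `"right_point"`,
#'   `"scatter_cloud"`.
#' @param n number of scatterers for `"scatter_cloud"` (default 10000).
#' @param x_range,z_range cloud extents in mm.
#' @param target_xz centre of the embedded circular target (mm).
#' @param target_radius radius of the target disc (mm).
#' @param target_contrast amplitude scale inside the disc (0 = anechoic).
#' @param amplitude marker reflectivity for the point phantoms.
#' @param seed RNG seed for the scatter cloud (required for it).
#' @return a [phantom()].
#' @export
marker_phantom <- function(kind = c("center_point", "two_points",
                                    "right_point", "scatter_cloud"),
                           n = 10000L,
                           x_range = c(-40, 40), z_range = c(20, 60),
                           target_xz = c(0, 40), target_radius = 5,
                           target_contrast = 0, amplitude = 1, seed = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    center_point = phantom(0, 30, amplitude),
    two_points   = phantom(c(-30, 30), c(30, 30), amplitude),
    right_point  = phantom(30, 30, amplitude),
    scatter_cloud = {
      if (is.null(seed)) stop("scatter_cloud requires a seed")
      set.seed(seed)
      x <- stats::runif(n, x_range[1], x_range[2])
      z <- stats::runif(n, z_range[1], z_range[2])
      a <- rep(amplitude, n)
      inside <- (x - target_xz[1])^2 + (z - target_xz[2])^2 <= target_radius^2
      a[inside] <- a[inside] * target_contrast
      phantom(x, z, a, label = "background")
    })
}

#' Simulate RF channel data from a phantom
#'
#' A desk-scale time-of-flight simulator: one transmit element per scanline,
#' all elements receiving.  For every scanline `s` (transmit element
#' `tx_map[s]`), receive element `r` and scatterer `k`, a replica of the
#' excitation pulse is added to the trace, centred at the two-way
#' time of flight and weighted by `amplitude_k / (r_tx * r_rx)` (spherical
#' spreading, distances in mm), optionally multiplied by a cosine element
#' directivity on each leg.  Optional white Gaussian noise is added last.
#'
#' This intentionally omits full spatial-impulse-response physics
#' (element surface integration, elevation aperture, nonlinearity); it
#' reproduces arrival times exactly and relative amplitudes to first order,
#' which is what peak-alignment delay estimation depends on.
#'
#' @param phantom a [phantom()].
#' @param geometry an [array_geometry()].
#' @param pulse a [gauss_pulse()]; its `fs` is the data sampling rate.
#' @param sound_speed m/s, default 1540.
#' @param tx_map integer vector: transmit element of each scanline.  Default
#'   the identity map (scanline s transmits on element s).
#' @param n_samples trace length; default covers the deepest echo plus the
#'   pulse tail.
#' @param t0 time of sample 1 relative to transmit (s), default 0.
#' @param noise_level standard deviation of additive white Gaussian noise
#'   (same units as the echo amplitudes); requires `seed` when > 0.
#' @param seed RNG seed for the noise.
#' @param directivity if `TRUE`, apply a cosine obliquity factor per leg
#'   (angle between the element normal and the scatterer direction).
#' @return An object of class `"rf_data"`: list with `data` (array
#'   `n_samples x n_elements x n_scanlines`), `fs`, `t0`, `sound_speed`,
#'   `tx_map`, `geometry`.
#' @export
simulate_rf <- function(phantom, geometry, pulse = gauss_pulse(),
                        sound_speed = 1540,
                        tx_map = seq_len(geometry$n_elements),
                        n_samples = NULL, t0 = 0,
                        noise_level = 0, seed = NULL,
                        directivity = FALSE) {
  stopifnot(inherits(geometry, "array_geometry"), inherits(pulse, "pulse"))
  if (noise_level > 0 && is.null(seed))
    stop("seed is required when noise_level > 0")
  fs <- pulse$fs
  n_el <- geometry$n_elements
  n_sc <- length(tx_map)
  tx_map <- as.integer(tx_map)
  if (any(tx_map < 1L | tx_map > n_el)) stop("tx_map index out of range")

  ex <- geometry$element_x; ez <- geometry$element_z
  K <- nrow(phantom)
  tail_s <- 4 * pulse$sigma_t
  if (is.null(n_samples)) {
    if (K == 0) {
      n_samples <- 1024L
    } else {
      # worst-case two-way path over all element pairs
      dmax <- 0
      for (k in seq_len(K)) {
        d <- sqrt((phantom$x[k] - ex)^2 + (phantom$z[k] - ez)^2)
        dmax <- max(dmax, max(d))
      }
      n_samples <- as.integer(ceiling((2 * dmax / 1000 / sound_speed +
                                         tail_s - t0) * fs) + 8L)
    }
  }
  n_samples <- as.integer(n_samples)

  data <- array(0, dim = c(n_samples, n_el, n_sc))
  if (K > 0) {
    # earliest possible echo centre; used for the too-short validation
    any_echo <- FALSE
    sig <- pulse$sigma_t
    f0 <- pulse$center_frequency
    for (s in seq_len(n_sc)) {
      txe <- tx_map[s]
      dx_tx <- phantom$x - ex[txe]; dz_tx <- phantom$z - ez[txe]
      d_tx <- sqrt(dx_tx^2 + dz_tx^2)           # mm, per scatterer
      w_tx <- rep(1, K)
      if (directivity) w_tx <- pmax(0, dz_tx / pmax(d_tx, 1e-12))
      for (r in seq_len(n_el)) {
        dx_rx <- phantom$x - ex[r]; dz_rx <- phantom$z - ez[r]
        d_rx <- sqrt(dx_rx^2 + dz_rx^2)
        tau <- (d_tx + d_rx) / 1000 / sound_speed
        amp <- phantom$amplitude / pmax(d_tx * d_rx, 1e-12)
        if (directivity)
          amp <- amp * w_tx * pmax(0, dz_rx / pmax(d_rx, 1e-12))
        trace <- data[, r, s]
        for (k in seq_len(K)) {
          if (amp[k] == 0) next
          n_lo <- max(1L, floor((tau[k] - tail_s - t0) * fs) + 1L)
          n_hi <- min(n_samples, ceiling((tau[k] + tail_s - t0) * fs) + 1L)
          if (n_lo > n_samples) next
          if (n_hi < 1L) next
          any_echo <- TRUE
          idx <- n_lo:n_hi
          tt <- t0 + (idx - 1) / fs - tau[k]
          trace[idx] <- trace[idx] +
            amp[k] * exp(-tt^2 / (2 * sig^2)) * cos(2 * pi * f0 * tt)
        }
        data[, r, s] <- trace
      }
    }
    if (!any_echo)
      stop("n_samples too small: no echo falls inside the trace")
  }
  if (noise_level > 0) {
    set.seed(seed)
    data <- data + stats::rnorm(length(data), 0, noise_level)
  }
  structure(list(data = data, fs = fs, t0 = t0, sound_speed = sound_speed,
                 tx_map = tx_map, geometry = geometry, pulse = pulse),
            class = "rf_data")
}

#' @export
print.rf_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<rf_data> %d samples x %d elements x %d scanlines, fs %.3g MHz, c %g m/s\n",
    d[1], d[2], d[3], x$fs / 1e6, x$sound_speed))
  if (!is.null(x$geometry)) cat("  geometry:", x$geometry$shape, "\n")
  else cat("  geometry: unknown (shape-blind data)\n")
  invisible(x)
}

#' Add seeded white Gaussian noise to RF data
#'
#' @param rf an `rf_data` object.
#' @param noise_level noise standard deviation (absolute, same units as the
#'   data), or relative to the data's max absolute sample when
#'   `relative = TRUE`.
#' @param seed RNG seed (required).
#' @param relative interpret `noise_level` as a fraction of `max(|data|)`.
#' @return the noisy `rf_data`.
#' @export
add_noise <- function(rf, noise_level, seed, relative = FALSE) {
  stopifnot(inherits(rf, "rf_data"))
  if (missing(seed)) stop("seed is required")
  if (noise_level < 0) stop("noise_level must be >= 0")
  if (noise_level == 0) return(rf)
  sd_abs <- if (relative) noise_level * max(abs(rf$data)) else noise_level
  set.seed(seed)
  rf$data <- rf$data + stats::rnorm(length(rf$data), 0, sd_abs)
  rf
}

#' Artificially curve flat-acquisition RF data
#'
#' Re-delays RF channel data recorded (or simulated) with a flat array so
#' that it looks as if it had been acquired with a deformed array of the
#' given target geometry.  For every scanline/element pair the channel trace
#' is resampled with a depth-dependent time shift
#' `dt = tof_curved - tof_flat`, evaluated at one focal point per depth
#' sample along the scanline axis (the vertical line through the transmit
#' element's flat position).  The output's geometry field is the target
#' geometry, so the curved data can be beamformed with a geometry-aware DAS
#' to validate the construction.
#'
#' @param rf_flat `rf_data` carrying a flat geometry.
#' @param target_geometry [array_geometry()] with the same element count.
#' @param interp `"spline"` (default; cubic resampling, needed to keep the
#'   round-trip error at the sub-dB level for RF sampled at a few samples
#'   per wavelength), `"linear"`, or `"nearest"` (integer sample shifts;
#'   exact for integer delays).
#' @return the curved `rf_data`.
#' @export
curve_rf <- function(rf_flat, target_geometry,
                     interp = c("spline", "linear", "nearest")) {
  stopifnot(inherits(rf_flat, "rf_data"),
            inherits(target_geometry, "array_geometry"))
  interp <- match.arg(interp)
  src <- rf_flat$geometry
  if (is.null(src)) stop("rf_flat must carry its (flat) geometry")
  if (src$n_elements != target_geometry$n_elements)
    stop("element counts differ between source and target geometry")
  n_samples <- dim(rf_flat$data)[1]
  n_el <- dim(rf_flat$data)[2]
  n_sc <- dim(rf_flat$data)[3]
  fs <- rf_flat$fs; t0 <- rf_flat$t0; c0 <- rf_flat$sound_speed
  t_axis <- t0 + (seq_len(n_samples) - 1) / fs
  # focal depth grid: one point per sample via on-axis pulse-echo depth
  z_grid <- pmax(c0 * t_axis / 2 * 1000, 1e-6)   # mm
  out <- rf_flat
  for (s in seq_len(n_sc)) {
    txe <- rf_flat$tx_map[s]
    x_axis <- src$element_x[txe]                 # scanline axis (flat frame)
    pts <- cbind(rep(x_axis, n_samples), z_grid)
    for (e in seq_len(n_el)) {
      tau_f <- tof(src, txe, e, pts, c0)
      tau_c <- tof(target_geometry, txe, e, pts, c0)
      # associate output time t with the focal point whose *curved* ToF is t,
      # so that reading the curved data at tof_curved recovers the flat data
      # at tof_flat (round-trip consistency with the curved-geometry DAS)
      dt <- stats::approx(tau_c, tau_c - tau_f, xout = t_axis,
                          rule = 2)$y
      t_src <- t_axis - dt
      trace <- rf_flat$data[, e, s]
      out$data[, e, s] <- switch(interp,
        linear  = stats::approx(t_axis, trace, xout = t_src,
                                yleft = 0, yright = 0)$y,
        spline  = {
          y <- stats::spline(t_axis, trace, xout = t_src)$y
          y[t_src < t_axis[1] | t_src > t_axis[n_samples]] <- 0
          y
        },
        nearest = {
          idx <- round((t_src - t0) * fs) + 1
          ok <- idx >= 1 & idx <= n_samples
          y <- numeric(n_samples)
          y[ok] <- trace[idx[ok]]
          y
        })
    }
  }
  out$geometry <- target_geometry
  out
}
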