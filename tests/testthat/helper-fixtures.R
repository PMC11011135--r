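# Shared fixture builders: everything is generated in code at test time.

# a small flat aperture for fast unit tests
small_flat <- function(n = 32L, pitch = 1) array_geometry("flat", n, pitch)

# simulated RF for a single marker on a small flat aperture
small_marker_rf <- function(n = 32L, marker = c(0, 17), fs = 40e6, ...) {
  simulate_rf(phantom(marker[1], marker[2]), small_flat(n),
              gauss_pulse(fs = fs), ...)
}

# hand-built rf_data from a trace matrix [n_samples x n_scanlines]:
# every scanline has n_el identical copies of its trace (or per-element
# traces when `per_element` is an array [n_samples x n_el x n_sc])
rf_from_traces <- function(traces, n_el = 1L, fs = 40e6, sound_speed = 1540,
                           t0 = 0, geometry = NULL, per_element = NULL) {
  if (!is.null(per_element)) {
    data <- per_element
  } else {
    traces <- as.matrix(traces)
    n_sa <- nrow(traces); n_sc <- ncol(traces)
    data <- array(0, dim = c(n_sa, n_el, n_sc))
    for (s in seq_len(n_sc)) for (e in seq_len(n_el))
      data[, e, s] <- traces[, s]
  }
  n_sc <- dim(data)[3]
  structure(list(data = data, fs = fs, t0 = t0, sound_speed = sound_speed,
                 tx_map = pmin(seq_len(n_sc), dim(data)[2]),
                 geometry = geometry),
            class = "rf_data")
}

# a Gaussian-modulated pulse echo centred at a given sample
pulse_trace <- function(n_samples, center_sample, fs = 40e6, f0 = 5e6,
                        sigma_t = 1 / (2 * pi * (0.6 * f0 / (2 * sqrt(2 * log(2))))),
                        amp = 1) {
  t <- (seq_len(n_samples) - center_sample) / fs
  amp * exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * f0 * t)
}
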