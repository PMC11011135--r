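#' Gated peak sample of a trace
#'
#' Finds the sample index of the peak echo: the argmax of the (optionally
#' smoothed) envelope magnitude inside the gate.  Ties are broken toward the
#' earliest sample (values within 1e-9 relative of the maximum count as
#' tied).
#'
#' @param trace numeric RF trace.
#' @param gate_idx integer sample indices to search (default: whole trace).
#' @param smooth_window odd moving-average window applied to the envelope
#'   before the argmax (1 = no smoothing).
#' @return integer sample index (into the full trace).  Throws an error of
#'   class `"flexbeam_no_peak"` when the gated segment is all zero.
#' @export
peak_sample <- function(trace, gate_idx = NULL, smooth_window = 9L) {
  if (is.null(gate_idx)) gate_idx <- seq_along(trace)
  env <- envelope(trace)
  if (smooth_window > 1L) env <- smooth_trace(env, window = smooth_window)
  seg <- env[gate_idx]
  m <- max(seg)
  if (m <= 0 || all(abs(trace[gate_idx]) == 0))
    stop(structure(class = c("flexbeam_no_peak", "error", "condition"),
                   list(message = "no peak: gated segment is all zero",
                        call = sys.call(-1))))
  gate_idx[which(seg >= m * (1 - 1e-9))[1]]
}

# fill NA entries from the nearest valid neighbour (ties -> earlier side)
fill_from_neighbours <- function(x) {
  bad <- which(is.na(x)); ok <- which(!is.na(x))
  if (length(ok) == 0L) return(x)
  for (i in bad) x[i] <- x[ok[which.min(abs(ok - i))]]
  x
}

resolve_reference <- function(reference, peaks_strength, n_sc) {
  if (is.numeric(reference)) {
    r <- as.integer(reference)
    if (r < 1L || r > n_sc) stop("reference scanline index out of range")
    return(r)
  }
  switch(match.arg(reference, c("first", "center", "strongest")),
         first = 1L,
         center = as.integer(ceiling(n_sc / 2)),
         strongest = which.max(peaks_strength))
}

#' First-round APR: per-scanline reference delays
#'
#' For each scanline the trace received by its own transmitting element is
#' the scanline's reference trace.  Its gated peak sample `p_s` is aligned
#' to the reference scanline's peak: `round1[s] = p_ref - p_s`, so a
#' positive delay means the trace must be shifted later in time.
#'
#' @param rf an `rf_data` object.
#' @param gate a [gate_window()] or `NULL` (whole trace).
#' @param reference `"first"` (default), `"center"`, `"strongest"` (scanline
#'   with the largest gated envelope), or an integer index.
#' @param smooth_window envelope moving-average window (see [peak_sample()]).
#' @return list with `delays` (integer per scanline), `peaks` (peak sample
#'   per scanline), `reference` (resolved index) and `n_substituted`
#'   (scanlines whose peak was missing and whose delay was copied from the
#'   nearest valid neighbour).
#' @export
apr_round1 <- function(rf, gate = NULL, reference = "first",
                       smooth_window = 9L) {
  stopifnot(inherits(rf, "rf_data"))
  n_sc <- dim(rf$data)[3]
  gidx <- gate_samples(gate, rf$fs, rf$sound_speed, dim(rf$data)[1], rf$t0)
  mp <- matrix_peaks(tx_traces(rf), gidx, smooth_window)
  peaks <- mp$peaks; strength <- mp$strength
  ref <- resolve_reference(reference, strength, n_sc)
  if (is.na(peaks[ref]))
    stop("no peak found on the reference scanline (", ref, "): fatal")
  n_sub <- sum(is.na(peaks))
  if (n_sub > 0) {
    warning(n_sub, " scanline(s) had no gated peak; delay copied from the ",
            "nearest valid neighbour")
    peaks <- fill_from_neighbours(peaks)
  }
  list(delays = as.integer(peaks[ref] - peaks), peaks = peaks,
       reference = ref, n_substituted = n_sub)
}

#' Second-round APR: per-element receive delays with outlier clamping
#'
#' Within each scanline (after the first-round delays have been applied),
#' each element's gated peak is aligned to the transmitting element's trace:
#' `round2[s, e] = p_[s, tx] - p_[s, e]`.  Element-to-element delay
#' increments whose magnitude exceeds `threshold` are clamped to the
#' threshold-bounded value relative to the previous valid element, walking
#' outward from the transmit element in both directions; this suppresses
#' isolated misdetections caused by noise or clutter.
#'
#' @param rf an `rf_data` object with first-round delays already applied.
#' @param gate a [gate_window()] or `NULL`.
#' @param threshold maximum allowed element-to-element increment in samples
#'   (>= 0; default 5; `Inf` disables clamping).
#' @param smooth_window envelope moving-average window.
#' @return list with `delays` (n_scanlines x n_elements integer matrix) and
#'   `n_substituted` (columns whose peak was missing; delay copied from the
#'   inner neighbour).
#' @export
apr_round2 <- function(rf, gate = NULL, threshold = 5, smooth_window = 9L) {
  stopifnot(inherits(rf, "rf_data"))
  if (threshold < 0) stop("threshold must be >= 0")
  dims <- dim(rf$data)
  n_el <- dims[2]; n_sc <- dims[3]
  gidx <- gate_samples(gate, rf$fs, rf$sound_speed, dims[1], rf$t0)
  delays <- matrix(0L, n_sc, n_el)
  n_sub <- 0L
  for (s in seq_len(n_sc)) {
    txe <- rf$tx_map[s]
    p <- matrix_peaks(matrix(rf$data[, , s], nrow = dims[1]), gidx,
                      smooth_window)$peaks
    if (is.na(p[txe]))
      stop("no peak on the transmit element's trace of scanline ", s)
    raw <- p[txe] - p                 # receive delay per element
    d <- rep(0L, n_el)
    walk <- function(idx_seq) {
      prev <- 0L
      for (e in idx_seq) {
        if (is.na(raw[e])) {
          n_sub <<- n_sub + 1L
          d[e] <<- prev               # copy inner neighbour
        } else {
          inc <- raw[e] - prev
          if (abs(inc) > threshold) inc <- sign(inc) * threshold
          d[e] <<- as.integer(prev + inc)
        }
        prev <- d[e]
      }
    }
    if (txe < n_el) walk((txe + 1L):n_el)
    if (txe > 1L) walk((txe - 1L):1L)
    delays[s, ] <- d
  }
  if (n_sub > 0)
    warning(n_sub, " element trace(s) had no gated peak; delay copied from ",
            "the inner neighbour")
  list(delays = delays, n_substituted = n_sub)
}

#' Fit APR delay curves to RF channel data
#'
#' The central estimator of the package: two-round Aligned Peak Response
#' delay estimation.  The first round aligns, per scanline, the gated peak
#' echo of the trace received by the scanline's own transmitting element to
#' the reference scanline's peak.  The resulting per-scanline delay curve
#' is Savitzky--Golay re-smoothed (optional), applied, and a second round is
#' run:
#' \describe{
#'   \item{`mode = "simulation"`}{the second round re-aligns the scanline
#'     reference traces once more and folds the residual into the
#'     per-scanline curve (per-element receive delays stay zero).  This is
#'     the protocol appropriate for clean simulated data.}
#'   \item{`mode = "experimental"`}{the second round aligns every receive
#'     element's trace to the transmitting element's trace within each
#'     scanline, with increment clamping at `threshold` (see
#'     [apr_round2()]).  This is the protocol for recorded data with
#'     clutter and noise.}
#' }
#' Total delays are `total[s, e] = round1[s] + round2[s, e]`, in integer
#' samples; a positive delay shifts a trace later in time, so
#' `apply_delays(rf, fit)` aligns all peaks at the reference scanline's
#' peak sample.
#'
#' @param rf an `rf_data` object.
#' @param gate a [gate_window()] restricting normalization and peak search
#'   to the marker depth band, or `NULL` (default) for the whole trace.
#' @param reference reference scanline: `"first"` (default), `"center"`,
#'   `"strongest"`, or an integer index.
#' @param mode `"simulation"` (default) or `"experimental"`; see above.
#' @param threshold increment clamp for the experimental second round, in
#'   samples (default 5; `Inf` disables).
#' @param smooth_window envelope moving-average window for peak detection
#'   (odd; default 9; 1 disables).
#' @param curve_smooth logical: Savitzky--Golay re-smooth the first-round
#'   delay curve (default `TRUE`).
#' @param sg_window,sg_order Savitzky--Golay window (odd; default 21) and
#'   polynomial order (default 2) for the delay-curve re-smoothing.
#' @param normalize logical: run global (and, when `gate` is given, gated)
#'   normalization first (default `TRUE`).
#' @return An object of class `"apr"`: list with elements `round1` (integer
#'   per scanline), `round2` (integer n_scanlines x n_elements matrix),
#'   `total` (their sum), `reference_scanline`, `gate`, `mode`, `threshold`,
#'   `residuals` (post-alignment per-scanline peak misalignment, samples),
#'   `peaks` (first-round peak samples), `n_substituted`, `fs`, `call`.
#' @seealso [apply_delays()], [beamform_apr()], [oracle_delays()]
#' @examples
#' g <- array_geometry("flat", 32, 1)
#' rf <- simulate_rf(phantom(0, 15), g, gauss_pulse(fs = 20e6))
#' fit <- apr(rf, reference = "strongest")
#' fit
#' head(coef(fit, "round1"))
#' @export
apr <- function(rf, gate = NULL, reference = "first",
                mode = c("simulation", "experimental"),
                threshold = 5, smooth_window = 9L,
                curve_smooth = TRUE, sg_window = 21L, sg_order = 2L,
                normalize = TRUE) {
  stopifnot(inherits(rf, "rf_data"))
  mode <- match.arg(mode)
  cl <- match.call()
  if (normalize) {
    rf <- if (is.null(gate)) normalize_global(rf) else normalize_gated(rf, gate)
  }
  n_sc <- dim(rf$data)[3]; n_el <- dim(rf$data)[2]
  gidx <- gate_samples(gate, rf$fs, rf$sound_speed, dim(rf$data)[1], rf$t0)

  tx_mat <- tx_traces(rf)
  mp <- matrix_peaks(tx_mat, gidx, smooth_window)
  ref <- resolve_reference(reference, mp$strength, n_sc)
  if (is.na(mp$peaks[ref]))
    stop("no peak found on the reference scanline (", ref, "): fatal")
  n_sub <- sum(is.na(mp$peaks))
  if (n_sub > 0) {
    warning(n_sub, " scanline(s) had no gated peak; delay copied from the ",
            "nearest valid neighbour")
    mp$peaks <- fill_from_neighbours(mp$peaks)
  }
  peaks1 <- mp$peaks
  round1 <- as.integer(peaks1[ref] - peaks1)
  if (curve_smooth && length(round1) >= 5) {
    w <- min(as.integer(sg_window), length(round1))
    if (w %% 2L == 0L) w <- w - 1L
    if (w > sg_order + 1L) {
      sm <- round(smooth_delay_curve(round1, window = w, order = sg_order))
      round1 <- as.integer(sm - sm[ref])   # keep round1[reference] == 0
    }
  }

  realign <- function(delays) {
    # residual per-scanline misalignment after applying `delays`
    mpx <- matrix_peaks(shift_matrix_cols(tx_mat, delays), gidx,
                        smooth_window)
    p <- fill_from_neighbours(mpx$peaks)
    if (is.na(p[ref])) stop("reference peak lost during re-alignment")
    as.integer(p[ref] - p)
  }
  if (mode == "simulation") {
    round1 <- as.integer(round1 + realign(round1))
    round2 <- matrix(0L, n_sc, n_el)
  } else {
    rf1 <- apply_delays(rf, round1)
    r2 <- apr_round2(rf1, gate, threshold, smooth_window)
    round2 <- r2$delays
    n_sub <- n_sub + r2$n_substituted
  }
  resid <- -realign(round1)
  total <- sweep(round2, 1L, -as.integer(round1))  # round1[s] + round2[s,e]
  storage.mode(total) <- "integer"

  structure(list(round1 = round1, round2 = round2, total = total,
                 reference_scanline = ref, gate = gate, mode = mode,
                 threshold = threshold, residuals = as.numeric(resid),
                 peaks = peaks1, n_substituted = n_sub,
                 fs = rf$fs, call = cl),
            class = "apr")
}

#' @export
print.apr <- function(x, ...) {
  cat("Aligned Peak Response delay fit\n")
  cat(sprintf("  mode: %s   reference scanline: %d   scanlines: %d\n",
              x$mode, x$reference_scanline, length(x$round1)))
  cat(sprintf("  round-1 delays: [%d, %d] samples\n",
              min(x$round1), max(x$round1)))
  if (any(x$round2 != 0L))
    cat(sprintf("  round-2 delays: [%d, %d] samples (threshold %g)\n",
                min(x$round2), max(x$round2), x$threshold))
  if (x$n_substituted > 0)
    cat("  no-peak substitutions:", x$n_substituted, "\n")
  invisible(x)
}

#' @export
summary.apr <- function(object, ...) {
  s <- list(mode = object$mode,
            reference = object$reference_scanline,
            n_scanlines = length(object$round1),
            round1 = summary(object$round1),
            round2_range = range(object$round2),
            mean_abs_residual = mean(abs(object$residuals)),
            n_substituted = object$n_substituted)
  class(s) <- "summary.apr"
  s
}

#' @export
print.summary.apr <- function(x, ...) {
  cat("APR delay fit (", x$mode, " mode), ", x$n_scanlines,
      " scanlines, reference ", x$reference, "\n", sep = "")
  cat("Round-1 delay curve (samples):\n"); print(x$round1)
  cat(sprintf("Round-2 range: [%d, %d] samples\n",
              x$round2_range[1], x$round2_range[2]))
  cat(sprintf("Mean |post-alignment residual|: %.3f samples\n",
              x$mean_abs_residual))
  if (x$n_substituted > 0)
    cat("No-peak substitutions:", x$n_substituted, "\n")
  invisible(x)
}

#' Extract APR delay curves
#' @param object an [apr()] fit.
#' @param type `"total"` (default; n_scanlines x n_elements matrix),
#'   `"round1"` (per-scanline vector) or `"round2"` (matrix).
#' @param ... unused.
#' @return integer vector or matrix of delays in samples.
#' @export
coef.apr <- function(object, type = c("total", "round1", "round2"), ...) {
  switch(match.arg(type), total = object$total,
         round1 = object$round1, round2 = object$round2)
}

#' @export
residuals.apr <- function(object, ...) object$residuals

#' @export
plot.apr <- function(x, ...) {
  op <- graphics::par(no.readonly = TRUE); on.exit(graphics::par(op))
  if (any(x$round2 != 0L)) graphics::par(mfrow = c(1, 2))
  graphics::plot(seq_along(x$round1), x$round1, type = "l",
                 xlab = "scanline", ylab = "delay (samples)",
                 main = "Round-1 delay curve", ...)
  graphics::abline(v = x$reference_scanline, lty = 3)
  if (any(x$round2 != 0L))
    graphics::image(seq_len(nrow(x$round2)), seq_len(ncol(x$round2)),
                    x$round2, xlab = "scanline", ylab = "element",
                    main = "Round-2 delays (samples)")
  invisible(x)
}

#' Apply integer-sample delays to RF channel data
#'
#' Shifts each channel trace by its delay: positive delays move the trace
#' later in time (zero-padding the vacated start), negative earlier.
#'
#' @param rf an `rf_data` object.
#' @param delays an [apr()] fit (its total delays are used), a per-scanline
#'   vector, or an n_scanlines x n_elements matrix, in samples.
#' @return the delayed `rf_data` (same shape).
#' @export
apply_delays <- function(rf, delays) {
  stopifnot(inherits(rf, "rf_data"))
  dims <- dim(rf$data)
  n_sa <- dims[1]; n_el <- dims[2]; n_sc <- dims[3]
  if (inherits(delays, "apr")) delays <- delays$total
  if (is.matrix(delays)) {
    if (!all(dim(delays) == c(n_sc, n_el)))
      stop("delay matrix must be n_scanlines x n_elements")
    D <- delays
  } else {
    if (length(delays) != n_sc)
      stop("per-scanline delays must have length n_scanlines")
    D <- matrix(rep(as.integer(delays), n_el), n_sc, n_el)
  }
  if (any(abs(D) >= n_sa)) stop("|delay| must be < n_samples")
  out <- rf
  for (s in seq_len(n_sc)) {
    ds <- D[s, ]
    if (all(ds == 0L)) next
    out$data[, , s] <- shift_matrix_cols(matrix(rf$data[, , s], nrow = n_sa),
                                         ds)
  }
  out
}

# shift each column of a matrix by its integer delay (positive = later),
# zero-padding the vacated end
shift_matrix_cols <- function(m, d) {
  n <- nrow(m)
  if (all(d == d[1])) {
    dj <- d[1]
    if (dj == 0) return(m)
    out <- matrix(0, n, ncol(m))
    if (dj > 0) out[(dj + 1):n, ] <- m[1:(n - dj), ]
    else out[1:(n + dj), ] <- m[(1 - dj):n, ]
    return(out)
  }
  out <- m
  for (j in seq_len(ncol(m))) {
    dj <- d[j]
    if (dj == 0) next
    y <- numeric(n)
    if (dj > 0) y[(dj + 1):n] <- m[1:(n - dj), j]
    else y[1:(n + dj)] <- m[(1 - dj):n, j]
    out[, j] <- y
  }
  out
}

# the per-scanline reference traces (received by each scanline's tx element)
tx_traces <- function(rf) {
  n_sc <- dim(rf$data)[3]
  vapply(seq_len(n_sc), function(s) rf$data[, rf$tx_map[s], s],
         numeric(dim(rf$data)[1]))
}

# gated peak sample per column of a trace matrix (envelope + smoothing),
# NA where the gated segment is all zero
matrix_peaks <- function(mat, gidx, smooth_window = 9L) {
  env <- envelope(mat)
  n_c <- ncol(mat)
  peaks <- rep(NA_integer_, n_c)
  strength <- numeric(n_c)
  for (j in seq_len(n_c)) {
    if (all(mat[gidx, j] == 0)) next
    e <- if (smooth_window > 1L)
      smooth_trace(env[, j], window = smooth_window) else env[, j]
    seg <- e[gidx]
    m <- max(seg)
    if (m <= 0) next
    peaks[j] <- gidx[which(seg >= m * (1 - 1e-9))[1]]
    strength[j] <- max(env[gidx, j])
  }
  list(peaks = peaks, strength = strength)
}

#' Geometric ground-truth delay curves
#'
#' The delays a known geometry implies for a single marker: the curve an
#' ideal APR fit should recover.  Per scanline `s` (transmit element
#' `tx_map[s]`) the reference-trace arrival is
#' `tau(s) = tof(geometry, tx_s, tx_s, marker)`; per element,
#' `tau(s, e) = tof(geometry, tx_s, e, marker)`.  Delays are expressed
#' relative to the reference scanline's arrival:
#' `round1[s] = (tau(ref) - tau(s)) * fs`,
#' `total[s, e] = (tau(ref) - tau(s, e)) * fs`.
#'
#' @param geometry an [array_geometry()].
#' @param marker_xz length-2 marker position `c(x, z)` in mm.
#' @param fs sampling rate (Hz).
#' @param sound_speed m/s.
#' @param tx_map transmit element per scanline (default identity).
#' @param reference reference scanline index (default 1).
#' @return list with `round1` (numeric per scanline, in samples, not
#'   rounded), `round2` (matrix of receive-delay differences) and `total`.
#' @export
oracle_delays <- function(geometry, marker_xz, fs, sound_speed = 1540,
                          tx_map = seq_len(geometry$n_elements),
                          reference = 1L) {
  stopifnot(inherits(geometry, "array_geometry"))
  n_sc <- length(tx_map); n_el <- geometry$n_elements
  tau_self <- vapply(seq_len(n_sc), function(s)
    tof(geometry, tx_map[s], tx_map[s], marker_xz, sound_speed), numeric(1))
  tau_ref <- tau_self[reference]
  round1 <- (tau_ref - tau_self) * fs
  total <- matrix(0, n_sc, n_el)
  for (s in seq_len(n_sc)) {
    tau_se <- vapply(seq_len(n_el), function(e)
      tof(geometry, tx_map[s], e, marker_xz, sound_speed), numeric(1))
    total[s, ] <- (tau_ref - tau_se) * fs
  }
  list(round1 = round1, round2 = total - round1, total = total)
}
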