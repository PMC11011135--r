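test_that("peak_sample finds gated envelope maxima with earliest-tie rule", {
  tr <- numeric(300); tr[100] <- 1
  expect_equal(peak_sample(tr, smooth_window = 1), 100L)
  # two identical pulses: the earlier one wins the tie
  tr2 <- pulse_trace(300, 90) + pulse_trace(300, 110)
  expect_equal(peak_sample(tr2, smooth_window = 1), 90L)
  # gating can exclude the earlier peak
  expect_equal(peak_sample(tr2, gate_idx = 101:300, smooth_window = 1), 110L)
  expect_error(peak_sample(numeric(50)), class = "flexbeam_no_peak")
})

test_that("round 1 aligns constructed shifts exactly", {
  n_sc <- 12
  base <- pulse_trace(600, 200)
  shifts <- c(0, 3, -5, 10, 0, 7, -2, 15, 4, -8, 1, 6)
  traces <- vapply(shifts, function(k) pulse_trace(600, 200 + k),
                   numeric(600))
  rf <- rf_from_traces(traces, n_el = n_sc)
  r1 <- apr_round1(rf, reference = 1)
  expect_equal(r1$delays, as.integer(-shifts))
  expect_equal(r1$reference, 1L)
  expect_equal(r1$delays[1], 0L)
  # identical traces give all-zero delays
  rf0 <- rf_from_traces(vapply(1:5, function(i) base, numeric(600)),
                        n_el = 5)
  expect_equal(apr_round1(rf0)$delays, rep(0L, 5))
})

test_that("round 1 matches geometric delays for a simulated marker", {
  g <- small_flat(32)
  rf <- simulate_rf(phantom(0, 17), g, gauss_pulse())
  r1 <- apr_round1(rf, reference = 1)
  orc <- oracle_delays(g, c(0, 17), rf$fs, reference = 1)
  expect_lte(mean(abs(r1$delays - orc$round1)), 1)
})

test_that("round 2 clamps element-to-element increments at the threshold", {
  # one scanline, 7 elements, all peaks aligned except element 5 (+9 samples)
  n_el <- 7
  data <- array(0, dim = c(400, n_el, 1))
  for (e in 1:n_el) data[, e, 1] <- pulse_trace(400, 150 + 9 * (e == 5))
  rf <- rf_from_traces(NULL, per_element = data)
  rf$tx_map <- 3L   # transmit element 3
  r2 <- apr_round2(rf, threshold = 5)
  d <- r2$delays[1, ]
  expect_equal(d[3], 0L)                         # tx element is its own ref
  expect_equal(d[5], -5L)                        # clamped from -9 to -5
  expect_true(all(abs(diff(d)) <= 5))
  # without clamping the raw displacement is recovered
  r2i <- apr_round2(rf, threshold = Inf)
  expect_equal(r2i$delays[1, 5], -9L)
  expect_equal(r2i$delays[1, -5], rep(0L, n_el - 1))
  # perfectly aligned scanline gives all zeros
  for (e in 1:n_el) data[, e, 1] <- pulse_trace(400, 150)
  rf0 <- rf_from_traces(NULL, per_element = data); rf0$tx_map <- 3L
  expect_equal(apr_round2(rf0)$delays[1, ], rep(0L, n_el))
})

test_that("round 2 recovers per-element receive delays on an arc", {
  g <- array_geometry("arc", 32, 1, radius = 700)
  # headroom beyond the deepest echo so that applying the (edge-referenced)
  # first-round delays cannot clip marker echoes off the trace end
  rf <- simulate_rf(phantom(0, 17), g, gauss_pulse(), n_samples = 1800)
  # align scanlines first, as the estimator does
  r1 <- apr_round1(rf, reference = 1)
  rf1 <- apply_delays(rf, r1$delays)
  r2 <- apr_round2(rf1, threshold = Inf)
  orc <- oracle_delays(g, c(0, 17), rf$fs, reference = 1)
  expect_lte(mean(abs(r2$delays - orc$round2)), 2)
})

test_that("the fitted delay object satisfies its structural invariants", {
  rf <- small_marker_rf(32, n_samples = 1800)
  for (mode in c("simulation", "experimental")) {
    fit <- apr(rf, mode = mode, threshold = Inf)
    expect_s3_class(fit, "apr")
    expect_equal(fit$round1[fit$reference_scanline], 0L)
    for (s in seq_len(nrow(fit$round2)))
      expect_equal(fit$round2[s, s], 0L)      # identity tx map
    expect_equal(fit$total, sweep(fit$round2, 1, -fit$round1))
    expect_identical(coef(fit), fit$total)
    expect_identical(coef(fit, "round1"), fit$round1)
  }
})

test_that("fitting is deterministic and gate-choice invariant", {
  rf <- small_marker_rf(24, marker = c(0, 15))
  f1 <- apr(rf)
  f2 <- apr(rf)
  expect_identical(coef(f1), coef(f2))
  # two different gates that both contain the marker echoes
  f3 <- apr(rf, gate = gate_window(1, 50))
  f4 <- apr(rf, gate = gate_window(4, 45))
  expect_identical(coef(f3, "round1"), coef(f4, "round1"))
})

test_that("total APR delays match the geometric oracle for a single marker", {
  for (gspec in list(list("flat", NULL), list("arc", 300))) {
    g <- array_geometry(gspec[[1]], 32, 1, radius = gspec[[2]])
    rf <- simulate_rf(phantom(0, 17), g, gauss_pulse())
    fit <- apr(rf, reference = "strongest")
    orc <- oracle_delays(g, c(0, 17), rf$fs,
                         reference = fit$reference_scanline)
    expect_lte(mean(abs(fit$round1 - orc$round1)), 2)
  }
})

test_that("a common time shift leaves the fitted delays unchanged", {
  set.seed(17)
  centers <- 200 + sample(-30:30, 12)
  traces <- vapply(centers, function(ctr) pulse_trace(600, ctr),
                   numeric(600))
  rf <- rf_from_traces(traces, n_el = 12)
  fit <- apr(rf, curve_smooth = FALSE)
  rfk <- apply_delays(rf, rep(25L, 12))
  fitk <- apr(rfk, curve_smooth = FALSE)
  expect_identical(fitk$round1, fit$round1)
  expect_identical(fitk$round2, fit$round2)
  # shifting a single scanline by +k lowers its round-1 delay by k
  rf1 <- rf
  rf1$data[, , 5] <- rbind(matrix(0, 10, 12), rf$data[1:590, , 5])
  fit1 <- apr(rf1, reference = 1, curve_smooth = FALSE)
  expect_equal(fit1$round1[5], fit$round1[5] - 10L)
})

test_that("apply_delays shifts, inverts and validates", {
  rf <- small_marker_rf(8)
  expect_identical(apply_delays(rf, rep(0L, 8))$data, rf$data)
  n_sa <- dim(rf$data)[1]
  k <- 40L
  fwd <- apply_delays(rf, rep(k, 8))
  back <- apply_delays(fwd, rep(-k, 8))
  # restored over the interior that was never clipped
  expect_equal(back$data[(k + 1):(n_sa - k), , ],
               rf$data[(k + 1):(n_sa - k), , ])
  expect_error(apply_delays(rf, rep(n_sa, 8)), "n_samples")
  expect_error(apply_delays(rf, rep(0L, 3)), "length")
  expect_error(apply_delays(rf, matrix(0L, 3, 3)), "n_scanlines")
})

test_that("applying the fit aligns marker peaks at the reference's peak", {
  # the three-trace alignment picture: first and third traces delayed onto
  # the middle reference
  traces <- cbind(pulse_trace(500, 180), pulse_trace(500, 160),
                  pulse_trace(500, 210))
  rf <- rf_from_traces(traces, n_el = 3)
  fit <- apr(rf, reference = 2, curve_smooth = FALSE)
  aligned <- apply_delays(rf, fit)
  peaks <- vapply(1:3, function(s)
    which.max(envelope(aligned$data[, s, s])), integer(1))
  expect_equal(peaks, rep(160L, 3))
})

test_that("no-peak scanlines inherit the nearest neighbour's delay", {
  traces <- vapply(c(0, 2, 4, 6, 8), function(k) pulse_trace(400, 150 + k),
                   numeric(400))
  traces[, 3] <- 0                     # dead scanline
  rf <- rf_from_traces(traces, n_el = 5)
  expect_warning(r1 <- apr_round1(rf, reference = 1), "no gated peak")
  expect_equal(r1$n_substituted, 1L)
  expect_true(r1$delays[3] %in% r1$delays[c(2, 4)])
  # a dead reference scanline is fatal
  traces[, 1] <- 0
  rf2 <- rf_from_traces(traces, n_el = 5)
  expect_error(suppressWarnings(apr_round1(rf2, reference = 1)), "fatal")
})

test_that("oracle delay curves are internally consistent", {
  g <- array_geometry("arc", 24, 1, radius = 500)
  orc <- oracle_delays(g, c(3, 20), 40e6, reference = 5L)
  expect_equal(orc$round1[5], 0)
  expect_equal(orc$total, orc$round2 + matrix(orc$round1, 24, 24))
  # per-element receive delay of the tx element's own trace is zero
  for (s in c(1L, 12L, 24L)) expect_equal(orc$round2[s, s], 0)
})
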