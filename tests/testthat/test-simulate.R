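test_that("standard marker phantoms have the documented positions", {
  p1 <- marker_phantom("center_point")
  expect_equal(c(p1$x, p1$z), c(0, 30))
  p2 <- marker_phantom("two_points")
  expect_equal(p2$x, c(-30, 30))
  expect_equal(p2$z, c(30, 30))
  p3 <- marker_phantom("right_point")
  expect_equal(c(p3$x, p3$z), c(30, 30))
  expect_error(marker_phantom("bogus"))
})

test_that("scatter clouds are seeded, bounded and carve the target disc", {
  p <- marker_phantom("scatter_cloud", n = 2000, seed = 1,
                      target_xz = c(0, 40), target_radius = 5,
                      target_contrast = 0)
  expect_equal(nrow(p), 2000)
  expect_true(all(p$z > 0))
  inside <- p$x^2 + (p$z - 40)^2 <= 25
  expect_true(any(inside))            # the disc is populated
  expect_true(all(p$amplitude[inside] == 0))   # anechoic
  expect_true(all(p$amplitude[!inside] == 1))
  # reproducible under the same seed
  p2 <- marker_phantom("scatter_cloud", n = 2000, seed = 1,
                       target_xz = c(0, 40), target_radius = 5,
                       target_contrast = 0)
  expect_identical(p, p2)
  expect_error(marker_phantom("scatter_cloud", n = 10), "seed")
})

test_that("phantom invariants are enforced", {
  expect_error(phantom(0, -1), "depths")
  expect_error(phantom(0, 10, Inf), "finite")
  expect_error(phantom(c(0, 1), 10), "length")
})

test_that("empty phantom gives an all-zero tensor", {
  g <- small_flat(8)
  rf <- simulate_rf(phantom(numeric(0), numeric(0)), g, gauss_pulse(),
                    n_samples = 256)
  expect_true(all(rf$data == 0))
  expect_equal(dim(rf$data), c(256, 8, 8))
})

test_that("echo arrival matches the time-of-flight oracle within a sample", {
  g <- small_flat(16)
  pu <- gauss_pulse(fs = 40e6)
  rf <- simulate_rf(phantom(0, 20), g, pu)
  for (s in c(1L, 8L, 16L)) for (e in c(1L, 9L, 16L)) {
    tau <- tof(g, s, e, c(0, 20), rf$sound_speed)
    expect_lte(abs(which.max(envelope(rf$data[, e, s])) -
                     (round(tau * rf$fs) + 1)), 1)
  }
})

test_that("simulator is linear in scatterer amplitude", {
  g <- small_flat(8)
  ph <- phantom(c(-3, 4), c(12, 20), c(1, 0.5))
  ph2 <- ph; ph2$amplitude <- 2 * ph2$amplitude
  rf1 <- simulate_rf(ph, g, gauss_pulse())
  rf2 <- simulate_rf(ph2, g, gauss_pulse())
  expect_equal(rf2$data, 2 * rf1$data, tolerance = 1e-12)
})

test_that("tx/rx reciprocity holds for a single scatterer", {
  g <- small_flat(12)
  rf <- simulate_rf(phantom(2, 15), g, gauss_pulse(),
                    tx_map = seq_len(12))
  # swapping the roles of elements i and j leaves arrival samples unchanged
  for (pair in list(c(1L, 12L), c(3L, 9L))) {
    i <- pair[1]; j <- pair[2]
    a <- which.max(envelope(rf$data[, j, i]))   # tx i, rx j
    b <- which.max(envelope(rf$data[, i, j]))   # tx j, rx i
    expect_equal(a, b)
  }
})

test_that("noise requires a seed and is reproducible", {
  g <- small_flat(4)
  ph <- phantom(0, 10)
  expect_error(simulate_rf(ph, g, gauss_pulse(), noise_level = 0.1), "seed")
  r1 <- simulate_rf(ph, g, gauss_pulse(), noise_level = 0.1, seed = 7)
  r2 <- simulate_rf(ph, g, gauss_pulse(), noise_level = 0.1, seed = 7)
  expect_identical(r1$data, r2$data)
  r3 <- add_noise(simulate_rf(ph, g, gauss_pulse()), 0.1, seed = 7)
  expect_equal(r3$data, r1$data)
})

test_that("too-short traces are rejected", {
  g <- small_flat(4)
  expect_error(simulate_rf(phantom(0, 30), g, gauss_pulse(), n_samples = 16),
               "too small")
})

test_that("pulse parameter validation", {
  expect_error(gauss_pulse(fractional_bandwidth = 0), "bandwidth")
  expect_error(gauss_pulse(center_frequency = 5e6, fs = 8e6), "Nyquist")
})

test_that("curving to the same geometry is the identity", {
  g <- small_flat(16)
  rf <- simulate_rf(phantom(0, 15), g, gauss_pulse())
  for (interp in c("spline", "linear", "nearest")) {
    rfc <- curve_rf(rf, g, interp = interp)
    expect_lt(max(abs(rfc$data - rf$data)), 1e-9 * max(abs(rf$data)))
  }
})

test_that("curving shifts edge traces by the closed-form delay difference", {
  g_flat <- small_flat(32)
  g_arc <- array_geometry("arc", 32, 1, radius = 300)
  rf <- simulate_rf(phantom(0, 17), g_flat, gauss_pulse())
  rfc <- curve_rf(rf, g_arc)
  # for the centre scanline the marker lies on the scanline axis, where the
  # construction is exact: the echo must move to the curved-geometry ToF
  s <- 16L
  for (e in c(1L, 8L, 32L)) {
    tau_c <- tof(g_arc, s, e, c(0, 17), rf$sound_speed)
    got <- which.max(envelope(rfc$data[, e, s]))
    expect_lte(abs(got - (round(tau_c * rf$fs) + 1)), 1)
  }
})

test_that("curving validates element-count compatibility", {
  rf <- small_marker_rf(8)
  expect_error(curve_rf(rf, array_geometry("arc", 16, 1, radius = 300)),
               "element counts")
  rf$geometry <- NULL
  expect_error(curve_rf(rf, array_geometry("arc", 8, 1, radius = 300)),
               "geometry")
})
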