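test_that("fwhm matches closed forms for canonical profiles", {
  x <- seq(-10, 10, by = 0.02)
  # Gaussian with sigma = 1 mm: FWHM = 2 sqrt(2 ln 2) = 2.3548 mm
  expect_equal(fwhm(exp(-x^2 / 2), coords = x), 2 * sqrt(2 * log(2)),
               tolerance = 5e-3)
  # rectangular profile of width w
  rect <- as.numeric(abs(x) <= 2.5)
  expect_equal(fwhm(rect, coords = x), 5, tolerance = 0.05)
  # scale and sub-half-maximum background invariance
  prof <- exp(-x^2 / 2)
  expect_equal(fwhm(7 * prof, coords = x), fwhm(prof, coords = x))
  expect_equal(fwhm(prof + 0.05, coords = x), fwhm(prof, coords = x),
               tolerance = 0.05)
  # profile that never falls below half maximum
  expect_error(fwhm(rep(1, 50) + 0.01 * sin(1:50), coords = 1:50),
               "undefined")
})

test_that("fwhm reads lateral and axial profiles off a B-mode image", {
  x_mm <- seq(-20, 20, by = 0.25)
  z_mm <- seq(0, 40, by = 0.1)
  lin <- outer(exp(-(z_mm - 20)^2 / (2 * 1.5^2)),
               exp(-x_mm^2 / (2 * 2^2)))
  img <- structure(list(pixels = log_compress(lin, -60), x_mm = x_mm,
                        z_mm = z_mm, dynamic_range = c(-60, 0),
                        provenance = "apr"), class = "bmode_image")
  expect_equal(fwhm(img, axis = "lateral"), 2 * sqrt(2 * log(2)) * 2,
               tolerance = 0.01)
  expect_equal(fwhm(img, axis = "axial"), 2 * sqrt(2 * log(2)) * 1.5,
               tolerance = 0.01)
  # explicit point location hits the same peak
  expect_equal(fwhm(img, point = c(0.3, 19.5), axis = "lateral"),
               fwhm(img, axis = "lateral"))
})

test_that("cnr reproduces hand-computed contrast values", {
  # mu_out - mu_in = 1, sd_out^2 + sd_in^2 = 1  ->  0 dB
  # construct samples whose sample variance is exactly 0.5 on each side
  a <- rep(c(1, -1), 50) * sqrt(0.5 * 99 / 100)
  img <- matrix(0, 10, 20)
  img[1:5, ] <- a                            # inner: mean 0, var 0.5
  img[6:10, ] <- 1 + a                       # outer: mean 1, var 0.5
  ii <- which(row(img) <= 5); oo <- which(row(img) > 5)
  expect_equal(cnr(img, ii, oo), 0, tolerance = 1e-9)
  # invariance under global linear scaling
  expect_equal(cnr(3.7 * img, ii, oo), cnr(img, ii, oo), tolerance = 1e-9)
  # synthetic disc with amplitude ratio 10: direct arithmetic oracle
  set.seed(3)
  bg <- matrix(stats::rlnorm(400, 0, 0.3), 20, 20)
  im2 <- bg; im2[5:10, 5:10] <- bg[5:10, 5:10] * 10
  ii2 <- which(row(im2) %in% 5:10 & col(im2) %in% 5:10)
  oo2 <- setdiff(seq_along(im2), ii2)
  expected <- 20 * log10(abs(mean(im2[oo2]) - mean(im2[ii2])) /
                           sqrt(stats::sd(im2[oo2])^2 + stats::sd(im2[ii2])^2))
  expect_equal(cnr(im2, ii2, oo2), expected)
  # degenerate cases
  expect_equal(cnr(img, oo, ii), 0, tolerance = 1e-9)  # |.| symmetric
  flat_img <- matrix(rep(c(0, 1), 50), 10, 10)
  expect_equal(cnr(flat_img, 1:50, 51:100), -Inf)      # equal means
  expect_error(cnr(matrix(1, 4, 4), 1:8, 9:16), "variance")
  expect_error(cnr(img, ii, ii), "disjoint")
  expect_error(cnr(img, integer(0), oo), "empty")
})

test_that("psnr follows the peak-squared-over-MSE definition", {
  a <- matrix(stats::rnorm(100, -30, 5), 10, 10)
  expect_equal(psnr(a, a), Inf)
  # constant 6 dB offset on a 60 dB-range image: 10 log10(60^2/36) = 20
  expect_equal(psnr(a + 6, a), 20)
  # random perturbation with known MSE
  set.seed(9)
  e <- matrix(stats::rnorm(100), 10, 10)
  expect_equal(psnr(a + e, a), 10 * log10(3600 / mean(e^2)))
  expect_error(psnr(a, matrix(0, 5, 5)), "shapes")
})

test_that("location error is the signed depth difference", {
  expect_equal(location_error(67, 67), 0)
  expect_equal(location_error(67, 68), -1)
  for (z in c(0, 12.5, 70)) expect_equal(location_error(z, z), 0)
})

test_that("delay errors sum per-scanline deviations", {
  expect_equal(delay_error(1:128, 1:128), list(total = 0, mean = 0))
  k <- 3
  est <- rep(k, 128); gt <- rep(0, 128)
  expect_equal(delay_error(est, gt), list(total = 128 * k, mean = k))
  # brute-force oracle on random integer curves
  set.seed(21)
  a <- sample(-50:50, 128, TRUE); b <- sample(-50:50, 128, TRUE)
  brute <- 0; for (i in 1:128) brute <- brute + abs(a[i] - b[i])
  expect_equal(delay_error(a, b)$total, brute)
  expect_equal(delay_error(a, b, mode = "var")$total, sum((a - b)^2))
  expect_error(delay_error(1:5, 1:6), "length")
})

test_that("delay error satisfies the triangle inequality", {
  set.seed(33)
  for (i in 1:10) {
    a <- sample(-20:20, 64, TRUE)
    b <- sample(-20:20, 64, TRUE)
    c <- sample(-20:20, 64, TRUE)
    expect_lte(delay_error(a, c)$total,
               delay_error(a, b)$total + delay_error(b, c)$total)
  }
})

test_that("metrics_report assembles the standard evaluation row", {
  g <- small_flat(24)
  rf <- simulate_rf(phantom(0, 17), g, gauss_pulse())
  fit <- apr(rf, reference = "strongest")
  img <- beamform_apr(rf, fit)
  gt <- beamform_das(rf)
  orc <- oracle_delays(g, c(0, 17), rf$fs,
                       reference = fit$reference_scanline)
  # the sharp DAS image carries the FWHM reading; the APR image is the
  # comparison reference
  rep1 <- metrics_report(gt, reference = img, opt_xz = c(0, 17),
                         delays = fit$round1,
                         gt_delays = round(orc$round1))
  expect_equal(nrow(rep1), 1)
  expect_true(all(c("lateral_fwhm", "axial_fwhm", "cnr", "psnr",
                    "location_error", "delay_total_error",
                    "delay_mean_error") %in% names(rep1)))
  expect_gt(rep1$lateral_fwhm, 0)
  expect_gt(rep1$axial_fwhm, 0)
  expect_lt(abs(rep1$location_error), 1)
  expect_equal(rep1$delay_mean_error,
               rep1$delay_total_error / length(fit$round1))
})
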