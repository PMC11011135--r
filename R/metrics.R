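#' Full width at half maximum of a point-target profile
#'
#' Measures the width between the two half-maximum crossings (linear
#' interpolation between samples) of the envelope profile through a point
#' target's peak, along the lateral or axial axis.  dB images are converted
#' back to linear amplitude first.
#'
#' @param image a `bmode_image`, or a numeric profile vector (then supply
#'   `coords`).
#' @param point optional `c(x, z)` (mm): the profile passes through the
#'   brightest pixel within `search_mm` of this point; default the global
#'   maximum.
#' @param axis `"lateral"` or `"axial"` (ignored for vector input).
#' @param coords coordinates (mm) of the profile samples, for vector input.
#' @param search_mm half-width of the search box around `point` (mm).
#' @return width in mm.
#' @examples
#' x <- seq(-10, 10, 0.05)
#' fwhm(exp(-x^2 / 2), coords = x)   # 2.3548 for sigma = 1 mm
#' @export
fwhm <- function(image, point = NULL, axis = c("lateral", "axial"),
                 coords = NULL, search_mm = 5) {
  axis <- match.arg(axis)
  if (is.numeric(image) && is.null(dim(image))) {
    if (is.null(coords)) stop("vector input requires 'coords'")
    return(fwhm_profile(image, coords))
  }
  stopifnot(inherits(image, "bmode_image"))
  lin <- 10^(image$pixels / 20)
  if (is.null(point)) {
    ij <- which(lin == max(lin), arr.ind = TRUE)[1, ]
  } else {
    sub_r <- which(abs(image$z_mm - point[2]) <= search_mm)
    sub_c <- which(abs(image$x_mm - point[1]) <= search_mm)
    if (length(sub_r) == 0 || length(sub_c) == 0)
      stop("no pixels near the requested point")
    block <- lin[sub_r, sub_c, drop = FALSE]
    ij0 <- which(block == max(block), arr.ind = TRUE)[1, ]
    ij <- c(sub_r[ij0[1]], sub_c[ij0[2]])
  }
  if (axis == "lateral") fwhm_profile(lin[ij[1], ], image$x_mm)
  else fwhm_profile(lin[, ij[2]], image$z_mm)
}

# half-maximum width of a sampled profile, linear interpolation at crossings
fwhm_profile <- function(values, coords) {
  if (length(values) != length(coords)) stop("values/coords length mismatch")
  k <- which.max(values)
  half <- values[k] / 2
  left <- right <- NA_real_
  if (k >= 2L) for (i in k:2L) {
    if (values[i - 1] <= half) {
      f <- (values[i] - half) / (values[i] - values[i - 1])
      left <- coords[i] + f * (coords[i - 1] - coords[i])
      break
    }
  }
  if (k <= length(values) - 1L) for (i in k:(length(values) - 1L)) {
    if (values[i + 1] <= half) {
      f <- (values[i] - half) / (values[i] - values[i + 1])
      right <- coords[i] + f * (coords[i + 1] - coords[i])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop("undefined FWHM: profile never falls below half maximum")
  abs(right - left)
}

#' Circular region of interest on an image grid
#'
#' @param image a `bmode_image`.
#' @param x0,z0 centre (mm).
#' @param radius radius (mm); for `roi_annulus`, `r_in < r_out`.
#' @return logical mask with the image's dimensions.
#' @export
roi_disc <- function(image, x0, z0, radius) {
  stopifnot(inherits(image, "bmode_image"))
  outer(image$z_mm, image$x_mm,
        function(z, x) (x - x0)^2 + (z - z0)^2 <= radius^2)
}

#' @rdname roi_disc
#' @param r_in,r_out inner and outer radii (mm) of the annulus.
#' @export
roi_annulus <- function(image, x0, z0, r_in, r_out) {
  roi_disc(image, x0, z0, r_out) & !roi_disc(image, x0, z0, r_in)
}

#' Contrast-to-noise ratio
#'
#' `CNR = 20 log10(|mu_out - mu_in| / sqrt(sd_out^2 + sd_in^2))` over
#' linear-scale pixels.  The absolute value keeps the metric real-valued
#' whether the target is brighter (hyperechoic) or darker (anechoic) than
#' the background; the sign convention is documented rather than encoded.
#'
#' @param image_linear linear-amplitude matrix, or a `bmode_image` (its dB
#'   pixels are converted back to linear amplitude).
#' @param inner_roi,outer_roi logical masks (image dimensions) or index
#'   vectors selecting the target and background pixels; must be non-empty
#'   and disjoint.
#' @return CNR in dB; `-Inf` when the means are equal (undefined contrast).
#' @export
cnr <- function(image_linear, inner_roi, outer_roi) {
  x <- if (inherits(image_linear, "bmode_image"))
    10^(image_linear$pixels / 20) else image_linear
  ii <- if (is.logical(inner_roi)) which(inner_roi) else as.integer(inner_roi)
  oo <- if (is.logical(outer_roi)) which(outer_roi) else as.integer(outer_roi)
  if (length(ii) == 0 || length(oo) == 0) stop("empty ROI")
  if (length(intersect(ii, oo)) > 0) stop("ROIs must be disjoint")
  mi <- mean(x[ii]); mo <- mean(x[oo])
  v <- stats::sd(x[ii])^2 + stats::sd(x[oo])^2
  if (!is.finite(v) || v == 0) stop("undefined CNR: zero variance in ROIs")
  if (mo == mi) return(-Inf)
  20 * log10(abs(mo - mi) / sqrt(v))
}

#' Peak signal-to-noise ratio between two dB images
#'
#' `PSNR = 10 log10(peak^2 / MSE)` computed over dB-domain pixels, with
#' `peak` the dynamic-range span (default 60 dB).
#'
#' @param image,reference `bmode_image`s or numeric matrices of identical
#'   shape (dB pixels).
#' @param peak peak value; default the reference's dynamic-range span, or
#'   60 when unavailable.
#' @return PSNR in dB; `Inf` for identical images.
#' @export
psnr <- function(image, reference, peak = NULL) {
  a <- if (inherits(image, "bmode_image")) image$pixels else image
  b <- if (inherits(reference, "bmode_image")) reference$pixels else reference
  if (!all(dim(a) == dim(b))) stop("image shapes differ")
  if (is.null(peak)) {
    peak <- if (inherits(reference, "bmode_image"))
      abs(diff(reference$dynamic_range)) else 60
  }
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Axial location error
#'
#' Signed difference between a target's ground-truth depth and its depth in
#' the evaluated image, `gt - est`, in mm.
#'
#' @param gt_z,est_z depths in mm.
#' @return signed error in mm.
#' @export
location_error <- function(gt_z, est_z) gt_z - est_z

#' Total and mean delay-curve error
#'
#' Compares an estimated per-scanline delay curve with its ground truth:
#' the total error sums the per-scanline deviations over all scanlines and
#' the mean error divides by their number.  `mode = "abs"` (default) sums
#' absolute differences; `mode = "var"` sums squared differences.
#'
#' @param estimated,ground_truth numeric delay curves (samples), equal
#'   length.
#' @param mode `"abs"` or `"var"`.
#' @return list with `total` and `mean` (samples).
#' @export
delay_error <- function(estimated, ground_truth, mode = c("abs", "var")) {
  mode <- match.arg(mode)
  if (length(estimated) != length(ground_truth))
    stop("delay curves differ in length")
  d <- estimated - ground_truth
  tot <- if (mode == "abs") sum(abs(d)) else sum(d^2)
  list(total = tot, mean = tot / length(d))
}

#' Assemble an image-quality metrics report
#'
#' One row of the standard evaluation: lateral/axial FWHM of the objective
#' point target, CNR, PSNR against the reference image, axial location
#' error, and (when delay curves are supplied) total and mean delay error.
#'
#' @param image evaluated `bmode_image` (e.g. APR-reconstructed).
#' @param reference ground-truth `bmode_image`, or `NULL`.
#' @param opt_xz `c(x, z)` (mm) of the objective point target, or `NULL`
#'   to use the image's global maximum.
#' @param cnr_inner,cnr_outer optional ROI masks for [cnr()].
#' @param delays,gt_delays optional per-scanline delay curves for
#'   [delay_error()].
#' @return a one-row `data.frame` with columns `lateral_fwhm`, `axial_fwhm`,
#'   `cnr`, `psnr`, `location_error`, `delay_total_error`,
#'   `delay_mean_error` (NA where inputs were not supplied or the metric is
#'   undefined).
#' @export
metrics_report <- function(image, reference = NULL, opt_xz = NULL,
                           cnr_inner = NULL, cnr_outer = NULL,
                           delays = NULL, gt_delays = NULL) {
  lf <- tryCatch(fwhm(image, opt_xz, "lateral"), error = function(e) NA_real_)
  af <- tryCatch(fwhm(image, opt_xz, "axial"), error = function(e) NA_real_)
  cn <- if (!is.null(cnr_inner) && !is.null(cnr_outer))
    tryCatch(cnr(image, cnr_inner, cnr_outer), error = function(e) NA_real_)
  else NA_real_
  ps <- if (!is.null(reference))
    tryCatch(psnr(image, reference), error = function(e) NA_real_)
  else NA_real_
  le <- if (!is.null(opt_xz)) {
    pk <- image_peak(image)
    location_error(opt_xz[2], pk$z)
  } else NA_real_
  de <- if (!is.null(delays) && !is.null(gt_delays))
    delay_error(delays, gt_delays) else list(total = NA_real_, mean = NA_real_)
  data.frame(lateral_fwhm = lf, axial_fwhm = af, cnr = cn, psnr = ps,
             location_error = le,
             delay_total_error = de$total, delay_mean_error = de$mean)
}
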