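#' Construct a flexible-array element geometry
#'
#' Builds the in-plane element layout of a (possibly deformed) linear array.
#' The coordinate convention is: `x` lateral in mm, increasing with element
#' index; `z` axial depth in mm, positive into the medium; origin at the
#' aperture's lateral centre on the skin line.
#'
#' Three shapes are supported:
#' \describe{
#'   \item{`"flat"`}{all elements on the `z = 0` line, spaced by `pitch`.}
#'   \item{`"arc"`}{elements on a circle of radius `radius` (mm), equally
#'     spaced in *arc length* (a bent physical array preserves inter-element
#'     distance along the curve), convex toward the patient: the apex element
#'     sits at `z = 0` and the edges bend away from the medium to `z > 0`.}
#'   \item{`"polyline"`}{explicit element positions (`points`, an n-by-2
#'     matrix of x, z in mm); only re-centred laterally.}
#' }
#'
#' @param shape one of `"flat"`, `"arc"`, `"polyline"`.
#' @param n_elements number of elements (>= 2). Default 128, the width of the
#'   flexible probe the package models (128 elements at 1 mm pitch).
#' @param pitch inter-element spacing along the curve in mm (> 0).
#' @param radius circle radius in mm for `shape = "arc"`; must exceed the
#'   aperture half-width.
#' @param points n-by-2 matrix of element (x, z) positions in mm for
#'   `shape = "polyline"`.
#' @return An object of class `"array_geometry"`: a list with `element_x`,
#'   `element_z` (mm), `pitch`, `n_elements` and `shape` (a label such as
#'   `"flat"` or `"arc(500)"`).
#' @examples
#' g <- array_geometry("arc", n_elements = 128, pitch = 1, radius = 500)
#' range(g$element_z)
#' @export
array_geometry <- function(shape = c("flat", "arc", "polyline"),
                           n_elements = 128L, pitch = 1,
                           radius = NULL, points = NULL) {
  shape <- match.arg(shape)
  if (shape != "polyline") {
    n_elements <- as.integer(n_elements)
    if (n_elements < 2L) stop("n_elements must be >= 2")
    if (!is.numeric(pitch) || pitch <= 0) stop("pitch must be > 0")
  }
  # arc-length coordinate of each element, centred on 0
  s <- (seq_len(ifelse(shape == "polyline", 1L, n_elements)) - 1) * pitch
  s <- s - mean(s)
  if (shape == "flat") {
    x <- s
    z <- rep(0, n_elements)
    label <- "flat"
  } else if (shape == "arc") {
    if (is.null(radius) || !is.numeric(radius) || radius <= 0)
      stop("arc shape requires a positive radius (mm)")
    half_ap <- (n_elements - 1) * pitch / 2
    if (radius <= half_ap)
      stop("geometry infeasible: radius (", radius,
           " mm) must exceed the aperture half-width (", half_ap, " mm)")
    theta <- s / radius
    x <- radius * sin(theta)
    z <- radius * (1 - cos(theta))
    label <- sprintf("arc(%g)", radius)
  } else {
    if (is.null(points)) stop("polyline shape requires 'points'")
    points <- as.matrix(points)
    if (ncol(points) != 2L || nrow(points) < 2L)
      stop("'points' must be an n-by-2 matrix (x, z in mm), n >= 2")
    n_elements <- nrow(points)
    x <- points[, 1] - mean(points[, 1])
    z <- points[, 2]
    pitch <- mean(sqrt(diff(points[, 1])^2 + diff(points[, 2])^2))
    label <- "polyline"
  }
  if (any(diff(x) <= 0)) stop("element_x must be strictly increasing")
  structure(list(element_x = x, element_z = z, pitch = pitch,
                 n_elements = as.integer(n_elements), shape = label),
            class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("<array_geometry> %s, %d elements, pitch %.4g mm\n",
              x$shape, x$n_elements, x$pitch))
  cat(sprintf("  x: [%.2f, %.2f] mm   z: [%.4g, %.4g] mm\n",
              min(x$element_x), max(x$element_x),
              min(x$element_z), max(x$element_z)))
  invisible(x)
}

#' Two-way time of flight between elements via a field point
#'
#' Propagation time from the transmit element to a point in the medium and
#' back to the receive element, `(|p_tx - p| + |p - p_rx|) / c`.  If the
#' point coincides with one of the elements that leg contributes zero.
#'
#' @param geometry an [array_geometry()].
#' @param tx_index,rx_index 1-based element indices.
#' @param point_xz numeric length-2 vector `c(x, z)` in mm, or an n-by-2
#'   matrix of points (vectorised).
#' @param sound_speed speed of sound in m/s (> 0); 1540 m/s is soft tissue.
#' @return time(s) of flight in seconds (length = number of points).
#' @examples
#' g <- array_geometry("flat", 3, 1)
#' tof(g, 2, 2, c(0, 30), 1540)  # 2 * 30 mm / 1540 m/s
#' @export
tof <- function(geometry, tx_index, rx_index, point_xz, sound_speed = 1540) {
  stopifnot(inherits(geometry, "array_geometry"))
  if (!is.numeric(sound_speed) || sound_speed <= 0)
    stop("sound_speed must be > 0")
  n <- geometry$n_elements
  if (tx_index < 1L || tx_index > n || rx_index < 1L || rx_index > n)
    stop("element index out of range")
  p <- if (is.matrix(point_xz)) point_xz else matrix(point_xz, ncol = 2)
  ptx <- c(geometry$element_x[tx_index], geometry$element_z[tx_index])
  prx <- c(geometry$element_x[rx_index], geometry$element_z[rx_index])
  d_tx <- sqrt((p[, 1] - ptx[1])^2 + (p[, 2] - ptx[2])^2)
  d_rx <- sqrt((p[, 1] - prx[1])^2 + (p[, 2] - prx[2])^2)
  (d_tx + d_rx) / 1000 / sound_speed
}

#' Serialize / deserialize an array geometry as JSON
#'
#' @param geometry an [array_geometry()].
#' @param path optional file path; if omitted the JSON string is returned.
#' @return `geometry_to_json`: the JSON string (invisibly if written to
#'   file); `geometry_from_json`: an [array_geometry()].
#' @export
geometry_to_json <- function(geometry, path = NULL) {
  stopifnot(inherits(geometry, "array_geometry"))
  doc <- list(shape = geometry$shape,
              n_elements = geometry$n_elements,
              pitch_mm = geometry$pitch,
              element_x_mm = geometry$element_x,
              element_z_mm = geometry$element_z)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname geometry_to_json
#' @param json a JSON string or file path produced by [geometry_to_json()].
#' @export
geometry_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  g <- structure(list(element_x = as.numeric(doc$element_x_mm),
                      element_z = as.numeric(doc$element_z_mm),
                      pitch = as.numeric(doc$pitch_mm),
                      n_elements = as.integer(doc$n_elements),
                      shape = doc$shape),
                 class = "array_geometry")
  if (any(diff(g$element_x) <= 0)) stop("invalid geometry JSON")
  g
}
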