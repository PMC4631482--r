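#' Detector geometry
#'
#' Describes a flat, orthogonal area detector and the beam that illuminates
#' it: sample-to-detector distance, square pixel size, beam centre (fractional
#' pixel coordinates allowed), wavelength and raster shape. Pixel coordinates
#' are 0-based `(fast, slow)` with pixel centres at integer coordinates.
#'
#' @param distance_mm Sample-to-detector distance in mm (> 0).
#' @param pixel_mm Pixel edge length in mm (> 0).
#' @param beam_center_px Numeric length-2, beam centre as `(fast, slow)` pixels.
#' @param wavelength_a X-ray wavelength in Angstrom (> 0).
#' @param n_fast,n_slow Pixel counts along the fast and slow axes.
#'
#' @return An object of class `detector_geometry`.
#' @examples
#' geom <- detector_geometry(200, 0.172, c(120, 120), 1.0, 240, 240)
#' pixel_resolution(geom, 120, 120) # beam centre: h = 0
#' @export
detector_geometry <- function(distance_mm, pixel_mm, beam_center_px,
                              wavelength_a, n_fast, n_slow) {
  stopifnot(
    is.numeric(distance_mm), length(distance_mm) == 1L, distance_mm > 0,
    is.numeric(pixel_mm), length(pixel_mm) == 1L, pixel_mm > 0,
    is.numeric(wavelength_a), length(wavelength_a) == 1L, wavelength_a > 0,
    length(beam_center_px) == 2L,
    n_fast >= 1, n_slow >= 1
  )
  n <- c(n_fast, n_slow)
  if (any(beam_center_px < -n | beam_center_px > 2 * n)) {
    stop("beam_center_px must lie within [-n, 2n] of the detector raster")
  }
  structure(
    list(
      distance_mm = as.numeric(distance_mm),
      pixel_mm = as.numeric(pixel_mm),
      beam_center_px = as.numeric(beam_center_px),
      wavelength_a = as.numeric(wavelength_a),
      n_fast = as.integer(n_fast),
      n_slow = as.integer(n_slow)
    ),
    class = "detector_geometry"
  )
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "<detector_geometry> %d x %d px, %.4g mm/px, D = %.4g mm, lambda = %.4g A\n",
    x$n_fast, x$n_slow, x$pixel_mm, x$distance_mm, x$wavelength_a
  ))
  cat(sprintf(
    "  beam centre (%.2f, %.2f) px; corner resolution d = %.3g A\n",
    x$beam_center_px[1], x$beam_center_px[2], 1 / max_h(x)
  ))
  invisible(x)
}

#' Map detector pixels to diffraction-vector length
#'
#' For a flat detector normal to the beam, a pixel at radial distance `r` mm
#' from the beam centre sees scattering angle `2theta = atan(r / D)` and
#' diffraction-vector length `h = 2 sin(theta) / lambda = 1/d` in 1/Angstrom.
#'
#' @param geom A [detector_geometry()].
#' @param px,py Pixel coordinates (0-based, fast then slow); vectorized.
#' @return Numeric vector of `h` values (1/Angstrom). `h = 0` at the beam
#'   centre, strictly increasing with radial distance.
#' @export
pixel_resolution <- function(geom, px, py) {
  stopifnot(inherits(geom, "detector_geometry"))
  r_mm <- sqrt((px - geom$beam_center_px[1])^2 +
                 (py - geom$beam_center_px[2])^2) * geom$pixel_mm
  two_theta <- atan(r_mm / geom$distance_mm)
  2 * sin(two_theta / 2) / geom$wavelength_a
}

# largest h reachable on the detector (at the farthest corner)
max_h <- function(geom) {
  corners_x <- c(0, geom$n_fast - 1)
  corners_y <- c(0, geom$n_slow - 1)
  g <- expand.grid(px = corners_x, py = corners_y)
  max(pixel_resolution(geom, g$px, g$py))
}

# full raster of h values, n_slow x n_fast matrix (row = slow, col = fast),
# matching the frame matrix layout used throughout
resolution_raster <- function(geom) {
  px <- matrix(rep(seq_len(geom$n_fast) - 1L, each = geom$n_slow),
               nrow = geom$n_slow)
  py <- matrix(rep(seq_len(geom$n_slow) - 1L, times = geom$n_fast),
               nrow = geom$n_slow)
  matrix(pixel_resolution(geom, px, py), nrow = geom$n_slow)
}

#' Resolution-shell binning
#'
#' Partitions the resolution range `(0, 1/d_min]` into `n_shells` concentric
#' shells. The default policy gives every shell the same reciprocal-space
#' volume (equal increments in `h^3`), so the per-shell volume weights
#' `V(h) = (4 pi / 3) (h_out^3 - h_in^3)` are uniform; `policy = "equal_h"`
#' uses equal-width `h` bins instead.
#'
#' @param geom A [detector_geometry()].
#' @param n_shells Number of shells (>= 4 recommended; >= 1 required).
#' @param d_min Highest resolution (smallest d-spacing, Angstrom) to bin.
#'   Must be attainable at the detector corner.
#' @param policy `"equal_volume"` (default) or `"equal_h"`.
#' @return An object of class `shell_binning` with fields `edges` (length
#'   `n_shells + 1`, from 0 to `1/d_min`) and `volumes` (1/Angstrom^3).
#' @export
make_shells <- function(geom, n_shells, d_min,
                        policy = c("equal_volume", "equal_h")) {
  policy <- match.arg(policy)
  stopifnot(n_shells >= 1, d_min > 0)
  h_max <- 1 / d_min
  h_reach <- max_h(geom)
  if (h_max > h_reach + 1e-12) {
    stop(sprintf(
      "d_min = %.3g A is beyond the detector edge; maximum attainable resolution is %.3g A",
      d_min, 1 / h_reach
    ))
  }
  k <- seq(0, n_shells)
  edges <- switch(policy,
    equal_volume = h_max * (k / n_shells)^(1 / 3),
    equal_h = h_max * k / n_shells
  )
  volumes <- (4 * pi / 3) * diff(edges^3)
  structure(
    list(edges = edges, volumes = volumes, d_min = d_min, policy = policy),
    class = "shell_binning"
  )
}

#' @export
print.shell_binning <- function(x, ...) {
  cat(sprintf(
    "<shell_binning> %d shells to d_min = %.3g A (%s)\n",
    length(x$volumes), x$d_min, x$policy
  ))
  invisible(x)
}

# shell index for each h; shells are (edge[i], edge[i+1]], with h = 0 assigned
# to shell 1 so the beam-centre pixel is not orphaned; NA above h_max
shell_index <- function(shells, h) {
  n <- length(shells$volumes)
  idx <- findInterval(h, shells$edges, left.open = TRUE) # 0..n+? (n+1 never: last edge closed)
  idx[h == 0] <- 1L
  idx[idx > n] <- NA_integer_
  idx[idx == 0L] <- NA_integer_
  as.integer(idx)
}

# mid-shell h values (by reciprocal-volume centroid edge midpoint in h)
shell_mid_h <- function(shells) {
  e <- shells$edges
  (e[-1] + e[-length(e)]) / 2
}

#' Read or write a detector-geometry JSON sidecar
#'
#' Geometry is serialized as
#' `{"distance_mm", "pixel_mm", "beam_center_px":[x,y], "wavelength_A", "shape":[nfast,nslow]}`.
#'
#' @param geom A [detector_geometry()].
#' @param path File path.
#' @return `write_geometry()` returns `path` invisibly; `read_geometry()`
#'   returns a [detector_geometry()].
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "detector_geometry"))
  jsonlite::write_json(
    list(
      distance_mm = geom$distance_mm,
      pixel_mm = geom$pixel_mm,
      beam_center_px = geom$beam_center_px,
      wavelength_A = geom$wavelength_a,
      shape = c(geom$n_fast, geom$n_slow)
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  detector_geometry(
    distance_mm = j$distance_mm,
    pixel_mm = j$pixel_mm,
    beam_center_px = j$beam_center_px,
    wavelength_a = j$wavelength_A,
    n_fast = j$shape[1],
    n_slow = j$shape[2]
  )
}
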