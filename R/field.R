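#' Imaging field geometry
#'
#' Describes the rectangular field of view in physical units together with
#' its pixel sampling. The default pixel scale, 3.115 pixels per micrometer,
#' is the 20X objective scale used throughout the package. Pixel `(i, j)`
#' (row `i`, column `j`, origin at the top-left) covers the half-open
#' interval `[(j-1)/s, j/s) x [(i-1)/s, i/s)` in micrometers, with
#' `s = pixel_scale`.
#'
#' @param width,height field size in micrometers; both must be positive.
#' @param pixel_scale pixels per micrometer (default 3.115).
#' @return An object of class `field_spec` with elements `width`, `height`,
#'   `pixel_scale`, and the derived pixel grid size `nx`, `ny` (columns,
#'   rows) and `pixel_side_um`.
#' @examples
#' field_spec(32, 32)
#' field_from_pixels(512, 512)
#' @export
field_spec <- function(width, height, pixel_scale = 3.115) {
  stopifnot(is.numeric(width), width > 0,
            is.numeric(height), height > 0,
            is.numeric(pixel_scale), pixel_scale > 0)
  structure(
    list(width = width, height = height, pixel_scale = pixel_scale,
         nx = max(1L, as.integer(round(width * pixel_scale))),
         ny = max(1L, as.integer(round(height * pixel_scale))),
         pixel_side_um = 1 / pixel_scale),
    class = "field_spec")
}

#' @rdname field_spec
#' @param nx,ny pixel grid size (columns, rows).
#' @export
field_from_pixels <- function(nx, ny, pixel_scale = 3.115) {
  stopifnot(nx >= 1, ny >= 1, pixel_scale > 0)
  f <- field_spec(nx / pixel_scale, ny / pixel_scale, pixel_scale)
  f$nx <- as.integer(nx)
  f$ny <- as.integer(ny)
  f
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("<field_spec> %.3g x %.3g um, %d x %d px (%.4g px/um)\n",
              x$width, x$height, x$nx, x$ny, x$pixel_scale))
  invisible(x)
}

#' Receptor point set
#'
#' Ground-truth receptor coordinates (micrometers) on a rectangular field,
#' as produced by [sample_points()]. Coordinates lie inside the field bounds.
#'
#' @param x,y coordinates in micrometers.
#' @param field a [field_spec()].
#' @param process generating process label (`"poisson"` or `"thomas"`).
#' @return An object of class `point_set`.
#' @export
point_set <- function(x, y, field, process = "poisson") {
  stopifnot(length(x) == length(y), inherits(field, "field_spec"))
  if (length(x) > 0) {
    stopifnot(all(x >= 0 & x <= field$width),
              all(y >= 0 & y <= field$height))
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 field = field, process = process),
            class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d points (%s) on %.3g x %.3g um\n",
              length(x$x), x$process, x$field$width, x$field$height))
  invisible(x)
}

#' Number of points in a point set
#' @param ps a [point_set()].
#' @return Integer count.
#' @export
n_points <- function(ps) {
  stopifnot(inherits(ps, "point_set"))
  length(ps$x)
}

#' Nearest-neighbor distances of a point set
#'
#' Distance from each point to its closest other point, computed with a
#' cell-list search (linear expected time in the point count).
#'
#' @param ps a [point_set()], or a list with numeric `x` and `y`.
#' @return Numeric vector of distances in the units of the coordinates
#'   (micrometers for [point_set()] objects); `Inf` for a single point.
#' @export
nn_distances <- function(ps) {
  .nn_info(as.numeric(ps$x), as.numeric(ps$y))$dist
}

#' Ellipse specification in micrometers
#'
#' @param cx,cy center.
#' @param rx,ry semi-axes; both positive.
#' @return An object of class `ellipse_um`.
#' @export
ellipse_um <- function(cx, cy, rx, ry) {
  stopifnot(rx > 0, ry > 0)
  structure(list(cx = cx, cy = cy, rx = rx, ry = ry), class = "ellipse_um")
}

#' @rdname ellipse_um
#' @param e an `ellipse_um`.
#' @param x,y coordinates to test (micrometers).
#' @return `in_ellipse()`: logical vector.
#' @export
in_ellipse <- function(e, x, y) {
  ((x - e$cx) / e$rx)^2 + ((y - e$cy) / e$ry)^2 <= 1
}

# Pixel-center mask of an ellipse on a field's grid (rows = y, cols = x).
ellipse_pixel_mask <- function(e, field) {
  xc <- (seq_len(field$nx) - 0.5) / field$pixel_scale
  yc <- (seq_len(field$ny) - 0.5) / field$pixel_scale
  outer(yc, xc, function(y, x) in_ellipse(e, x, y))
}

#' Optical forward-model parameters
#'
#' Parameters of the rendering model used by [render_stained_image()] and
#' [simulate_selectivity_stack()]: an isotropic Gaussian point-spread
#' function, Poisson shot noise on the expected photon count, and additive
#' Gaussian read noise. `labeling_efficiency` is the fraction of receptors
#' carrying a detectable label.
#'
#' @param psf_sigma_nm PSF standard deviation in nanometers (>= 0).
#' @param photons_per_receptor expected photons collected per labeled
#'   receptor (or per ligand source when rendering the ligand channel).
#' @param background_rate expected background photons per pixel.
#' @param read_noise_sd Gaussian read-noise standard deviation (photons).
#' @param labeling_efficiency fraction in \[0, 1\].
#' @return An object of class `optics_spec`.
#' @export
optics_spec <- function(psf_sigma_nm = 200, photons_per_receptor = 20,
                        background_rate = 20, read_noise_sd = 3,
                        labeling_efficiency = 1) {
  stopifnot(psf_sigma_nm >= 0, photons_per_receptor >= 0,
            background_rate >= 0, read_noise_sd >= 0,
            labeling_efficiency >= 0, labeling_efficiency <= 1)
  structure(list(psf_sigma_nm = psf_sigma_nm,
                 photons_per_receptor = photons_per_receptor,
                 background_rate = background_rate,
                 read_noise_sd = read_noise_sd,
                 labeling_efficiency = labeling_efficiency),
            class = "optics_spec")
}
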