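#' Sample a receptor point field
#'
#' Draws receptor positions on a rectangular field from either a homogeneous
#' Poisson process (the "random surface distribution" regime) or a Thomas
#' cluster process (nanoclustered receptors: Poisson parents, Poisson
#' offspring counts, isotropic Gaussian displacements).
#'
#' `density` may also be a per-pixel density matrix (receptors per square
#' micrometer, dimensions `field$ny x field$nx`); in that case counts are
#' drawn per pixel and positions are uniform within each pixel
#' (Poisson process with piecewise-constant intensity).
#'
#' @param field a [field_spec()].
#' @param density receptors per square micrometer (scalar, or matrix for an
#'   inhomogeneous Poisson field).
#' @param process `"poisson"` or `"thomas"`.
#' @param cluster_params for `"thomas"`: list with `parent_rate` (parents per
#'   square micrometer), `mean_offspring`, and `cluster_sd_um` (> 0). When
#'   given, `density` is ignored for the thomas process (its intensity is
#'   `parent_rate * mean_offspring`).
#' @param seed integer seed; identical seeds give identical point sets.
#' @return A [point_set()].
#' @examples
#' ps <- sample_points(field_spec(10, 10), density = 50, seed = 1)
#' n_points(ps)
#' @export
sample_points <- function(field, density = NULL,
                          process = c("poisson", "thomas"),
                          cluster_params = NULL, seed = 1L) {
  stopifnot(inherits(field, "field_spec"))
  process <- match.arg(process)
  with_seed(seed, {
    if (process == "poisson") {
      if (is.matrix(density)) {
        if (!all(dim(density) == c(field$ny, field$nx)))
          stop("density grid is ", nrow(density), "x", ncol(density),
               " but field pixel grid is ", field$ny, "x", field$nx)
        if (any(density < 0))
          stop("negative density in grid (min ", min(density), ")")
        lam <- density * (1 / field$pixel_scale)^2
        cnt <- rpois(length(lam), as.vector(lam))
        idx <- rep.int(seq_along(cnt), cnt)
        i <- (idx - 1L) %% field$ny + 1L          # row
        j <- (idx - 1L) %/% field$ny + 1L         # column
        s <- field$pixel_scale
        x <- (j - runif(length(idx))) / s
        y <- (i - runif(length(idx))) / s
        return(point_set(pmin(x, field$width), pmin(y, field$height),
                         field, "poisson"))
      }
      stopifnot(is.numeric(density), length(density) == 1L)
      if (density < 0)
        stop("negative density: ", density)
      n <- rpois(1L, density * field$width * field$height)
      point_set(runif(n, 0, field$width), runif(n, 0, field$height),
                field, "poisson")
    } else {
      stopifnot(is.list(cluster_params),
                all(c("parent_rate", "mean_offspring", "cluster_sd_um") %in%
                      names(cluster_params)))
      if (cluster_params$parent_rate < 0)
        stop("negative density: parent_rate = ", cluster_params$parent_rate)
      if (cluster_params$cluster_sd_um <= 0)
        stop("cluster_sd_um must be > 0")
      npar <- rpois(1L, cluster_params$parent_rate *
                      field$width * field$height)
      px <- runif(npar, 0, field$width)
      py <- runif(npar, 0, field$height)
      noff <- rpois(npar, cluster_params$mean_offspring)
      x <- rep(px, noff) + rnorm(sum(noff), 0, cluster_params$cluster_sd_um)
      y <- rep(py, noff) + rnorm(sum(noff), 0, cluster_params$cluster_sd_um)
      keep <- x >= 0 & x <= field$width & y >= 0 & y <= field$height
      point_set(x[keep], y[keep], field, "thomas")
    }
  })
}

# Bin point coordinates into per-pixel counts (rows = y, cols = x).
bin_points <- function(ps) {
  f <- ps$field
  cnt <- matrix(0L, f$ny, f$nx)
  if (length(ps$x) == 0) return(cnt)
  j <- pmin(f$nx, floor(ps$x * f$pixel_scale) + 1L)
  i <- pmin(f$ny, floor(ps$y * f$pixel_scale) + 1L)
  tab <- table(factor(i + (j - 1L) * f$ny, levels = seq_len(f$ny * f$nx)))
  cnt[] <- as.integer(tab)
  cnt
}

#' Build a synthetic cell scene with known ground truth
#'
#' Places a homogeneous (or clustered) receptor field of surface density
#' `density` inside an elliptical cell, with an interior nucleus ellipse.
#' The realized receptor configuration is drawn once, at construction, so
#' downstream rendering and recovery can be scored against it.
#'
#' Two storage modes exist. With `keep_points = TRUE`, explicit coordinates
#' are stored (required for scaffold-binding simulations). With
#' `keep_points = FALSE`, only per-pixel Poisson counts are drawn — the same
#' point process marginalized to the pixel grid — which keeps scenes with
#' tens of millions of receptors tractable. The default keeps points while
#' the expected count is below two million.
#'
#' @param field a [field_spec()].
#' @param density receptors per square micrometer inside the cell.
#' @param cell,nucleus [ellipse_um()] specs; defaults are a centered cell
#'   ellipse with semi-axes 35%/28% of the field and a nucleus of a third of
#'   the cell's size. The nucleus must be contained in the cell.
#' @param process,cluster_params passed to [sample_points()].
#' @param keep_points logical or `NULL` (auto).
#' @param seed integer seed.
#' @return An object of class `scene_truth`: `field`, `cell`, `nucleus`,
#'   `density`, `true_density_map` (receptors per square micrometer per
#'   pixel), `counts` (realized per-pixel receptor counts), `points`
#'   (a [point_set()] or `NULL`), `cell_mask` / `nucleus_mask`
#'   (pixel-center truth masks).
#' @export
make_scene <- function(field, density, cell = NULL, nucleus = NULL,
                       process = c("poisson", "thomas"),
                       cluster_params = NULL, keep_points = NULL,
                       seed = 1L) {
  stopifnot(inherits(field, "field_spec"))
  process <- match.arg(process)
  if (is.null(cell))
    cell <- ellipse_um(field$width / 2, field$height / 2,
                       0.35 * field$width, 0.28 * field$height)
  if (is.null(nucleus))
    nucleus <- ellipse_um(cell$cx, cell$cy, cell$rx / 3, cell$ry / 3)
  # nucleus containment: check on the bounding extremes
  if (nucleus$cx - nucleus$rx < cell$cx - cell$rx ||
      nucleus$cx + nucleus$rx > cell$cx + cell$rx ||
      nucleus$cy - nucleus$ry < cell$cy - cell$ry ||
      nucleus$cy + nucleus$ry > cell$cy + cell$ry)
    stop("nucleus ellipse is not contained in the cell ellipse")
  if (density < 0) stop("negative density: ", density)

  cell_mask <- ellipse_pixel_mask(cell, field)
  nucleus_mask <- ellipse_pixel_mask(nucleus, field)
  density_map <- density * cell_mask

  expected_n <- density * pi * cell$rx * cell$ry
  if (is.null(keep_points)) keep_points <- expected_n <= 2e6
  if (process == "thomas" && !keep_points)
    stop("thomas scenes require keep_points = TRUE")

  pts <- NULL
  if (keep_points) {
    raw <- sample_points(field, density = density, process = process,
                         cluster_params = cluster_params, seed = seed)
    keep <- in_ellipse(cell, raw$x, raw$y)
    pts <- point_set(raw$x[keep], raw$y[keep], field, raw$process)
    counts <- bin_points(pts)
  } else {
    counts <- with_seed(seed, {
      lam <- density_map * (1 / field$pixel_scale)^2
      matrix(rpois(length(lam), as.vector(lam)), field$ny, field$nx)
    })
  }
  structure(list(field = field, cell = cell, nucleus = nucleus,
                 density = density, true_density_map = density_map,
                 counts = counts, points = pts,
                 cell_mask = cell_mask, nucleus_mask = nucleus_mask,
                 process = process, seed = seed),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(
    "<scene_truth> %d x %d px, density %.4g um^-2, %s receptors (%s)\n",
    x$field$nx, x$field$ny, x$density,
    format(sum(x$counts), big.mark = ","),
    if (is.null(x$points)) "pixel counts only" else "explicit points"))
  invisible(x)
}

# Gaussian blur that conserves total intensity (circular boundary).
psf_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  size <- 2L * as.integer(ceiling(4 * sigma_px)) + 1L
  size <- min(size, 2L * (min(dim(m)) %/% 2L) - 1L)
  if (size < 3L) return(m)
  k <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma_px)
  as.matrix(EBImage::filter2(EBImage::Image(m), k, boundary = "circular"))
}

# Render one channel from a per-pixel photon-source map.
render_channel <- function(source_photons, optics, pixel_scale) {
  sigma_px <- optics$psf_sigma_nm * 1e-3 * pixel_scale
  expected <- psf_blur(source_photons, sigma_px) + optics$background_rate
  expected[expected < 0] <- 0
  img <- matrix(rpois(length(expected), as.vector(expected)),
                nrow(expected), ncol(expected))
  if (optics$read_noise_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, optics$read_noise_sd),
                        nrow(img), ncol(img))
  img
}

#' Render a stained-receptor fluorescence image
#'
#' Forward model for a single-channel widefield/confocal-plane image of the
#' antibody-stained receptors in a scene: each receptor is labeled with
#' probability `labeling_efficiency`, emits `photons_per_receptor` expected
#' photons spread by an isotropic Gaussian PSF, a uniform background rate is
#' added, and the camera records Poisson shot noise plus additive Gaussian
#' read noise. The expected total image intensity is
#' `labeling_efficiency * photons_per_receptor * n_receptors +
#' background_rate * n_pixels`.
#'
#' @param truth a [make_scene()] object.
#' @param optics an [optics_spec()].
#' @param seed integer seed.
#' @return Numeric intensity matrix (`ny x nx`) with attribute
#'   `pixel_scale` (pixels per micrometer).
#' @export
render_stained_image <- function(truth, optics = optics_spec(), seed = 1L) {
  stopifnot(inherits(truth, "scene_truth"), inherits(optics, "optics_spec"))
  counts <- truth$counts
  if (!all(dim(counts) == c(truth$field$ny, truth$field$nx)))
    stop("scene count grid ", nrow(counts), "x", ncol(counts),
         " does not match the field pixel grid ",
         truth$field$ny, "x", truth$field$nx)
  img <- with_seed(seed, {
    labeled <- counts
    if (optics$labeling_efficiency < 1)
      labeled <- matrix(
        rbinom(length(counts), as.vector(counts),
               optics$labeling_efficiency),
        nrow(counts), ncol(counts))
    render_channel(labeled * optics$photons_per_receptor, optics,
                   truth$field$pixel_scale)
  })
  attr(img, "pixel_scale") <- truth$field$pixel_scale
  img
}

#' Simulate a serial-dilution calibration series
#'
#' Generates the antibody-amount versus fluorescence table measured on
#' poly-L-lysine-coated calibration wells: `intensity = slope * amount +
#' intercept + N(0, noise_sd)` for each replicate of each dilution level.
#'
#' @param slope_truth intensity per antibody.
#' @param intercept_truth background intensity at zero antibody.
#' @param levels antibody amounts (non-negative, non-empty).
#' @param replicates replicate wells per level.
#' @param noise_sd Gaussian measurement noise (>= 0).
#' @param seed integer seed.
#' @return A `data.frame` with columns `amount` and `intensity`
#'   (class `calibration_series`), `levels * replicates` rows.
#' @examples
#' simulate_calibration_series(2, 5, levels = c(0, 10), replicates = 2,
#'                             noise_sd = 0, seed = 1)
#' @export
simulate_calibration_series <- function(slope_truth, intercept_truth,
                                        levels, replicates = 3L,
                                        noise_sd = 0, seed = 1L) {
  stopifnot(length(levels) >= 1, all(levels >= 0), replicates >= 1)
  if (noise_sd < 0) stop("noise_sd must be >= 0, got ", noise_sd)
  amount <- rep(levels, each = replicates)
  intensity <- with_seed(seed, {
    slope_truth * amount + intercept_truth +
      rnorm(length(amount), 0, noise_sd)
  })
  structure(data.frame(amount = amount, intensity = intensity),
            class = c("calibration_series", "data.frame"))
}

#' Match bivalent-scaffold binding pairs in a point field
#'
#' Binding model for a bivalent ligand with arm span `spacing_nm`: a
#' scaffold bridges a pair of receptors that are mutual nearest neighbors
#' and whose separation matches the scaffold span within
#' `reach_tolerance_nm`. Mutual nearest-neighbor pairs are disjoint, so each
#' receptor is consumed by at most one scaffold.
#'
#' @param ps a [point_set()] (coordinates in micrometers).
#' @param spacing_nm designed ligand spacing (> 0).
#' @param reach_tolerance_nm allowed deviation of the receptor pair distance
#'   from the scaffold span (>= 0); default 2 nm.
#' @return A `data.frame` with one row per bound scaffold: receptor indices
#'   `i`, `j`, midpoint `mx`, `my` (micrometers), pair distance `d_nm`.
#' @export
match_scaffold_pairs <- function(ps, spacing_nm, reach_tolerance_nm = 2) {
  stopifnot(inherits(ps, "point_set"))
  if (spacing_nm <= 0) stop("spacing_nm must be > 0")
  if (reach_tolerance_nm < 0) stop("reach_tolerance_nm must be >= 0")
  n <- length(ps$x)
  empty <- data.frame(i = integer(), j = integer(), mx = numeric(),
                      my = numeric(), d_nm = numeric())
  if (n < 2) return(empty)
  nn <- .nn_info(ps$x, ps$y)
  i <- seq_len(n)
  mutual <- which(nn$index[nn$index[i]] == i & i < nn$index[i])
  if (length(mutual) == 0) return(empty)
  j <- nn$index[mutual]
  d_nm <- nn$dist[mutual] * 1000
  ok <- abs(d_nm - spacing_nm) <= reach_tolerance_nm
  data.frame(i = mutual[ok], j = j[ok],
             mx = (ps$x[mutual[ok]] + ps$x[j[ok]]) / 2,
             my = (ps$y[mutual[ok]] + ps$y[j[ok]]) / 2,
             d_nm = d_nm[ok])
}

# bin arbitrary (x, y) source positions, each with `photons` expected
# photons, onto the field pixel grid
bin_sources <- function(x, y, field, photons) {
  m <- matrix(0, field$ny, field$nx)
  if (length(x) == 0) return(m)
  j <- pmin(field$nx, floor(x * field$pixel_scale) + 1L)
  i <- pmin(field$ny, floor(y * field$pixel_scale) + 1L)
  idx <- i + (j - 1L) * field$ny
  tab <- table(factor(idx, levels = seq_len(field$ny * field$nx)))
  m[] <- as.numeric(tab) * photons
  m
}

#' Default per-channel optics for selectivity stacks
#'
#' Antibody and ligand channels use the standard [optics_spec()]; the
#' nucleus channel is a bright areal stain (DAPI-like), rendered at 500
#' expected photons per nucleus pixel so that nuclear segmentation is
#' contrast-limited rather than noise-limited.
#'
#' @return Named list of [optics_spec()] objects (`antibody`, `ligand`,
#'   `nucleus`).
#' @export
stack_optics <- function() {
  list(antibody = optics_spec(),
       ligand = optics_spec(),
       nucleus = optics_spec(photons_per_receptor = 500))
}

#' Simulate a three-channel selectivity Z-stack
#'
#' Renders the confocal acquisition used by the selectivity pipeline:
#' an antibody channel showing every receptor, a ligand-label channel
#' showing one dye per bound bivalent scaffold (placed at the midpoint of
#' its receptor pair, see [match_scaffold_pairs()]), and a nucleus channel
#' staining the nucleus ellipse. Each channel is a Z-stack of `n_slices`
#' planes separated by `slice_step_um`; out-of-focus attenuation is Gaussian
#' in the slice offset from the central plane (s.d. `z_sigma_um`), and each
#' plane carries the full Poisson + read-noise camera model.
#'
#' @param truth a [make_scene()] object built with explicit points.
#' @param scaffold_spacing_nm designed ligand spacing (> 0).
#' @param reach_tolerance_nm binding tolerance in nanometers.
#' @param optics an [optics_spec()] applied to every channel, or a named
#'   list with elements `antibody`, `ligand`, `nucleus` (default
#'   [stack_optics()]).
#' @param n_slices number of Z planes (default 15).
#' @param slice_step_um Z step (default 0.2).
#' @param z_sigma_um Gaussian Z-attenuation scale (default 0.5).
#' @param seed integer seed.
#' @return An object of class `selectivity_stack`: `channels` (named list of
#'   `ny x nx x n_slices` arrays), `pairs` (the matched scaffold table),
#'   `n_matched`, acquisition metadata, and the generating scene parameters.
#' @export
simulate_selectivity_stack <- function(truth, scaffold_spacing_nm,
                                       reach_tolerance_nm = 2,
                                       optics = stack_optics(),
                                       n_slices = 15L, slice_step_um = 0.2,
                                       z_sigma_um = 0.5, seed = 1L) {
  stopifnot(inherits(truth, "scene_truth"))
  if (is.null(truth$points))
    stop("simulate_selectivity_stack needs a scene with explicit points ",
         "(make_scene(..., keep_points = TRUE))")
  if (n_slices < 1) stop("n_slices must be >= 1, got ", n_slices)
  if (scaffold_spacing_nm <= 0) stop("scaffold_spacing_nm must be > 0")
  if (reach_tolerance_nm < 0) stop("reach_tolerance_nm must be >= 0")
  if (inherits(optics, "optics_spec"))
    optics <- list(antibody = optics, ligand = optics, nucleus = optics)
  stopifnot(all(c("antibody", "ligand", "nucleus") %in% names(optics)))

  f <- truth$field
  pairs <- match_scaffold_pairs(truth$points, scaffold_spacing_nm,
                                reach_tolerance_nm)
  src <- list(
    antibody = truth$counts * optics$antibody$photons_per_receptor,
    ligand = bin_sources(pairs$mx, pairs$my, f,
                         optics$ligand$photons_per_receptor),
    nucleus = truth$nucleus_mask * optics$nucleus$photons_per_receptor)

  k <- seq_len(n_slices)
  zw <- exp(-((k - (n_slices + 1) / 2) * slice_step_um)^2 /
              (2 * z_sigma_um^2))
  channels <- with_seed(seed, {
    lapply(names(src), function(ch) {
      op <- optics[[ch]]
      base <- psf_blur(src[[ch]], op$psf_sigma_nm * 1e-3 * f$pixel_scale)
      arr <- array(0, dim = c(f$ny, f$nx, n_slices))
      for (s in k) {
        expected <- base * zw[s] + op$background_rate
        plane <- matrix(rpois(length(expected), as.vector(expected)),
                        f$ny, f$nx)
        if (op$read_noise_sd > 0)
          plane <- plane + matrix(rnorm(length(plane), 0, op$read_noise_sd),
                                  f$ny, f$nx)
        arr[, , s] <- plane
      }
      arr
    })
  })
  names(channels) <- names(src)
  structure(list(channels = channels, pairs = pairs,
                 n_matched = nrow(pairs),
                 scaffold_spacing_nm = scaffold_spacing_nm,
                 reach_tolerance_nm = reach_tolerance_nm,
                 n_slices = as.integer(n_slices),
                 slice_step_um = slice_step_um, z_sigma_um = z_sigma_um,
                 pixel_scale = f$pixel_scale, field = f,
                 cell = truth$cell, nucleus = truth$nucleus,
                 density = truth$density, seed = seed),
            class = "selectivity_stack")
}

#' @export
print.selectivity_stack <- function(x, ...) {
  cat(sprintf(
    "<selectivity_stack> %d x %d px x %d slices, %.3g nm scaffold, %d bound\n",
    x$field$nx, x$field$ny, x$n_slices, x$scaffold_spacing_nm, x$n_matched))
  invisible(x)
}
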