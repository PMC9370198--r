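#' Spacing-model configuration
#'
#' Parameters of the within-pixel receptor spacing model. Defaults are the
#' package's standard imaging and packing constants: 3.115 pixels per
#' micrometer (20X objective), a random-sequential-adsorption jamming
#' fraction of 0.55 for non-overlapping discs, a 5 nm receptor footprint
#' (the lower end of the 5-10 nm integrin headpiece diameter, so the cap
#' does not truncate the densest ~10 nm regime), and the square-lattice
#' within-pixel rule.
#'
#' @param pixel_scale pixels per micrometer.
#' @param jamming_fraction maximal surface coverage in (0, 1].
#' @param receptor_footprint_nm receptor footprint (disc) diameter, nm.
#' @param within_pixel_rule `"lattice"` (`d = side / sqrt(n)`) or
#'   `"poisson"` (`d = 0.5 * side / sqrt(n)`), the two standard readings of
#'   an even within-pixel distribution.
#' @param background_margin_px dilation margin (pixels) separating the cell
#'   mask from the background region used for background estimation.
#' @param gain_ratio imaging-to-plate-reader gain ratio applied before the
#'   calibration curve (see [receptors_from_intensity()]).
#' @return An object of class `spacing_config`.
#' @export
spacing_config <- function(pixel_scale = 3.115, jamming_fraction = 0.55,
                           receptor_footprint_nm = 5,
                           within_pixel_rule = c("lattice", "poisson"),
                           background_margin_px = 5L, gain_ratio = 1) {
  within_pixel_rule <- match.arg(within_pixel_rule)
  stopifnot(pixel_scale > 0, jamming_fraction > 0, jamming_fraction <= 1,
            receptor_footprint_nm > 0, background_margin_px >= 0,
            gain_ratio > 0)
  structure(list(pixel_scale = pixel_scale,
                 jamming_fraction = jamming_fraction,
                 receptor_footprint_nm = receptor_footprint_nm,
                 within_pixel_rule = within_pixel_rule,
                 background_margin_px = as.integer(background_margin_px),
                 gain_ratio = gain_ratio),
            class = "spacing_config")
}

#' Jamming-limited receptor capacity of one pixel
#'
#' Maximal receptor count a pixel can hold under random sequential
#' adsorption of non-overlapping receptor footprints:
#' `cap = jamming_fraction * pixel_area / footprint_area`, with
#' `pixel_area = (1000 / pixel_scale)^2` square nanometers and
#' `footprint_area = pi * (d/2)^2`.
#'
#' @param config a [spacing_config()].
#' @return Real-valued receptor capacity per pixel.
#' @examples
#' max_count_per_pixel(spacing_config())  # ~2887 receptors per pixel
#' @export
max_count_per_pixel <- function(config = spacing_config()) {
  stopifnot(inherits(config, "spacing_config"))
  side_nm <- 1000 / config$pixel_scale
  config$jamming_fraction * side_nm^2 /
    (pi * (config$receptor_footprint_nm / 2)^2)
}

#' Allocate a calibrated receptor total over cell pixels
#'
#' Distributes `total_receptors` over the pixels of `mask` proportionally
#' to background-subtracted image intensity, then enforces the per-pixel
#' jamming cap ([max_count_per_pixel()]) by iteratively redistributing the
#' excess over uncapped pixels (water-filling; at most 100 iterations,
#' convergence to 1e-6 of the total). Counts stay real-valued. If the total
#' exceeds the mask's capped capacity the map saturates at the cap and is
#' flagged.
#'
#' The background is the mean intensity outside a
#' `config$background_margin_px` dilation of the mask.
#'
#' @param image 2-D numeric intensity matrix.
#' @param mask logical matrix / [new_mask()] (`TRUE` = cell); non-empty.
#' @param total_receptors calibrated receptor total (>= 0).
#' @param config a [spacing_config()].
#' @return An object of class `density_map`: `n` (per-pixel receptor
#'   counts), `mask`, `config`, `total_allocated`, `cap_per_pixel`,
#'   `saturated`, `background`.
#' @export
allocate_receptors <- function(image, mask, total_receptors,
                               config = spacing_config()) {
  stopifnot(is.matrix(image), all(dim(image) == dim(mask)),
            total_receptors >= 0)
  mask_m <- matrix(as.logical(mask), nrow(image), ncol(image))
  if (!any(mask_m)) stop("mask is empty; nothing to allocate onto")
  cap <- max_count_per_pixel(config)
  n <- matrix(0, nrow(image), ncol(image))
  bg <- background_outside_mask(image, mask_m, config$background_margin_px)

  if (total_receptors == 0) {
    return(structure(list(n = n, mask = mask_m, config = config,
                          total_allocated = 0, cap_per_pixel = cap,
                          saturated = FALSE, background = bg),
                     class = "density_map"))
  }
  w <- pmax(image - bg, 0)
  w[!mask_m] <- 0
  if (sum(w) == 0) {
    warning("all-zero background-subtracted intensity in mask; ",
            "allocating uniformly")
    w[mask_m] <- 1
  }

  npix <- sum(mask_m)
  saturated <- total_receptors > cap * npix + 1e-9
  if (saturated) {
    warning(sprintf(
      "total %.6g exceeds mask capacity %.6g (= cap %.6g x %d px); ",
      total_receptors, cap * npix, cap, npix),
      "allocating to capacity")
    n[mask_m] <- cap
    total_alloc <- cap * npix
  } else {
    idx <- which(mask_m & w > 0)
    # pixels with zero weight inside the mask receive nothing
    alloc <- numeric(length(idx))
    capped <- rep(FALSE, length(idx))
    wi <- w[idx]
    for (it in seq_len(100L)) {
      free <- !capped
      if (!any(free)) break
      remaining <- total_receptors - cap * sum(capped)
      alloc[free] <- remaining * wi[free] / sum(wi[free])
      over <- free & alloc > cap
      if (!any(over) ||
          abs(sum(pmin(alloc, cap)) - total_receptors) <
            1e-6 * total_receptors) {
        alloc[over] <- cap
        break
      }
      capped[over] <- TRUE
      alloc[capped] <- cap
    }
    n[idx] <- pmin(alloc, cap)
    total_alloc <- sum(n)
    if (total_alloc < total_receptors * (1 - 1e-6)) {
      # mask pixels with zero weight cannot receive receptors; the
      # positive-weight pixels alone ran out of capacity
      warning("positive-intensity mask pixels saturated at the jamming cap; ",
              "allocated ", signif(total_alloc, 6), " of ",
              signif(total_receptors, 6), " receptors")
      saturated <- TRUE
    }
  }
  structure(list(n = n, mask = mask_m, config = config,
                 total_allocated = total_alloc, cap_per_pixel = cap,
                 saturated = saturated, background = bg),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "<density_map> %d x %d px, %.6g receptors over %d mask px (cap %.5g%s)\n",
    nrow(x$n), ncol(x$n), x$total_allocated, sum(x$mask), x$cap_per_pixel,
    if (x$saturated) ", SATURATED" else ""))
  invisible(x)
}

#' Within-pixel nearest-neighbor spacing
#'
#' Converts a per-pixel receptor count into the nearest-neighbor distance
#' under an even within-pixel distribution. The lattice rule places `n`
#' receptors on a square lattice: `d = side / sqrt(n)`; the poisson rule
#' uses the mean nearest-neighbor distance of a Poisson process of the same
#' density: `d = 0.5 * side / sqrt(n)`. `side = 1000 / pixel_scale` nm.
#'
#' @param n_p per-pixel receptor count(s); non-positive entries yield `NA`
#'   (no spacing contribution).
#' @param config a [spacing_config()].
#' @return Spacing(s) in nanometers.
#' @examples
#' pixel_nn_spacing(1)    # 321.0 nm at the default pixel scale
#' pixel_nn_spacing(100)  # 32.1 nm
#' @export
pixel_nn_spacing <- function(n_p, config = spacing_config()) {
  stopifnot(inherits(config, "spacing_config"))
  side_nm <- 1000 / config$pixel_scale
  d <- side_nm / sqrt(pmax(n_p, 0))
  if (config$within_pixel_rule == "poisson") d <- 0.5 * d
  d[!is.finite(d) | n_p <= 0] <- NA_real_
  d
}

#' Receptor-count-weighted spacing distribution
#'
#' Each pixel with a positive allocated count contributes its within-pixel
#' spacing, weighted by its receptor count; weights are normalized to sum
#' to one. Summary statistics (weighted median, mode, interquartile range)
#' are computed on the weighted sample. The mode is the spacing with the
#' largest aggregated weight after rounding spacings to 0.1 nm (reported as
#' the weighted mean of the raw spacings in the winning bin).
#'
#' @param dmap a [allocate_receptors()] density map with at least one
#'   positive pixel.
#' @return An object of class `spacing_distribution`: `samples` (data.frame
#'   `d_nm`, `weight`, sorted by spacing, weights summing to 1),
#'   `summary` (`median_nm`, `mode_nm`, `iqr_nm`, `q25_nm`, `q75_nm`),
#'   `within_pixel_rule`, `n_pixels`, `total_receptors`.
#' @export
spacing_distribution <- function(dmap) {
  stopifnot(inherits(dmap, "density_map"))
  n_p <- dmap$n[dmap$n > 0]
  if (length(n_p) == 0)
    stop("density map has no pixel with a positive receptor count; ",
         "spacing distribution undefined")
  d <- pixel_nn_spacing(n_p, dmap$config)
  w <- n_p / sum(n_p)
  o <- order(d)
  d <- d[o]; w <- w[o]
  q <- weighted_quantile(d, w, c(0.25, 0.5, 0.75))
  bins <- round(d, 1)
  wa <- vapply(split(w, bins), sum, numeric(1))
  top <- names(wa)[which.max(wa)]
  in_top <- bins == as.numeric(top)
  mode_nm <- sum(d[in_top] * w[in_top]) / sum(w[in_top])
  structure(list(samples = data.frame(d_nm = d, weight = w),
                 summary = list(median_nm = q[2], mode_nm = mode_nm,
                                iqr_nm = q[3] - q[1],
                                q25_nm = q[1], q75_nm = q[3]),
                 within_pixel_rule = dmap$config$within_pixel_rule,
                 n_pixels = length(n_p),
                 total_receptors = dmap$total_allocated),
            class = "spacing_distribution")
}

#' @export
print.spacing_distribution <- function(x, ...) {
  cat(sprintf(
    "<spacing_distribution> %d pixels, %.6g receptors (%s rule)\n",
    x$n_pixels, x$total_receptors, x$within_pixel_rule))
  cat(sprintf("  median %.4g nm, mode %.4g nm, IQR %.4g nm\n",
              x$summary$median_nm, x$summary$mode_nm, x$summary$iqr_nm))
  invisible(x)
}

#' Percentile-capped, normalized heatmap
#'
#' Caps pixel intensities at the `cap_percentile`-th percentile and divides
#' by that value, giving a display grid in \[0, 1\]; applied before any
#' colormap lookup. A constant image yields an all-ones heatmap with a
#' warning (the cap equals the maximum).
#'
#' @param x numeric matrix (an intensity image or a density map's `n`), or
#'   an [allocate_receptors()] density map.
#' @param cap_percentile percentile in (0, 100\] (default 98).
#' @param colormap data.frame with columns `value`, `R`, `G`, `B`
#'   (`value` in \[0, 1\], channels in \[0, 1\]); defaults to a
#'   viridis-like ramp.
#' @return An object of class `heatmap_grid`: `values` in \[0, 1\],
#'   `cap_percentile`, `cap_value`, `colormap`.
#' @export
render_heatmap <- function(x, cap_percentile = 98,
                           colormap = default_colormap()) {
  if (inherits(x, "density_map")) x <- x$n
  stopifnot(is.matrix(x), length(x) > 0,
            cap_percentile > 0, cap_percentile <= 100)
  cap_value <- unname(quantile(x, cap_percentile / 100))
  if (min(x) == max(x)) {
    warning("constant image; cap equals the maximum, heatmap is uniform")
    vals <- matrix(1, nrow(x), ncol(x))
    cap_value <- max(x)
  } else if (cap_value <= 0) {
    warning("cap percentile value is not positive; normalizing by the maximum")
    cap_value <- max(x)
    vals <- pmin(x, cap_value) / cap_value
    vals[vals < 0] <- 0
  } else {
    vals <- pmin(x, cap_value) / cap_value
    vals[vals < 0] <- 0
  }
  structure(list(values = vals, cap_percentile = cap_percentile,
                 cap_value = cap_value, colormap = colormap),
            class = "heatmap_grid")
}

#' Default heatmap colormap reference values
#'
#' Nine anchor points of a viridis ramp; intermediate display values are
#' linearly interpolated. Users may supply their own reference table to
#' [render_heatmap()].
#'
#' @return data.frame with columns `value`, `R`, `G`, `B` (all in \[0, 1\]).
#' @export
default_colormap <- function() {
  v <- seq(0, 1, length.out = 9)
  cols <- colorRamp(hcl.colors(9, "viridis"))(v) / 255
  data.frame(value = v, R = cols[, 1], G = cols[, 2], B = cols[, 3])
}

#' Write a heatmap to PNG through its colormap
#'
#' @param hm a [render_heatmap()] object.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(hm, path) {
  stopifnot(inherits(hm, "heatmap_grid"))
  cm <- hm$colormap
  rgb <- array(0, dim = c(nrow(hm$values), ncol(hm$values), 3))
  for (k in 1:3) {
    chan <- c("R", "G", "B")[k]
    rgb[, , k] <- matrix(
      stats::approx(cm$value, cm[[chan]], xout = as.vector(hm$values),
                    rule = 2)$y,
      nrow(hm$values), ncol(hm$values))
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Full receptor-spacing pipeline
#'
#' Composition of the spacing workflow on one image: segment the cell
#' (trained classifier or supplied mask), estimate the background, convert
#' the background-corrected summed cell intensity to a receptor total with
#' the calibration curve, allocate the total over cell pixels by intensity
#' under the jamming cap, and derive the weighted spacing distribution and
#' a percentile-capped heatmap.
#'
#' @param image 2-D numeric intensity matrix.
#' @param curve a [fit_calibration()] curve.
#' @param mask optional logical mask (`TRUE` = cell); if `NULL`,
#'   `classifier` is applied.
#' @param classifier optional [train_classifier()] model.
#' @param config a [spacing_config()].
#' @param cap_percentile heatmap cap percentile.
#' @return A list of class `spacing_result`: `distribution`
#'   ([spacing_distribution()]), `heatmap` ([render_heatmap()] of the
#'   density map), `density_map`, `total_receptors`, `mask`, `background`.
#' @export
run_spacing_pipeline <- function(image, curve, mask = NULL,
                                 classifier = NULL,
                                 config = spacing_config(),
                                 cap_percentile = 98) {
  stopifnot(is.matrix(image), inherits(curve, "calibration_curve"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(mask)) {
    if (is.null(classifier))
      stop("stage 'segmentation' failed: supply either a mask or a ",
           "trained classifier")
    mask <- stage("segmentation", predict_mask(image, classifier))
  }
  mask_m <- matrix(as.logical(mask), nrow(image), ncol(image))
  if (!any(mask_m))
    stop("stage 'segmentation' failed: empty cell mask")
  bg <- stage("background",
              background_outside_mask(image, mask_m,
                                      config$background_margin_px))
  total_intensity <- sum(pmax(image[mask_m] - bg, 0))
  total <- stage("calibration",
                 receptors_from_intensity(total_intensity, curve,
                                          gain_ratio = config$gain_ratio))
  dmap <- stage("allocation",
                allocate_receptors(image, mask_m, total, config))
  dist <- stage("spacing", spacing_distribution(dmap))
  hm <- stage("heatmap", render_heatmap(dmap$n, cap_percentile))
  structure(list(distribution = dist, heatmap = hm, density_map = dmap,
                 total_receptors = total, mask = mask_m, background = bg),
            class = "spacing_result")
}

#' @export
print.spacing_result <- function(x, ...) {
  cat(sprintf("<spacing_result> %.6g receptors over %d cell px\n",
              x$total_receptors, sum(x$mask)))
  print(x$distribution)
  invisible(x)
}

#' Spacing-recovery simulation study
#'
#' End-to-end validation run: for each seed, builds a synthetic scene with
#' uniform receptor density `density` inside an elliptical cell, renders the
#' stained image, simulates and fits a matched calibration series, segments
#' the cell with a classifier trained on `n_train` separately rendered
#' scenes, and runs [run_spacing_pipeline()]. Under the lattice rule the
#' true spacing is `1000 / sqrt(density)` nm (density per square
#' micrometer).
#'
#' @param density receptors per square micrometer.
#' @param n_seeds number of independent scenes.
#' @param seed base seed; per-scene seeds are derived from it.
#' @param image_px image side in pixels (square field).
#' @param optics an [optics_spec()].
#' @param config a [spacing_config()].
#' @param n_train training images for the classifier (default 3).
#' @param classifier optional pre-trained classifier (skips training).
#' @return data.frame with one row per seed: `seed`, `median_nm`,
#'   `mode_nm`, `total_receptors`, `true_n`, plus attributes
#'   `true_spacing_nm` and `classifier`.
#' @export
simulate_spacing_recovery <- function(density, n_seeds = 10L, seed = 1L,
                                      image_px = 512L,
                                      optics = optics_spec(),
                                      config = spacing_config(),
                                      n_train = 3L, classifier = NULL) {
  field <- field_from_pixels(image_px, image_px, config$pixel_scale)
  if (is.null(classifier)) {
    tr_seeds <- seed * 1000L + seq_len(n_train)
    imgs <- list(); labs <- list()
    for (k in seq_len(n_train)) {
      sc <- make_scene(field, density, keep_points = FALSE,
                       seed = tr_seeds[k])
      imgs[[k]] <- render_stained_image(sc, optics, seed = tr_seeds[k] + 500L)
      labs[[k]] <- sc$cell_mask
    }
    classifier <- train_classifier(imgs, labs, seed = seed)
  }
  # calibration series on the plate-reader scale of the rendered images:
  # intensity per antibody equals the photon yield per label
  res <- lapply(seq_len(n_seeds), function(k) {
    s <- seed * 10000L + k
    sc <- make_scene(field, density, keep_points = FALSE, seed = s)
    img <- render_stained_image(sc, optics, seed = s + 1L)
    series <- simulate_calibration_series(
      slope_truth = optics$photons_per_receptor, intercept_truth = 50,
      levels = max(1, sum(sc$counts)) * 2^-(0:7), replicates = 3L,
      noise_sd = optics$photons_per_receptor, seed = s + 2L)
    curve <- fit_calibration(series)
    out <- run_spacing_pipeline(img, curve, classifier = classifier,
                                config = config)
    data.frame(seed = s, median_nm = out$distribution$summary$median_nm,
               mode_nm = out$distribution$summary$mode_nm,
               total_receptors = out$total_receptors,
               true_n = sum(sc$counts))
  })
  out <- do.call(rbind, res)
  attr(out, "true_spacing_nm") <- 1000 / sqrt(density)
  attr(out, "classifier") <- classifier
  out
}
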