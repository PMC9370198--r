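# Shared fixtures, all generated in code under fixed seeds.

# A small rendered cell scene with everything downstream needs.
small_scene_fixture <- function(density = 2500, px = 96L, seed = 11L,
                                optics = optics_spec()) {
  field <- field_from_pixels(px, px)
  scene <- make_scene(field, density, keep_points = FALSE, seed = seed)
  image <- render_stained_image(scene, optics, seed = seed + 1L)
  list(field = field, scene = scene, image = image, optics = optics)
}

# Calibration curve matched to the rendering optics of a scene fixture.
matched_curve <- function(fx, seed = 21L) {
  total <- max(1, sum(fx$scene$counts))
  series <- simulate_calibration_series(
    slope_truth = fx$optics$photons_per_receptor, intercept_truth = 50,
    levels = total * 2^-(0:7), replicates = 3L,
    noise_sd = fx$optics$photons_per_receptor, seed = seed)
  fit_calibration(series)
}

# Independent brute-force spacing distribution: explicit loop over pixels.
brute_force_spacing <- function(dmap) {
  d <- numeric(0); w <- numeric(0)
  side_nm <- 1000 / dmap$config$pixel_scale
  for (i in seq_len(nrow(dmap$n))) {
    for (j in seq_len(ncol(dmap$n))) {
      n_p <- dmap$n[i, j]
      if (n_p > 0) {
        dd <- side_nm / sqrt(n_p)
        if (dmap$config$within_pixel_rule == "poisson") dd <- dd / 2
        d <- c(d, dd)
        w <- c(w, n_p)
      }
    }
  }
  o <- order(d)
  list(d_nm = d[o], weight = (w / sum(w))[o])
}

# Brute-force nearest-neighbor distances via the full distance matrix.
brute_force_nn <- function(x, y) {
  D <- as.matrix(dist(cbind(x, y)))
  diag(D) <- Inf
  unname(apply(D, 1, min))
}

# A scene built from hand-placed receptor coordinates.
scene_from_coords <- function(x, y, width = 2, height = 2,
                              pixel_scale = 3.115) {
  field <- field_spec(width, height, pixel_scale)
  cell <- ellipse_um(width / 2, height / 2, width * 0.45, height * 0.45)
  nucleus <- ellipse_um(width / 2, height / 2, width * 0.1, height * 0.1)
  scene <- make_scene(field, density = 0, cell = cell, nucleus = nucleus,
                      keep_points = TRUE, seed = 1L)
  pts <- point_set(x, y, field)
  scene$points <- pts
  scene$counts <- matrix(0L, field$ny, field$nx)
  scene$counts[] <- tabulate(
    pmin(field$ny, floor(y * pixel_scale) + 1L) +
      (pmin(field$nx, floor(x * pixel_scale) + 1L) - 1L) * field$ny,
    nbins = field$ny * field$nx)
  scene
}
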