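test_that("jamming cap follows the disc-packing arithmetic", {
  cfg <- spacing_config()
  # direct arithmetic oracle: phi * (1000/s)^2 / (pi (d/2)^2)
  side <- 1000 / 3.115
  expect_equal(max_count_per_pixel(cfg),
               0.55 * side^2 / (pi * 2.5^2), tolerance = 1e-12)
  expect_equal(max_count_per_pixel(cfg), 2886.6, tolerance = 1e-3)
  # doubling the footprint divides the cap by 4
  cfg2 <- spacing_config(receptor_footprint_nm = 10)
  expect_equal(max_count_per_pixel(cfg2), max_count_per_pixel(cfg) / 4)
  # config invariants
  expect_error(spacing_config(jamming_fraction = 0))
  expect_error(spacing_config(jamming_fraction = 1.2))
  expect_error(spacing_config(receptor_footprint_nm = 0))
})

test_that("allocation is proportional, conservative, and capped", {
  img <- matrix(c(1, 3), 1, 2)
  mask <- matrix(TRUE, 1, 2)
  dm <- suppressWarnings(allocate_receptors(img, mask, 8))
  expect_equal(as.vector(dm$n), c(2, 6))
  expect_equal(dm$total_allocated, 8)
  expect_false(dm$saturated)

  # uniform intensity: symmetric split
  dm2 <- suppressWarnings(
    allocate_receptors(matrix(5, 1, 2), mask, 10))
  expect_equal(as.vector(dm2$n), c(5, 5))

  # zero total
  dm0 <- suppressWarnings(allocate_receptors(img, mask, 0))
  expect_true(all(dm0$n == 0))
  expect_error(allocate_receptors(img, matrix(FALSE, 1, 2), 5), "empty")
})

test_that("cap redistribution conserves the total and respects the bound", {
  cfg <- spacing_config()
  cap <- max_count_per_pixel(cfg)
  # one dominant pixel would exceed the cap; excess flows to the others
  img <- matrix(c(1000, 1, 1, 1), 2, 2)
  total <- cap * 1.8
  dm <- suppressWarnings(allocate_receptors(img, matrix(TRUE, 2, 2), total))
  expect_true(all(dm$n <= cap + 1e-9))
  expect_equal(sum(dm$n), total, tolerance = 1e-6)
  expect_equal(max(dm$n), cap)

  # saturation: total above mask capacity allocates to capacity and flags
  suppressWarnings(
    expect_warning(
      dms <- allocate_receptors(img, matrix(TRUE, 2, 2), cap * 5),
      "capacity"))
  expect_true(dms$saturated)
  expect_equal(sum(dms$n), cap * 4, tolerance = 1e-9)
})

test_that("allocation conserves receptor totals on random fixtures", {
  cfg <- spacing_config()
  cap <- max_count_per_pixel(cfg)
  set.seed(99)
  for (k in 1:20) {
    nr <- sample(4:16, 1); nc <- sample(4:16, 1)
    img <- matrix(runif(nr * nc, 0, 100), nr, nc)
    mask <- matrix(runif(nr * nc) < 0.6, nr, nc)
    if (!any(mask)) next
    total <- runif(1, 0, 0.9 * cap * sum(mask))
    dm <- suppressWarnings(allocate_receptors(img, mask, total, cfg))
    expect_equal(dm$total_allocated, total, tolerance = 1e-6)
    expect_equal(sum(dm$n), total, tolerance = 1e-6)
    expect_true(all(dm$n <= cap + 1e-9))
    expect_true(all(dm$n[!mask] == 0))
  }
})

test_that("within-pixel spacing follows the lattice and poisson rules", {
  expect_equal(pixel_nn_spacing(1), 1000 / 3.115, tolerance = 1e-12)
  expect_equal(pixel_nn_spacing(1), 321.0, tolerance = 1e-4)
  expect_equal(pixel_nn_spacing(100), 32.1, tolerance = 1e-3)
  # n_p for density 1e4 um^-2: rho * pixel_area -> d = 1/sqrt(rho) = 10 nm
  n_p <- 1e4 / 3.115^2
  expect_equal(pixel_nn_spacing(n_p), 10, tolerance = 1e-12)
  cfgp <- spacing_config(within_pixel_rule = "poisson")
  expect_equal(pixel_nn_spacing(100, cfgp), 0.5 * 32.10273, tolerance = 1e-6)
  expect_true(is.na(pixel_nn_spacing(0)))
  expect_true(is.na(pixel_nn_spacing(-3)))
})

test_that("spacing distribution matches the brute-force per-pixel oracle exactly", {
  cfg <- spacing_config()
  set.seed(7)
  for (k in 1:5) {
    nr <- sample(8:64, 1); nc <- sample(8:64, 1)
    img <- matrix(rpois(nr * nc, 50), nr, nc)
    mask <- matrix(runif(nr * nc) < 0.5, nr, nc)
    if (!any(mask)) next
    dm <- suppressWarnings(allocate_receptors(img, mask, 5000, cfg))
    if (all(dm$n == 0)) next
    sd_ <- spacing_distribution(dm)
    bf <- brute_force_spacing(dm)
    expect_equal(sd_$samples$d_nm, bf$d_nm)
    expect_equal(sd_$samples$weight, bf$weight)
    expect_equal(sum(sd_$samples$weight), 1)
  }
})

test_that("two-pixel example reproduces the hand-computed distribution", {
  cfg <- spacing_config(pixel_scale = 1000 / 320)  # 320 nm pixel side
  dm <- structure(list(n = matrix(c(4, 16), 1, 2),
                       mask = matrix(TRUE, 1, 2), config = cfg,
                       total_allocated = 20,
                       cap_per_pixel = max_count_per_pixel(cfg),
                       saturated = FALSE, background = 0),
                  class = "density_map")
  sd_ <- spacing_distribution(dm)
  expect_equal(sd_$samples$d_nm, c(80, 160))
  expect_equal(sd_$samples$weight, c(0.8, 0.2))
  expect_equal(sd_$summary$median_nm, 80)
  # degenerate uniform map: median = mode = the single spacing
  dmu <- dm; dmu$n <- matrix(c(9, 9), 1, 2)
  sdu <- spacing_distribution(dmu)
  expect_equal(sdu$summary$median_nm, 320 / 3)
  expect_equal(sdu$summary$mode_nm, 320 / 3)
  # doubling every count divides every spacing by sqrt(2)
  dm2 <- dm; dm2$n <- dm$n * 2
  sd2 <- spacing_distribution(dm2)
  expect_equal(sd2$samples$d_nm, sd_$samples$d_nm / sqrt(2))
  expect_equal(sd2$samples$weight, sd_$samples$weight)
  # empty map errors
  dme <- dm; dme$n <- matrix(0, 1, 2)
  expect_error(spacing_distribution(dme), "positive")
})

test_that("heatmap caps at the percentile and normalizes to [0, 1]", {
  ramp <- matrix(1:100, 10, 10)
  hm <- render_heatmap(ramp, cap_percentile = 98)
  expect_equal(hm$cap_value, unname(quantile(1:100, 0.98)))
  expect_equal(sum(hm$values == 1), 2L)  # pixels 99 and 100 clip
  expect_true(all(hm$values >= 0 & hm$values <= 1))
  # cap 100 reduces to max-normalization
  hm100 <- render_heatmap(ramp, cap_percentile = 100)
  expect_equal(hm100$values[100], 1)
  expect_equal(hm100$values[50], 50 / 100)
  expect_warning(hmc <- render_heatmap(matrix(7, 4, 4)), "constant")
  expect_true(all(hmc$values == 1))
})

test_that("increasing the receptor total never increases the weighted median spacing", {
  fx <- small_scene_fixture(density = 2500, px = 64, seed = 33)
  mask <- fx$scene$cell_mask
  meds <- vapply(c(1e4, 3e4, 1e5, 3e5, 1e6), function(tot) {
    dm <- suppressWarnings(allocate_receptors(fx$image, mask, tot))
    spacing_distribution(dm)$summary$median_nm
  }, numeric(1))
  expect_true(all(diff(meds) <= 1e-9))
})

test_that("full pipeline recovers the three density regimes on single scenes", {
  for (rho in c(1e4, 2.5e3, 1.11e3)) {
    fx <- small_scene_fixture(density = rho, px = 128, seed = 55)
    cv <- matched_curve(fx)
    mask <- threshold_mask(fx$image, min_object_px = 50,
                           closing_radius_px = 3, fill_holes = TRUE)
    res <- run_spacing_pipeline(fx$image, cv, mask = mask)
    truth <- 1000 / sqrt(rho)
    expect_lt(abs(res$distribution$summary$median_nm - truth) / truth, 0.15)
  }
})

test_that("pipeline reports stage names on failure", {
  cv <- suppressWarnings(
    fit_calibration(data.frame(amount = c(0, 10), intensity = c(5, 25))))
  img <- matrix(1, 8, 8)
  expect_error(run_spacing_pipeline(img, cv, mask = matrix(FALSE, 8, 8)),
               "segmentation")
})

test_that("weighted quantiles agree with direct cumulative-weight computation", {
  x <- c(5, 1, 3); w <- c(0.5, 0.25, 0.25)
  expect_equal(weighted_quantile(x, w, 0.5), 3)
  expect_equal(weighted_quantile(x, w, 0.76), 5)
  expect_equal(weighted_quantile(x, w, 0.25), 1)
  expect_equal(weighted_quantile(rep(4, 3), c(1, 1, 1), c(0.1, 0.9)),
               c(4, 4))
})
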