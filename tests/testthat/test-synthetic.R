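test_that("point sampling is seeded, bounded, and handles the zero-rate process", {
  f <- field_spec(10, 10)
  a <- sample_points(f, 100, seed = 42)
  b <- sample_points(f, 100, seed = 42)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_true(all(a$x >= 0 & a$x <= 10 & a$y >= 0 & a$y <= 10))

  expect_equal(n_points(sample_points(f, 0, seed = 1)), 0L)
  expect_error(sample_points(f, -5, seed = 1), "-5")
})

test_that("homogeneous Poisson fields obey the count law and the NN distance law", {
  # density 1e4 um^-2 on 10 x 10 um: mean count 1e6, sd 1e3
  ps <- sample_points(field_spec(10, 10), 1e4, seed = 7)
  expect_lt(abs(n_points(ps) - 1e6), 4 * sqrt(1e6))
  # mean NN distance -> 0.5 / sqrt(rho) = 5 nm, within 2%
  mean_nn_nm <- mean(nn_distances(ps)) * 1000
  expect_lt(abs(mean_nn_nm - 5) / 5, 0.02)
})

test_that("cell-list NN distances agree with the brute-force distance matrix", {
  ps <- sample_points(field_spec(2, 3), 40, seed = 5)
  expect_equal(nn_distances(ps), brute_force_nn(ps$x, ps$y))
})

test_that("Thomas clustering pulls nearest neighbors closer than a Poisson field of equal intensity", {
  f <- field_spec(30, 30)
  cp <- list(parent_rate = 1, mean_offspring = 50, cluster_sd_um = 0.02)
  th <- sample_points(f, process = "thomas", cluster_params = cp, seed = 3)
  po <- sample_points(f, density = 50, seed = 3)
  d_th <- nn_distances(th)
  d_po <- nn_distances(po)
  # stochastically smaller: the thomas NN CDF dominates at every probe point
  for (q in c(0.005, 0.01, 0.02, 0.05)) {
    expect_gt(mean(d_th <= q), mean(d_po <= q))
  }
  expect_lt(mean(d_th), mean(d_po))
})

test_that("rendering satisfies the trivial and delta-PSF cases", {
  sc <- scene_from_coords(1.0, 1.0)
  dark <- optics_spec(psf_sigma_nm = 0, photons_per_receptor = 0,
                      background_rate = 0, read_noise_sd = 0)
  expect_true(all(render_stained_image(sc, dark, seed = 1) == 0))

  # single receptor, delta PSF, no shot/read noise surrogate: with Poisson
  # noise on a single source the photons still land in exactly one pixel
  op <- optics_spec(psf_sigma_nm = 0, photons_per_receptor = 1000,
                    background_rate = 0, read_noise_sd = 0)
  img <- render_stained_image(sc, op, seed = 2)
  expect_equal(sum(img > 0), 1L)
  expect_equal(sum(img), img[which.max(img)])
})

test_that("total rendered intensity matches the photon budget", {
  fx <- small_scene_fixture(density = 100, px = 64, seed = 9,
                            optics = optics_spec(psf_sigma_nm = 150,
                                                 photons_per_receptor = 100,
                                                 background_rate = 0,
                                                 read_noise_sd = 0))
  n <- sum(fx$scene$counts)
  # Poisson total: sd = sqrt(100 n)
  expect_lt(abs(sum(fx$image) - 100 * n), 4 * sqrt(100 * n))

  # with background: expectation over replicates
  op <- optics_spec(psf_sigma_nm = 150, photons_per_receptor = 50,
                    background_rate = 10, read_noise_sd = 2)
  tot <- vapply(1:5, function(s)
    sum(render_stained_image(fx$scene, op, seed = s)), numeric(1))
  expected <- 50 * n + 10 * prod(dim(fx$image))
  expect_lt(abs(mean(tot) - expected) / expected, 0.01)
})

test_that("labeling efficiency thins the expected photon count", {
  fx <- small_scene_fixture(density = 500, px = 64, seed = 13)
  op <- optics_spec(psf_sigma_nm = 0, photons_per_receptor = 40,
                    background_rate = 0, read_noise_sd = 0,
                    labeling_efficiency = 0.5)
  tot <- vapply(1:6, function(s)
    sum(render_stained_image(fx$scene, op, seed = s)), numeric(1))
  expected <- 0.5 * 40 * sum(fx$scene$counts)
  expect_lt(abs(mean(tot) - expected) / expected, 0.05)
})

test_that("calibration series generation is exact without noise and rejects bad input", {
  s <- simulate_calibration_series(2, 5, levels = 10, replicates = 4,
                                   noise_sd = 0, seed = 1)
  expect_equal(s$intensity, rep(25, 4))
  s0 <- simulate_calibration_series(2, 5, levels = 0, replicates = 3,
                                    noise_sd = 0, seed = 1)
  expect_equal(s0$intensity, rep(5, 3))
  expect_equal(nrow(simulate_calibration_series(1, 0, levels = 1:5,
                                                replicates = 10, seed = 2)),
               50L)
  expect_error(simulate_calibration_series(1, 0, levels = 1:3,
                                           noise_sd = -1), "noise_sd")
  # OLS on a noisy series recovers the slope within 3 standard errors
  s2 <- simulate_calibration_series(3, 0, levels = 1:5, replicates = 10,
                                    noise_sd = 0.1, seed = 8)
  fit <- lm(intensity ~ amount, data = s2)
  expect_lt(abs(coef(fit)["amount"] - 3),
            3 * summary(fit)$coefficients["amount", "Std. Error"])
})

test_that("scaffold pair matching honors the forced and empty cases", {
  # exactly two receptors 7 nm apart: one scaffold at their midpoint
  sc <- scene_from_coords(c(1.0, 1.007), c(1.0, 1.0))
  pairs <- match_scaffold_pairs(sc$points, spacing_nm = 7,
                                reach_tolerance_nm = 1)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$mx, 1.0035)
  expect_equal(pairs$my, 1.0)
  expect_equal(pairs$d_nm, 7, tolerance = 1e-9)

  # same pair, 36 nm scaffold: no match, ligand channel is background only
  st <- simulate_selectivity_stack(sc, 36, reach_tolerance_nm = 1,
                                   seed = 4)
  expect_equal(st$n_matched, 0L)
  op <- stack_optics()$ligand
  lig_mean <- mean(st$channels$ligand)
  expect_lt(abs(lig_mean - op$background_rate),
            4 * sqrt(op$background_rate / length(st$channels$ligand)) + 1)
})

test_that("matched-scaffold count per area increases with receptor density", {
  f <- field_spec(6, 6)
  n_dense <- n_sparse <- numeric(3)
  for (s in 1:3) {
    dense <- sample_points(f, 1e4, seed = s)
    sparse <- sample_points(f, 1e3, seed = s + 100)
    n_dense[s] <- nrow(match_scaffold_pairs(dense, 7, 2))
    n_sparse[s] <- nrow(match_scaffold_pairs(sparse, 7, 2))
  }
  expect_true(mean(n_dense) > mean(n_sparse))
})

test_that("selectivity stacks are seeded, shaped, and validated", {
  sc <- make_scene(field_from_pixels(24, 24), 2000, keep_points = TRUE,
                   seed = 6)
  a <- simulate_selectivity_stack(sc, 7, seed = 9)
  b <- simulate_selectivity_stack(sc, 7, seed = 9)
  expect_identical(a$channels, b$channels)
  expect_equal(dim(a$channels$antibody), c(24, 24, 15))
  expect_named(a$channels, c("antibody", "ligand", "nucleus"))
  expect_error(simulate_selectivity_stack(sc, 7, n_slices = 0), "n_slices")
  expect_error(simulate_selectivity_stack(sc, -7), "spacing")
  sc2 <- make_scene(field_from_pixels(24, 24), 100, keep_points = FALSE,
                    seed = 6)
  expect_error(simulate_selectivity_stack(sc2, 7), "explicit points")
})

test_that("scenes without explicit points draw the same point process per pixel", {
  f <- field_from_pixels(48, 48)
  n <- vapply(1:6, function(s)
    sum(make_scene(f, 2000, keep_points = FALSE, seed = s)$counts),
    numeric(1))
  sc <- make_scene(f, 2000, keep_points = FALSE, seed = 1)
  mu <- 2000 * sum(sc$cell_mask) / 3.115^2
  expect_lt(abs(mean(n) - mu), 4 * sqrt(mu / 6))
})
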