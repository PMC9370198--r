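test_that("Z-projection sums slices exactly", {
  one <- matrix(runif(36), 6, 6)
  expect_equal(z_project_sum(array(one, c(6, 6, 1))), one)
  rep15 <- array(rep(one, 15), c(6, 6, 15))
  expect_equal(z_project_sum(rep15), 15 * one)
  # elementwise brute-force oracle on a random stack
  arr <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  brute <- matrix(0, 6, 5)
  for (s in 1:4) brute <- brute + arr[, , s]
  expect_equal(z_project_sum(arr), brute)
})

test_that("cell and nucleus masks recover the generator geometry", {
  sc <- make_scene(field_from_pixels(64, 64), 5e3, keep_points = TRUE,
                   seed = 17)
  st <- simulate_selectivity_stack(sc, 7, seed = 18)
  cm <- build_cell_mask(z_project_sum(st$channels$antibody))
  nm <- build_nucleus_mask(z_project_sum(st$channels$nucleus))
  iou_cell <- sum(cm & sc$cell_mask) / sum(cm | sc$cell_mask)
  iou_nuc <- sum(nm & sc$nucleus_mask) / sum(nm | sc$nucleus_mask)
  expect_gt(iou_cell, 0.9)
  expect_gt(iou_nuc, 0.9)
  # nucleus sits inside a modest dilation of the cell mask
  dil <- EBImage::dilate(EBImage::Image(cm * 1),
                         EBImage::makeBrush(7, "disc")) > 0.5
  expect_true(all(!nm | matrix(as.logical(dil), 64, 64)))
  # nucleus-free frame: empty nucleus mask
  empty <- suppressWarnings(
    build_nucleus_mask(matrix(0, 32, 32)))
  expect_false(any(empty))
})

test_that("signal quantification matches the elementwise oracle", {
  set.seed(41)
  stack <- array(rpois(20 * 20 * 5, 30), c(20, 20, 5))
  cell <- matrix(FALSE, 20, 20); cell[5:16, 5:16] <- TRUE
  nuc <- matrix(FALSE, 20, 20); nuc[9:12, 9:12] <- TRUE
  rec <- quantify_signal(stack, cell, nuc, background_margin_px = 2)
  # oracle: explicit loops
  proj <- matrix(0, 20, 20)
  for (s in 1:5) proj <- proj + stack[, , s]
  region <- cell & !nuc
  dil <- EBImage::dilate(EBImage::Image(cell * 1),
                         EBImage::makeBrush(5, "disc")) > 0.5
  bg <- mean(proj[!matrix(as.logical(dil), 20, 20)])
  expect_equal(rec$region_mean, mean(proj[region]))
  expect_equal(rec$background_mean, bg)
  expect_equal(rec$corrected, max(0, mean(proj[region]) - bg))
  expect_equal(rec$region_area_px, sum(region))
})

test_that("quantification handles degenerate inputs per contract", {
  cell <- matrix(FALSE, 10, 10); cell[3:8, 3:8] <- TRUE
  nuc <- matrix(FALSE, 10, 10)
  zero <- array(0, c(10, 10, 3))
  rec <- suppressWarnings(quantify_signal(zero, cell, nuc))
  expect_equal(rec$corrected, 0)
  expect_false(rec$passed_background_filter)  # mean == background == 0
  # uniform level L inside the region, zero outside: corrected = L
  lvl <- matrix(0, 20, 20); lvl[6:15, 6:15] <- 4
  cell2 <- matrix(FALSE, 20, 20); cell2[6:15, 6:15] <- TRUE
  rec2 <- quantify_signal(array(lvl, c(20, 20, 1)), cell2,
                          matrix(FALSE, 20, 20),
                          background_margin_px = 2)
  expect_equal(rec2$corrected, 4)
  # empty region errors with mask sizes in the message
  expect_error(quantify_signal(zero, nuc, cell), "empty")
})

test_that("background filter drops boundary cases and normalization is scale-free", {
  recs <- data.frame(corrected = c(2, 4, 8), region_mean = c(3, 5, 9),
                     background_mean = c(1, 1, 1),
                     passed_background_filter = c(TRUE, TRUE, TRUE))
  out <- normalize_global(recs)
  expect_equal(out$normalized, c(0.25, 0.5, 1))
  # single record normalizes to 1
  expect_equal(normalize_global(recs[1, , drop = FALSE])$normalized, 1)
  # boundary: mean equal to background is removed
  recs$passed_background_filter <- c(TRUE, FALSE, TRUE)
  kept <- suppressMessages(filter_above_background(recs))
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$corrected, c(2, 8))
  # scale invariance
  scaled <- recs; scaled$corrected <- recs$corrected * 17
  expect_equal(normalize_global(scaled)$normalized,
               normalize_global(recs)$normalized)
  expect_error(normalize_global(data.frame(corrected = c(0, 0))), "zero")
})

test_that("scaling the ligand channel scales corrected means linearly", {
  sc <- make_scene(field_from_pixels(32, 32), 8e3, keep_points = TRUE,
                   seed = 23)
  st <- simulate_selectivity_stack(sc, 7, seed = 24)
  cm <- build_cell_mask(z_project_sum(st$channels$antibody))
  nm <- build_nucleus_mask(z_project_sum(st$channels$nucleus))
  r1 <- quantify_signal(st$channels$ligand, cm, nm)
  r3 <- quantify_signal(st$channels$ligand * 3, cm, nm)
  expect_equal(r3$corrected, 3 * r1$corrected, tolerance = 1e-9)
  expect_equal(r3$passed_background_filter, r1$passed_background_filter)
})

test_that("condition statistics reproduce classical identities", {
  recs <- data.frame(
    cell_type = "huvec",
    state = rep(c("resting", "activated"), each = 6),
    spacing_nm = rep(c(7, 24), times = 6),
    normalized = c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3))
  st <- suppressWarnings(compare_conditions(recs))
  # identical groups: F ~ 0, p ~ 1
  expect_lt(st$anova$F[1], 1e-12)
  expect_gt(st$anova$p[1], 0.999)
  # two-group ANOVA equals the squared pooled t statistic
  recs2 <- data.frame(cell_type = "x", state = rep(c("a", "b"), each = 5),
                      spacing_nm = 7,
                      normalized = c(1, 2, 3, 4, 5, 2, 3, 4, 5, 7))
  st2 <- compare_conditions(recs2)
  tt <- t.test(normalized ~ state, data = recs2, var.equal = TRUE)
  expect_equal(st2$anova$F[1], unname(tt$statistic)^2, tolerance = 1e-9)
  # strongly separated groups: tiny p
  recs3 <- data.frame(cell_type = "x", state = "a",
                      spacing_nm = rep(c(7, 36), each = 9),
                      normalized = c(rnorm(9, 0, 0.1), rnorm(9, 1, 0.1)))
  st3 <- suppressWarnings(compare_conditions(recs3))
  expect_lt(st3$ttests$p[1], 1e-6)
  # Holm adjustment is monotone and >= raw p
  recs4 <- data.frame(cell_type = "x", state = "a",
                      spacing_nm = rep(c(7, 24, 36), each = 4),
                      normalized = c(rnorm(4), rnorm(4, 1), rnorm(4, 2)))
  st4 <- suppressWarnings(compare_conditions(recs4, adjust = "holm"))
  expect_true(all(st4$ttests$p_adj >= st4$ttests$p - 1e-12))
})

test_that("small groups are skipped with a warning, not an error", {
  recs <- data.frame(cell_type = "x", state = c("a", "a", "b"),
                     spacing_nm = 7, normalized = c(1, 2, 3))
  expect_warning(st <- compare_conditions(recs), "skipped")
  expect_equal(nrow(st$anova), 0L)
})

test_that("the end-to-end pipeline prefers the matching scaffold on dense cells", {
  f <- field_from_pixels(40, 40)
  sc <- make_scene(f, 1e4, keep_points = TRUE, seed = 29)
  stacks <- lapply(c(7, 24, 36),
                   function(sp) simulate_selectivity_stack(sc, sp,
                                                           seed = 30 + sp))
  out <- suppressMessages(run_selectivity_pipeline(stacks))
  rec <- out$records
  expect_equal(rec$corrected[rec$spacing_nm == 7],
               max(rec$corrected))
  norm7 <- out$passing$normalized[out$passing$spacing_nm == 7]
  expect_equal(norm7, 1)
})

test_that("stacks round-trip through multi-page TIFF with sidecar metadata", {
  sc <- make_scene(field_from_pixels(16, 16), 3e3, keep_points = TRUE,
                   seed = 61)
  st <- simulate_selectivity_stack(sc, 7, n_slices = 4, seed = 62)
  path <- tempfile(fileext = ".tif")
  write_stack_tiff(st, path)
  back <- read_stack_tiff(path)
  expect_equal(names(back$channels), c("antibody", "ligand", "nucleus"))
  expect_equal(back$slice_step_um, 0.2)
  expect_equal(back$pixel_scale, 3.115)
  expect_equal(back$channels$ligand, st$channels$ligand, tolerance = 1e-4)
})
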