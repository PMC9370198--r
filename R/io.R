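#' Write / read a single-channel intensity image as TIFF
#'
#' Intensities are linearly mapped to \[0, 1\] and stored as 32-bit
#' samples; the affine transform (`intensity_offset`, `intensity_range`)
#' and the pixel scale go to a JSON sidecar (`<path>.json`), from which
#' `read_image_tiff()` restores the raw intensity scale. The sidecar is
#' used because baseline TIFF tags carry neither a physical pixel size nor
#' an intensity calibration reliably across readers.
#'
#' @param image numeric matrix, optionally with a `pixel_scale` attribute.
#' @param path output `.tif` path.
#' @param pixel_scale pixels per micrometer; default taken from the image
#'   attribute.
#' @return `write_image_tiff()` returns `path` invisibly;
#'   `read_image_tiff()` returns the matrix (raw intensity scale when the
#'   sidecar is present) with a `pixel_scale` attribute.
#' @export
write_image_tiff <- function(image, path,
                             pixel_scale = attr(image, "pixel_scale")) {
  stopifnot(is.matrix(image))
  off <- min(image)
  rng <- max(image) - off
  m <- if (rng > 0) (image - off) / rng else image * 0
  attributes(m) <- list(dim = dim(m))
  tiff::writeTIFF(m, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_scale = if (is.null(pixel_scale)) NA else pixel_scale,
         intensity_offset = off, intensity_range = rng,
         units = "pixels per micrometer"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$intensity_range))
      m <- m * meta$intensity_range + meta$intensity_offset
    if (!is.null(meta$pixel_scale) && !is.na(meta$pixel_scale))
      attr(m, "pixel_scale") <- meta$pixel_scale
  }
  m
}

#' Write / read a mask as 8-bit TIFF (0/255)
#'
#' @param mask logical matrix ([new_mask()]).
#' @param path output `.tif` path.
#' @return `write_mask_tiff()` returns `path` invisibly; `read_mask_tiff()`
#'   returns a [new_mask()].
#' @export
write_mask_tiff <- function(mask, path) {
  m <- matrix(as.numeric(as.logical(mask)), nrow(mask), ncol(mask))
  tiff::writeTIFF(m, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  new_mask(m > 0.5, provenance = paste0("read_mask_tiff(", path, ")"))
}

#' Write / read a multi-channel Z-stack as multi-page TIFF
#'
#' Pages are ordered channel-major (all slices of channel 1, then channel
#' 2, ...), intensities linearly mapped to \[0, 1\] as 32-bit samples.
#' Channel names, slice count, slice step, pixel scale and the intensity
#' transform go to a JSON sidecar (`<path>.json`), which
#' `read_stack_tiff()` uses to reassemble the named channel arrays on the
#' raw intensity scale.
#'
#' @param stack a [simulate_selectivity_stack()] object, or a named list of
#'   3-D arrays plus explicit metadata.
#' @param path output `.tif` path.
#' @param slice_step_um,pixel_scale metadata when `stack` is a plain list.
#' @return `write_stack_tiff()` returns `path` invisibly;
#'   `read_stack_tiff()` returns a list with `channels`, `slice_step_um`,
#'   `pixel_scale`.
#' @export
write_stack_tiff <- function(stack, path, slice_step_um = NULL,
                             pixel_scale = NULL) {
  if (inherits(stack, "selectivity_stack")) {
    channels <- stack$channels
    slice_step_um <- stack$slice_step_um
    pixel_scale <- stack$pixel_scale
  } else {
    channels <- stack
  }
  stopifnot(is.list(channels), !is.null(names(channels)))
  off <- min(vapply(channels, min, numeric(1)))
  rng <- max(vapply(channels, max, numeric(1))) - off
  if (rng <= 0) rng <- 1
  pages <- list()
  for (ch in names(channels)) {
    arr <- channels[[ch]]
    if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
    for (s in seq_len(dim(arr)[3])) {
      m <- (arr[, , s] - off) / rng
      attributes(m) <- list(dim = dim(m))
      pages[[length(pages) + 1L]] <- m
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  n_slices <- vapply(channels, function(a)
    if (is.matrix(a)) 1L else dim(a)[3], integer(1))
  jsonlite::write_json(
    list(channels = names(channels), n_slices = unname(n_slices),
         slice_step_um = slice_step_um, pixel_scale = pixel_scale,
         intensity_offset = off, intensity_range = rng,
         page_order = "channel-major"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  channels <- list()
  off <- 0L
  for (k in seq_along(meta$channels)) {
    ns <- meta$n_slices[k]
    arr <- array(0, dim = c(dim(pages[[1]])[1:2], ns))
    for (s in seq_len(ns)) {
      m <- pages[[off + s]]
      if (length(dim(m)) == 3) m <- m[, , 1]
      if (!is.null(meta$intensity_range))
        m <- m * meta$intensity_range + meta$intensity_offset
      arr[, , s] <- m
    }
    channels[[meta$channels[k]]] <- arr
    off <- off + ns
  }
  list(channels = channels, slice_step_um = meta$slice_step_um,
       pixel_scale = meta$pixel_scale)
}

#' Write a spacing distribution as CSV
#'
#' Plain two-column table: `d_nm` and normalized `weight`, one row per
#' contributing pixel.
#'
#' @param dist a [spacing_distribution()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spacing_csv <- function(dist, path) {
  stopifnot(inherits(dist, "spacing_distribution"))
  write.csv(dist$samples, path, row.names = FALSE)
  invisible(path)
}
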