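#' Per-pixel feature stack for trainable segmentation
#'
#' Computes the compact feature set used by the pixel classifier: the raw
#' intensity, Gaussian smoothings at each scale, and the gradient magnitude
#' of each smoothed image (central differences, replicate boundary). With
#' `k` scales the stack holds `1 + 2k` features.
#'
#' @param image 2-D numeric matrix.
#' @param scales Gaussian scales in pixels (all > 0); default
#'   `c(1, 2, 4, 8)`. An empty scale list yields a raw-intensity-only stack
#'   with a warning.
#' @return Numeric array `nrow x ncol x n_features` with feature names on
#'   the third dimension; class `feature_stack`, attribute `scales`.
#' @export
compute_pixel_features <- function(image, scales = c(1, 2, 4, 8)) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (length(scales) == 0) {
    warning("empty scale list; returning raw-intensity-only feature stack")
    fs <- array(image, dim = c(nrow(image), ncol(image), 1L),
                dimnames = list(NULL, NULL, "raw"))
    return(structure(fs, scales = numeric(0), class = "feature_stack"))
  }
  stopifnot(all(scales > 0))
  feats <- list(raw = image)
  for (s in scales) {
    size <- 2L * as.integer(ceiling(3 * s)) + 1L
    # kernel cannot exceed the image extent
    size <- min(size, 2L * ((min(dim(image)) - 1L) %/% 2L) + 1L)
    k <- EBImage::makeBrush(size, shape = "gaussian", sigma = s)
    sm <- as.matrix(EBImage::filter2(EBImage::Image(image), k,
                                     boundary = "replicate"))
    feats[[paste0("gauss_", s)]] <- sm
    feats[[paste0("grad_", s)]] <- gradient_magnitude(sm)
  }
  fs <- array(unlist(feats, use.names = FALSE),
              dim = c(nrow(image), ncol(image), length(feats)),
              dimnames = list(NULL, NULL, names(feats)))
  structure(fs, scales = scales, class = "feature_stack")
}

# Central-difference gradient magnitude with replicate boundary.
gradient_magnitude <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  right <- m[, c(2:nc, nc), drop = FALSE]
  left <- m[, c(1, 1:(nc - 1)), drop = FALSE]
  down <- m[c(2:nr, nr), , drop = FALSE]
  up <- m[c(1, 1:(nr - 1)), , drop = FALSE]
  sqrt(((right - left) / 2)^2 + ((down - up) / 2)^2)
}

# flatten a feature stack into an n_pixels x n_features data.frame
.features_as_df <- function(fs) {
  d <- dim(fs)
  m <- matrix(fs, d[1] * d[2], d[3])
  colnames(m) <- dimnames(fs)[[3]]
  as.data.frame(m)
}

#' Train a cell/background pixel classifier
#'
#' Trainable pixel classification of cell versus background, in the spirit
#' of interactive machine-learning segmentation tools: a bagged
#' decision-tree ensemble (random forest) on the [compute_pixel_features()]
#' stack, with a logistic-regression fallback for tiny labeled sets
#' (< 200 labeled pixels, or `method = "logistic"`). At most
#' `max_pixels_per_image` labeled pixels per image are sampled for training,
#' balanced between the two classes.
#'
#' @param images list of 2-D matrices (or a single matrix).
#' @param label_masks list of logical matrices, `TRUE` = cell pixel; must
#'   contain both classes overall.
#' @param scales feature scales in pixels.
#' @param method `"auto"`, `"forest"`, or `"logistic"`.
#' @param max_pixels_per_image training pixels sampled per image.
#' @param ntree trees in the forest.
#' @param seed integer seed (sampling and forest growth).
#' @return An object of class `pixel_classifier`: `model`, `method`,
#'   `scales`, `classes`, `training_accuracy` (on its own labels), `trained`.
#' @export
train_classifier <- function(images, label_masks, scales = c(1, 2, 4, 8),
                             method = c("auto", "forest", "logistic"),
                             max_pixels_per_image = 4000L, ntree = 50L,
                             seed = 1L) {
  method <- match.arg(method)
  if (is.matrix(images)) images <- list(images)
  if (is.matrix(label_masks)) label_masks <- list(label_masks)
  stopifnot(length(images) >= 1, length(images) == length(label_masks))

  with_seed(seed, {
    xs <- list(); ys <- list()
    for (k in seq_along(images)) {
      stopifnot(all(dim(images[[k]]) == dim(label_masks[[k]])))
      fs <- .features_as_df(compute_pixel_features(images[[k]], scales))
      lab <- as.logical(label_masks[[k]])
      idx_cell <- which(lab); idx_bg <- which(!lab)
      n_half <- max_pixels_per_image %/% 2L
      take <- c(if (length(idx_cell)) sample(idx_cell,
                                             min(n_half, length(idx_cell))),
                if (length(idx_bg)) sample(idx_bg,
                                           min(n_half, length(idx_bg))))
      xs[[k]] <- fs[take, , drop = FALSE]
      ys[[k]] <- lab[take]
    }
    x <- do.call(rbind, xs)
    y <- unlist(ys)
    if (length(unique(y)) < 2)
      stop("training labels contain a single class; need both cell and ",
           "background pixels")
    if (method == "auto")
      method <- if (length(y) < 200) "logistic" else "forest"
    yf <- factor(ifelse(y, "cell", "background"),
                 levels = c("background", "cell"))
    if (method == "forest") {
      model <- randomForest::randomForest(x = x, y = yf, ntree = ntree)
      pred <- predict(model, x, type = "prob")[, "cell"] >= 0.5
    } else {
      dat <- cbind(x, .y = yf)
      model <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
      pred <- predict(model, x, type = "response") >= 0.5
    }
    structure(list(model = model, method = method, scales = scales,
                   classes = c("background", "cell"),
                   training_accuracy = mean(pred == y),
                   trained = TRUE),
              class = "pixel_classifier")
  })
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(
    "<pixel_classifier> %s, scales {%s}, training accuracy %.3f\n",
    x$method, paste(x$scales, collapse = ", "), x$training_accuracy))
  invisible(x)
}

#' Binary mask constructor
#'
#' @param m logical matrix.
#' @param pixel_scale pixels per micrometer (optional metadata).
#' @param provenance free-text description of how the mask was made.
#' @return Logical matrix of class `mask` with `pixel_scale` and
#'   `provenance` attributes.
#' @export
new_mask <- function(m, pixel_scale = NA_real_, provenance = "") {
  stopifnot(is.matrix(m))
  storage.mode(m) <- "logical"
  structure(m, pixel_scale = pixel_scale, provenance = provenance,
            class = c("mask", class(m)))
}

#' Predict a cell mask with a trained pixel classifier
#'
#' Recomputes the classifier's feature stack on `image` (the feature
#' configuration travels with the classifier) and thresholds the cell-class
#' score at 0.5. Deterministic for a fixed trained classifier.
#'
#' @param image 2-D numeric matrix.
#' @param classifier a [train_classifier()] model.
#' @return A [new_mask()] (`TRUE` = cell) with provenance recording the
#'   classifier.
#' @export
predict_mask <- function(image, classifier) {
  stopifnot(inherits(classifier, "pixel_classifier"),
            isTRUE(classifier$trained))
  fs <- .features_as_df(compute_pixel_features(image, classifier$scales))
  expected <- if (classifier$method == "forest")
    rownames(classifier$model$importance) else
      setdiff(names(classifier$model$coefficients), "(Intercept)")
  if (!identical(sort(colnames(fs)), sort(expected)))
    stop("feature configuration mismatch between image features {",
         paste(colnames(fs), collapse = ", "), "} and classifier {",
         paste(expected, collapse = ", "), "}")
  score <- if (classifier$method == "forest")
    predict(classifier$model, fs, type = "prob")[, "cell"]
  else
    predict(classifier$model, fs, type = "response")
  m <- matrix(score >= 0.5, nrow(image), ncol(image))
  new_mask(m, provenance = sprintf(
    "predict_mask(%s classifier, scales {%s}, accuracy %.3f)",
    classifier$method, paste(classifier$scales, collapse = ","),
    classifier$training_accuracy))
}

#' Threshold-and-morphology mask
#'
#' Hard-threshold segmentation with morphological cleanup, in this order:
#' pixels strictly above the threshold, morphological closing (disc brush),
#' hole filling, and removal of connected objects (8-connectivity) smaller
#' than `min_object_px`.
#'
#' @param image 2-D numeric matrix.
#' @param threshold intensity threshold; `NULL` (default) uses Otsu's
#'   method on the image. A threshold outside the intensity range yields an
#'   empty or full mask with a warning.
#' @param min_object_px remove objects with fewer pixels than this.
#' @param closing_radius_px disc radius for morphological closing (0 = off).
#' @param fill_holes fill enclosed background holes.
#' @return A [new_mask()] with provenance recording the parameters; the
#'   applied threshold is stored in attribute `threshold`.
#' @export
threshold_mask <- function(image, threshold = NULL, min_object_px = 0L,
                           closing_radius_px = 0L, fill_holes = FALSE) {
  stopifnot(is.matrix(image), is.numeric(image))
  rng <- range(image)
  if (is.null(threshold)) {
    if (rng[1] == rng[2]) {
      warning("constant image; Otsu threshold undefined, returning empty mask")
      threshold <- rng[2]
    } else {
      x01 <- (image - rng[1]) / (rng[2] - rng[1])
      threshold <- rng[1] +
        EBImage::otsu(EBImage::Image(x01)) * (rng[2] - rng[1])
    }
  } else if (threshold >= rng[2]) {
    warning("threshold ", signif(threshold, 4),
            " is at or above the image maximum; mask is empty")
  } else if (threshold < rng[1]) {
    warning("threshold ", signif(threshold, 4),
            " is below the image minimum; mask is full")
  }
  m <- image > threshold
  if (closing_radius_px > 0 && any(m)) {
    m <- EBImage::closing(EBImage::Image(m * 1),
                          .disc_brush(closing_radius_px)) > 0.5
    m <- matrix(as.logical(m), nrow(image), ncol(image))
  }
  if (fill_holes && any(m)) {
    m <- EBImage::fillHull(EBImage::Image(m * 1)) > 0.5
    m <- matrix(as.logical(m), nrow(image), ncol(image))
  }
  if (min_object_px > 0 && any(m)) {
    lab <- .label8(m)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_px)
    m <- matrix(lab %in% keep, nrow(image), ncol(image))
  }
  new_mask(m, provenance = sprintf(
    "threshold_mask(threshold = %.6g, min_object_px = %d, closing_radius_px = %d, fill_holes = %s)",
    threshold, as.integer(min_object_px), as.integer(closing_radius_px),
    fill_holes)) -> out
  attr(out, "threshold") <- threshold
  out
}

#' Label connected objects in a mask (8-connectivity)
#'
#' @param m logical matrix.
#' @return Integer matrix of object labels; 0 is background.
#' @export
label_objects <- function(m) {
  stopifnot(is.matrix(m))
  .label8(matrix(as.logical(m), nrow(m), ncol(m)))
}

#' Save / load a pixel classifier
#'
#' The random-forest (or logistic) model is serialized with the embedded
#' feature configuration so prediction recomputes identical features.
#'
#' @param classifier a [train_classifier()] model.
#' @param path file path (`.rds`).
#' @return `save_classifier()` returns `path` invisibly; `load_classifier()`
#'   returns the `pixel_classifier`.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "pixel_classifier"))
  x
}
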