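#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards. All stochastic generators in the package route their
#' randomness through this helper so that no call perturbs global random
#' state.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Weighted quantiles of a sample
#'
#' Left-continuous inverse of the weighted empirical CDF: the smallest `x`
#' whose cumulative normalized weight reaches `probs`.
#'
#' @param x numeric values.
#' @param w non-negative weights, same length as `x`.
#' @param probs probabilities in \[0, 1\].
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w, probs = 0.5) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0,
            all(probs >= 0 & probs <= 1))
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}

# Mean intensity outside a `margin_px` dilation of a mask; the package's
# common background estimator. Returns 0 (with a warning) when the dilated
# mask swallows the whole frame.
background_outside_mask <- function(image, mask_matrix, margin_px = 5L) {
  stopifnot(all(dim(image) == dim(mask_matrix)))
  if (margin_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(margin_px) + 1L, shape = "disc")
    dil <- EBImage::dilate(EBImage::Image(mask_matrix * 1), brush) > 0.5
    dil <- matrix(as.logical(dil), nrow(image), ncol(image))
  } else {
    dil <- mask_matrix
  }
  outside <- !dil
  if (!any(outside)) {
    warning("mask dilation covers the whole frame; background set to 0")
    return(0)
  }
  mean(image[outside])
}

# round a brush radius into an odd EBImage brush size
.disc_brush <- function(radius_px) {
  EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
}
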