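#' Fit a serial-dilution calibration curve
#'
#' Ordinary least-squares line through the antibody-amount versus
#' fluorescence table measured on calibration wells. The fit keeps an
#' intercept: poly-L-lysine-coated wells have a nonzero background
#' fluorescence which the intercept absorbs. A non-positive slope is
#' physically unusable and is flagged (`usable = FALSE`) with a warning.
#'
#' @param series a `data.frame` with columns `amount` and `intensity`
#'   (e.g. from [simulate_calibration_series()] or
#'   [read_calibration_series()]); at least two distinct amounts.
#' @param binding_ratio secondary antibodies per receptor (default 1,
#'   the 1:1 binding assumption).
#' @return An object of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `binding_ratio`, standard errors `se_slope` /
#'   `se_intercept`, the coefficient covariance `vcov`, `n`, `usable`.
#' @examples
#' fit_calibration(data.frame(amount = c(0, 10), intensity = c(5, 25)))
#' @export
fit_calibration <- function(series, binding_ratio = 1) {
  stopifnot(is.data.frame(series),
            all(c("amount", "intensity") %in% names(series)),
            binding_ratio > 0)
  if (any(series$amount < 0)) stop("antibody amounts must be >= 0")
  if (length(unique(series$amount)) < 2)
    stop("calibration needs >= 2 distinct antibody amounts (singular fit)")
  fit <- lm(intensity ~ amount, data = series)
  cf <- coef(fit)
  sm <- summary(fit)
  usable <- cf[["amount"]] > 0
  if (!usable)
    warning("calibration slope is not positive (", signif(cf[["amount"]], 4),
            "); curve flagged unusable")
  structure(list(slope = unname(cf["amount"]),
                 intercept = unname(cf["(Intercept)"]),
                 r_squared = sm$r.squared,
                 binding_ratio = binding_ratio,
                 se_slope = sm$coefficients["amount", "Std. Error"],
                 se_intercept = sm$coefficients["(Intercept)", "Std. Error"],
                 vcov = vcov(fit),
                 n = nrow(series),
                 usable = usable),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> intensity = %.6g * amount + %.6g (r^2 = %.4f, n = %d)%s\n",
    x$slope, x$intercept, x$r_squared, x$n,
    if (x$usable) "" else " [UNUSABLE: slope <= 0]"))
  invisible(x)
}

#' Convert measured fluorescence to a receptor count
#'
#' Inverts the calibration line under the 1:1 secondary-antibody-to-receptor
#' binding assumption:
#' `count = max(0, (intensity / gain_ratio - intercept) / slope) / binding_ratio`.
#' Intensities below the intercept back-calculate to a negative antibody
#' amount; these are clamped to zero with a warning (a physical count cannot
#' be negative). `gain_ratio` rescales image-derived intensities onto the
#' plate-reader scale of the calibration (imaging gain divided by
#' plate-reader gain); it defaults to 1, i.e. both instruments on a common
#' scale.
#'
#' @param total_intensity measured fluorescence (scalar or vector).
#' @param curve a [fit_calibration()] curve with positive slope.
#' @param gain_ratio imaging-to-plate-reader gain ratio (> 0).
#' @return Receptor count(s), real-valued and non-negative.
#' @examples
#' curve <- fit_calibration(data.frame(amount = c(0, 10), intensity = c(5, 25)))
#' receptors_from_intensity(2005, curve)
#' @export
receptors_from_intensity <- function(total_intensity, curve, gain_ratio = 1) {
  stopifnot(inherits(curve, "calibration_curve"), gain_ratio > 0)
  if (curve$slope <= 0)
    stop("calibration slope must be > 0 (got ", signif(curve$slope, 4), ")")
  antibodies <- (total_intensity / gain_ratio - curve$intercept) / curve$slope
  if (any(antibodies < 0))
    warning(sum(antibodies < 0), " intensity value(s) below the calibration ",
            "intercept; clamped to 0 receptors")
  pmax(0, antibodies) / curve$binding_ratio
}

#' Read a calibration series from CSV
#'
#' @param path CSV file with columns `amount` and `intensity`.
#' @return A `calibration_series` data.frame.
#' @export
read_calibration_series <- function(path) {
  df <- read.csv(path)
  if (!all(c("amount", "intensity") %in% names(df)))
    stop("calibration CSV must have columns 'amount' and 'intensity'")
  structure(df[c("amount", "intensity")],
            class = c("calibration_series", "data.frame"))
}

#' Write / read calibration curve parameters as JSON
#'
#' @param curve a [fit_calibration()] curve.
#' @param path output JSON path.
#' @return `write_calibration_curve()` returns `path` invisibly;
#'   `read_calibration_curve()` returns a `calibration_curve`.
#' @export
write_calibration_curve <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  x <- curve[c("slope", "intercept", "r_squared", "binding_ratio",
               "se_slope", "se_intercept", "n", "usable")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_curve
#' @export
read_calibration_curve <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$vcov <- NULL
  structure(x, class = "calibration_curve")
}
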