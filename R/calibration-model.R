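#' Fit the thoracic-to-lung regression calibration
#'
#' Ordinary least squares of manually delineated (gold-standard) lung volume
#' on frustum-derived thoracic volume. The fitted line converts a thoracic
#' volume into a "theoretical lung volume", the end product of the protocol.
#' Diagnostics include the coefficient of determination, the Pearson
#' product-moment correlation and its p-value, and the training range used
#' to flag extrapolation at prediction time.
#'
#' @param data A data frame of paired volumes, one row per scan.
#' @param thoracic,lung Columns holding thoracic and lung volume (mm^3);
#'   unquoted names, defaults `thoracic_mm3` and `manual_mm3`.
#' @return An object of class `lung_regression`.
#' @export
fit_lung_regression <- function(data, thoracic = thoracic_mm3,
                                lung = manual_mm3) {
  stopifnot(is.data.frame(data))
  x <- dplyr::pull(data, {{ thoracic }})
  y <- dplyr::pull(data, {{ lung }})
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 paired volumes", call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero variance in thoracic volumes", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  sm <- quiet_perfect(summary(fit))
  ct <- quiet_perfect(stats::cor.test(x, y, method = "pearson"))
  structure(
    list(fit = fit,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         pearson_r = unname(ct$estimate),
         p_value = ct$p.value,
         n = n,
         range = range(x)),
    class = "lung_regression")
}

#' @export
print.lung_regression <- function(x, ...) {
  cat(sprintf(
    "<lung_regression> lung = %.4f * thoracic + %.2f mm3  (n = %d)\n",
    x$slope, x$intercept, x$n))
  cat(sprintf("  R2 = %.4f, Pearson r = %.4f (p = %.3g), trained on [%.1f, %.1f] mm3\n",
              x$r_squared, x$pearson_r, x$p_value, x$range[1], x$range[2]))
  invisible(x)
}

#' Predict the theoretical lung volume
#'
#' `slope * thoracic + intercept`, vectorised. Thoracic volumes outside the
#' training range raise an extrapolation warning (pathologic thoraces can
#' legitimately exceed the healthy training range) rather than an error.
#'
#' @param model A `lung_regression`.
#' @param thoracic Thoracic volume(s), mm^3, all positive.
#' @return Theoretical lung volume(s), mm^3.
#' @export
predict_theoretical_lung <- function(model, thoracic) {
  stopifnot(inherits(model, "lung_regression"))
  if (any(!is.finite(thoracic)) || any(thoracic <= 0))
    stop("thoracic volume must be positive", call. = FALSE)
  if (any(thoracic < model$range[1] | thoracic > model$range[2]))
    warning("predicting outside the training thoracic-volume range (extrapolation)",
            call. = FALSE)
  model$slope * thoracic + model$intercept
}

#' @export
predict.lung_regression <- function(object, thoracic, ...) {
  predict_theoretical_lung(object, thoracic)
}

#' Absolute percent deviation from a gold-standard volume
#'
#' `100 * |theoretical - gold| / gold`; direction-free, as only deviation
#' magnitudes are of interest downstream (the 5 percent classification rule).
#'
#' @param theoretical,gold Volumes in mm^3, vectorised; `gold` must be
#'   positive.
#' @return Percent deviation(s).
#' @export
percent_deviation <- function(theoretical, gold) {
  if (any(!is.finite(gold)) || any(gold <= 0))
    stop("gold-standard volume must be positive", call. = FALSE)
  100 * abs(theoretical - gold) / gold
}

#' @exportS3Method generics::tidy
tidy.lung_regression <- function(x, ...) {
  sm <- quiet_perfect(summary(x$fit))$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = sm[, 1], std.error = sm[, 2],
                 statistic = sm[, 3], p.value = sm[, 4])
}

#' @exportS3Method generics::glance
glance.lung_regression <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, pearson_r = x$pearson_r,
                 p.value = x$p_value, n = x$n,
                 range_min = x$range[1], range_max = x$range[2])
}

#' @exportS3Method ggplot2::autoplot
autoplot.lung_regression <- function(object, ...) {
  df <- tibble::tibble(thoracic = object$fit$model$x,
                       lung = object$fit$model$y)
  ggplot2::ggplot(df, ggplot2::aes(.data$thoracic, .data$lung)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "thoracic (frustum) volume [mm3]",
      y = "manually delineated lung volume [mm3]",
      title = sprintf("lung = %.4f thoracic + %.1f   (R2 = %.3f, n = %d)",
                      object$slope, object$intercept, object$r_squared,
                      object$n)) +
    ggplot2::theme_minimal()
}

#' Regression-model JSON input/output
#' @param model A `lung_regression`.
#' @param path JSON file path.
#' @return [read_lung_regression()] returns a reduced `lung_regression`
#'   (coefficients and diagnostics; no refit object).
#' @export
write_lung_regression <- function(model, path) {
  stopifnot(inherits(model, "lung_regression"))
  jsonlite::write_json(
    list(slope = model$slope, intercept = model$intercept,
         r_squared = model$r_squared, pearson_r = model$pearson_r,
         p_value = model$p_value, n = model$n, range = model$range),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lung_regression
#' @export
read_lung_regression <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(fit = NULL, slope = j$slope, intercept = j$intercept,
         r_squared = j$r_squared, pearson_r = j$pearson_r,
         p_value = j$p_value, n = j$n, range = as.numeric(j$range)),
    class = "lung_regression")
}
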