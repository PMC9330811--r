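#' Fit a Hounsfield-unit calibration from air and water VOIs
#'
#' The two-point HU calibration of the scanning protocol: the mean raw grey
#' value inside the air VOI is mapped to -1000 HU, the mean inside the water
#' VOI to 0 HU, and every other grey value linearly in between:
#' `slope = 1000 / (mean_water - mean_air)`, `intercept = -slope * mean_water`.
#' VOI means are plain arithmetic means over all mask voxels.
#'
#' @param vol A raw-grey [ct_volume()] of the calibration tube scan.
#' @param air,water [voi_mask()]s placed strictly inside the air and water
#'   compartments.
#' @return An object of class `hu_calibration` with fields `slope`
#'   (HU per grey unit), `intercept` (HU), `air_mean`, `water_mean`.
#' @export
fit_hu_calibration <- function(vol, air, water) {
  stopifnot(inherits(vol, "ct_volume"), inherits(air, "voi_mask"),
            inherits(water, "voi_mask"))
  if (vol$units != "raw_grey")
    stop("calibration is fitted on raw grey values", call. = FALSE)
  check_same_grid(vol, air, "air VOI")
  check_same_grid(vol, water, "water VOI")
  if (sum(air$data) == 0L || sum(water$data) == 0L)
    stop("empty VOI", call. = FALSE)
  mean_air <- mean(vol$data[air$data == 1L])
  mean_water <- mean(vol$data[water$data == 1L])
  if (mean_water <= mean_air)
    stop("VOIs inverted or degenerate: mean(water) must exceed mean(air)",
         call. = FALSE)
  slope <- 1000 / (mean_water - mean_air)
  hu_calibration(slope, -slope * mean_water, mean_air, mean_water)
}

#' @rdname fit_hu_calibration
#' @param slope,intercept,air_mean,water_mean Calibration parameters.
#' @export
hu_calibration <- function(slope, intercept, air_mean = NA_real_,
                           water_mean = NA_real_) {
  if (!is.finite(slope) || slope <= 0)
    stop("slope must be positive", call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 air_mean = air_mean, water_mean = water_mean),
            class = "hu_calibration")
}

#' @export
print.hu_calibration <- function(x, ...) {
  cat(sprintf("<hu_calibration> HU = %.6g * grey + %.6g\n", x$slope,
              x$intercept))
  if (is.finite(x$air_mean))
    cat(sprintf("  anchors: air grey %.4g -> %.4g HU, water grey %.4g -> %.4g HU\n",
                x$air_mean, x$slope * x$air_mean + x$intercept,
                x$water_mean, x$slope * x$water_mean + x$intercept))
  invisible(x)
}

#' Apply a Hounsfield calibration voxel-wise
#'
#' `HU = slope * grey + intercept`. Spacing and shape are unchanged; the
#' output is tagged `"HU"`. Applying a calibration to an already-calibrated
#' volume is an error (double calibration).
#'
#' @param vol A raw-grey [ct_volume()].
#' @param cal A `hu_calibration`.
#' @return A [ct_volume()] in HU.
#' @export
apply_hu_calibration <- function(vol, cal) {
  stopifnot(inherits(vol, "ct_volume"), inherits(cal, "hu_calibration"))
  if (vol$units == "HU")
    stop("double calibration: volume is already in HU", call. = FALSE)
  ct_volume(cal$slope * vol$data + cal$intercept, vol$spacing, units = "HU",
            orientation = vol$orientation)
}

#' Calibration JSON input/output
#' @param cal A `hu_calibration`.
#' @param path JSON file path.
#' @return [read_hu_calibration()] returns a `hu_calibration`.
#' @export
write_hu_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "hu_calibration"))
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hu_calibration
#' @export
read_hu_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  hu_calibration(j$slope, j$intercept, j$air_mean %||% NA_real_,
                 j$water_mean %||% NA_real_)
}
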