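#' Protocol run configuration
#'
#' Bundles the tunables of the end-to-end protocol. Defaults mirror the
#' reference workflow: (-700, -300) HU window, landmark spans halved to
#' radii, 5 percent deviation threshold.
#'
#' @param window A [hu_window()].
#' @param halve_diameters Landmark spans are diameters (halved to radii).
#' @param deviation_threshold Classification threshold, percent (> 0).
#' @param min_component Minimum connected-component size for
#'   [threshold_segment()], voxels.
#' @param fit_on `"controls"` (fit the regression on non-pathologic scans
#'   only, then predict for all) or `"all"`.
#' @param seed Integer seed recorded in every report.
#' @param out_dir Optional output directory for [write_report()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(window = hu_window_reference(), halve_diameters = TRUE,
                       deviation_threshold = 5, min_component = 27L,
                       fit_on = c("controls", "all"), seed = 1L,
                       out_dir = NULL) {
  stopifnot(inherits(window, "hu_window"))
  if (deviation_threshold <= 0)
    stop("deviation threshold must be > 0", call. = FALSE)
  structure(list(window = window, halve_diameters = isTRUE(halve_diameters),
                 deviation_threshold = deviation_threshold,
                 min_component = as.integer(min_component),
                 fit_on = match.arg(fit_on), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the end-to-end volumetry protocol on a cohort
#'
#' For every scan: measure the three landmark distances, compute the frustum
#' thoracic volume, threshold-segment the aerated lung, and collect the
#' gold-standard manual lung volume. Then fit the thoracic-to-lung
#' regression, predict theoretical lung volumes, and run the validation
#' battery (ratios, Bland-Altman of theoretical vs manual, deviation
#' classification when pathologic scans are present). Re-running with the
#' same inputs and config is bit-identical.
#'
#' @param cohort A tibble with one row per scan: `scan_id`; `volume` (a
#'   list-column of [ct_volume()]s, or a character column of file paths);
#'   `landmarks` (list-column of [landmark_set()]s) or a `truth` list-column
#'   of `phantom_truth` objects from which landmarks and the manual volume
#'   are taken; `manual_mm3` (numeric, optional when `truth` is present);
#'   optional `pathologic` (logical, default `FALSE`). The output of
#'   [generate_cohort()] can be passed directly.
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `conelung_report`: `records` tibble, `model`
#'   (`lung_regression`), `ratios` summary, `bland_altman`,
#'   `classification` (or `NULL`), and the `config`.
#' @export
run_protocol <- function(cohort, config = run_config(), quiet = FALSE) {
  stopifnot(is.data.frame(cohort), inherits(config, "run_config"))
  if (!"scan_id" %in% names(cohort))
    stop("cohort needs a scan_id column", call. = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  n <- nrow(cohort)
  has_truth <- "truth" %in% names(cohort)
  pathologic <- if ("pathologic" %in% names(cohort)) cohort$pathologic
                else rep(FALSE, n)

  stage <- function(id, name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("scan %s failed at stage %s: %s", id, name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  records <- purrr::map(seq_len(n), function(i) {
    id <- cohort$scan_id[i]
    vol <- stage(id, "load", {
      v <- cohort$volume[[i]]
      if (is.character(v)) v <- read_volume(v)
      if (!inherits(v, "ct_volume")) stop("no volume available")
      v
    })
    lm <- stage(id, "landmarks", {
      if ("landmarks" %in% names(cohort)) cohort$landmarks[[i]]
      else if (has_truth) cohort$truth[[i]]$landmarks
      else stop("no landmarks available")
    })
    cone <- stage(id, "cone", thoracic_volume_from_image(
      vol, lm, halve_diameters = config$halve_diameters))
    thr <- stage(id, "threshold", mask_volume_mm3(threshold_segment(
      vol, config$window, min_size = config$min_component)))
    manual <- stage(id, "manual", {
      if ("manual_mm3" %in% names(cohort) && is.finite(cohort$manual_mm3[i]))
        cohort$manual_mm3[i]
      else if (has_truth) cohort$truth[[i]]$lung_mm3
      else stop("no manual gold-standard volume available")
    })
    say("scan %s: d_small %.2f, d_large %.2f, height %.2f mm; thoracic %.1f, threshold %.1f, manual %.1f mm3",
        id, cone$measure$d_small, cone$measure$d_large, cone$measure$height,
        cone$volume_mm3, thr, manual)
    tibble::tibble(
      scan_id = id, pathologic = pathologic[i],
      d_small_mm = cone$measure$d_small, d_large_mm = cone$measure$d_large,
      height_mm = cone$measure$height,
      thoracic_mm3 = cone$volume_mm3, threshold_mm3 = thr,
      manual_mm3 = manual)
  })
  records <- dplyr::bind_rows(records)

  say("fitting thoracic-to-lung regression (%s)", config$fit_on)
  train <- if (config$fit_on == "controls" && any(!records$pathologic))
    records[!records$pathologic, ] else records
  if (nrow(train) < 3)
    stop("scan cohort failed at stage fit: need >= 3 paired volumes",
         call. = FALSE)
  model <- fit_lung_regression(train)
  records$theoretical_mm3 <- withCallingHandlers(
    predict_theoretical_lung(model, records$thoracic_mm3),
    warning = function(w) {
      say("note: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  records$deviation_pct <- percent_deviation(records$theoretical_mm3,
                                             records$manual_mm3)
  ratios <- summarise_ratios(records)
  ba <- bland_altman(records$theoretical_mm3, records$manual_mm3)
  classification <- NULL
  if (any(records$pathologic) && any(!records$pathologic)) {
    classification <- classify_cohort(
      tibble::tibble(scan_id = records$scan_id,
                     pathologic = records$pathologic,
                     volume_mm3 = records$theoretical_mm3),
      reference = "auto", threshold = config$deviation_threshold)
  }
  report <- structure(
    list(records = records, model = model, ratios = ratios,
         bland_altman = ba, classification = classification,
         config = config),
    class = "conelung_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.conelung_report <- function(x, ...) {
  cat(sprintf("<conelung_report> %d scans (%d pathologic)\n",
              nrow(x$records), sum(x$records$pathologic)))
  print(x$model)
  print(x$bland_altman)
  if (!is.null(x$classification)) print(x$classification)
  invisible(x)
}

#' Write a protocol report bundle
#'
#' `report.json` (summary), `records.csv` (per-scan table) and
#' `ratios.csv`. Files contain no timestamps, so re-running the same seeded
#' protocol produces byte-identical output.
#'
#' @param report A `conelung_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "conelung_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(report$ratios, file.path(dir, "ratios.csv"),
                   row.names = FALSE)
  summary <- list(
    n_scans = nrow(report$records),
    seed = report$config$seed,
    window = unclass(report$config$window),
    halve_diameters = report$config$halve_diameters,
    deviation_threshold_pct = report$config$deviation_threshold,
    model = list(slope = report$model$slope,
                 intercept = report$model$intercept,
                 r_squared = report$model$r_squared,
                 n = report$model$n, range = report$model$range),
    bland_altman = glance(report$bland_altman),
    ratios = report$ratios)
  if (!is.null(report$classification))
    summary$classification <- glance(report$classification)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
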