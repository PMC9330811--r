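#' Per-scan volume ratios
#'
#' The size-compensation ratios of the protocol: manually delineated over
#' thoracic volume, thresholded over manually delineated, and thresholded
#' over thoracic, each as a percentage. A thresholded volume exceeding the
#' manual one is physically impossible (aerated lung cannot exceed total
#' lung) and is flagged as anomalous rather than rejected.
#'
#' @param data Data frame with columns `thoracic_mm3`, `manual_mm3`,
#'   `threshold_mm3` (all positive).
#' @return `data` with added columns `manual_over_thoracic_pct`,
#'   `threshold_over_manual_pct`, `threshold_over_thoracic_pct`, `anomalous`.
#' @export
volume_ratios <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("thoracic_mm3", "manual_mm3", "threshold_mm3")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop(sprintf("missing volume column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  vals <- as.matrix(data[need])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("missing volume: all three volumes must be present and positive",
         call. = FALSE)
  dplyr::mutate(
    tibble::as_tibble(data),
    manual_over_thoracic_pct = 100 * .data$manual_mm3 / .data$thoracic_mm3,
    threshold_over_manual_pct = 100 * .data$threshold_mm3 / .data$manual_mm3,
    threshold_over_thoracic_pct = 100 * .data$threshold_mm3 / .data$thoracic_mm3,
    anomalous = .data$threshold_mm3 > .data$manual_mm3)
}

#' Cohort ratio summary
#'
#' Reports both reading conventions of a cohort-level ratio: the mean of the
#' per-scan ratios and the ratio of the cohort means.
#'
#' @param data As for [volume_ratios()].
#' @return A tibble with one row per ratio and columns
#'   `mean_of_ratios_pct`, `ratio_of_means_pct`.
#' @export
summarise_ratios <- function(data) {
  r <- volume_ratios(data)
  tibble::tibble(
    ratio = c("manual/thoracic", "threshold/manual", "threshold/thoracic"),
    mean_of_ratios_pct = c(mean(r$manual_over_thoracic_pct),
                           mean(r$threshold_over_manual_pct),
                           mean(r$threshold_over_thoracic_pct)),
    ratio_of_means_pct = c(100 * mean(r$manual_mm3) / mean(r$thoracic_mm3),
                           100 * mean(r$threshold_mm3) / mean(r$manual_mm3),
                           100 * mean(r$threshold_mm3) / mean(r$thoracic_mm3)))
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`, bias `mean(d)` and 95 percent limits of agreement
#' `bias +/- 1.96 * sd(d)` (sample SD, n - 1 denominator; fixed normal
#' quantile, no small-sample t correction). Per-pair `(mean, difference)`
#' points are kept for plotting.
#'
#' @param a,b Paired measurement series (mm^3), equal length >= 2.
#' @return An object of class `bland_altman`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ", call. = FALSE)
  if (length(a) < 2) stop("need >= 2 pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(bias = bias, sd = s,
         loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
         n = length(d),
         points = tibble::tibble(mean = (a + b) / 2, difference = d)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> bias %.3f, sd %.3f, 95%% limits [%.3f, %.3f] (n = %d)\n",
    x$bias, x$sd, x$loa_lower, x$loa_upper, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bland_altman <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd = x$sd, loa_lower = x$loa_lower,
                 loa_upper = x$loa_upper, n = x$n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$mean, .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of the two methods [mm3]",
                  y = "difference between methods [mm3]",
                  title = sprintf("bias %.2f, 95%% limits [%.2f, %.2f]",
                                  object$bias, object$loa_lower,
                                  object$loa_upper)) +
    ggplot2::theme_minimal()
}

#' Gage R&R variance-component analysis
#'
#' Two-way crossed ANOVA (part x operator with interaction) decomposed into
#' variance components by the expected-mean-squares method: repeatability
#' (replicate error), operator, operator x part interaction, and
#' part-to-part variation. Negative component estimates are truncated to
#' zero. When the interaction mean square falls below the error mean square
#' the interaction is pooled into error (the additive model is refitted), a
#' standard measurement-systems-analysis convention. The design must be
#' balanced and crossed: every operator measures every part the same number
#' of times, with at least 2 parts, 2 operators and 2 replicates.
#'
#' @param data Data frame with columns `part`, `operator`, `value` (a
#'   `replicate` column is permitted but not required).
#' @return An object of class `gage_rr` with a `components` tibble
#'   (variance and percent contribution per component), the design sizes,
#'   and `operator_pct` = percent contribution of operator plus interaction
#'   (reproducibility share of total variation).
#' @export
gage_rr <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("part", "operator", "value")
  if (!all(need %in% names(data)))
    stop("need columns part, operator, value", call. = FALSE)
  part <- factor(data$part)
  oper <- factor(data$operator)
  p <- nlevels(part); o <- nlevels(oper)
  if (o < 2) stop("need >= 2 operators", call. = FALSE)
  if (p < 2) stop("need >= 2 parts", call. = FALSE)
  counts <- table(part, oper)
  r <- counts[1, 1]
  if (any(counts != r))
    stop("unbalanced design: every operator must measure every part equally often",
         call. = FALSE)
  if (r < 2) stop("need >= 2 replicates", call. = FALSE)
  y <- data$value

  fit <- stats::aov(y ~ part * oper)
  ms <- summary(fit)[[1]][, "Mean Sq"]
  names(ms) <- trimws(rownames(summary(fit)[[1]]))
  ms_p <- ms[["part"]]; ms_o <- ms[["oper"]]
  ms_po <- ms[["part:oper"]]; ms_e <- ms[["Residuals"]]

  if (ms_po < ms_e) {
    # pool interaction into error: additive two-way model
    fit2 <- stats::aov(y ~ part + oper)
    ms2 <- summary(fit2)[[1]][, "Mean Sq"]
    names(ms2) <- trimws(rownames(summary(fit2)[[1]]))
    ms_e2 <- ms2[["Residuals"]]
    var_rep <- ms_e2
    var_int <- 0
    var_op <- max(0, (ms2[["oper"]] - ms_e2) / (p * r))
    var_part <- max(0, (ms2[["part"]] - ms_e2) / (o * r))
  } else {
    var_rep <- ms_e
    var_int <- max(0, (ms_po - ms_e) / r)
    var_op <- max(0, (ms_o - ms_po) / (p * r))
    var_part <- max(0, (ms_p - ms_po) / (o * r))
  }
  comps <- c(part = var_part, operator = var_op, interaction = var_int,
             repeatability = var_rep)
  total <- sum(comps)
  pct <- if (total > 0) 100 * comps / total else rep(NA_real_, 4)
  structure(
    list(components = tibble::tibble(component = names(comps),
                                     variance = unname(comps),
                                     pct_contribution = unname(pct)),
         n_parts = p, n_operators = o, n_replicates = as.integer(r),
         operator_pct = unname(pct["operator"] + pct["interaction"]),
         total_variance = total),
    class = "gage_rr")
}

#' @export
print.gage_rr <- function(x, ...) {
  cat(sprintf("<gage_rr> %d parts x %d operators x %d replicates\n",
              x$n_parts, x$n_operators, x$n_replicates))
  print(x$components)
  cat(sprintf("  operator contribution (operator + interaction): %.2f%%\n",
              x$operator_pct))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gage_rr <- function(x, ...) x$components

#' @exportS3Method generics::glance
glance.gage_rr <- function(x, ...) {
  tibble::tibble(operator_pct = x$operator_pct,
                 repeatability_pct =
                   x$components$pct_contribution[x$components$component ==
                                                   "repeatability"],
                 part_pct = x$components$pct_contribution[
                   x$components$component == "part"],
                 total_variance = x$total_variance,
                 n_parts = x$n_parts, n_operators = x$n_operators,
                 n_replicates = x$n_replicates)
}

#' Deviation-rule sensitivity/specificity classification
#'
#' Each scan's lung volume is compared to a reference population volume (by
#' default the mean over the non-pathologic control scans). A percent
#' deviation strictly over the threshold (default 5 percent) calls the scan
#' positive: pathologic scans become true positives (else false negatives),
#' control scans false positives (else true negatives). A deviation exactly
#' at the threshold is negative ("over 5 percent" is strict).
#'
#' @param data Data frame with columns `scan_id`, `pathologic` (logical) and
#'   `volume_mm3`.
#' @param reference Population reference volume in mm^3, or `"auto"` to use
#'   the mean of the control scans.
#' @param threshold Deviation threshold, percent (> 0); default 5.
#' @return An object of class `deviation_classification`: per-scan tibble
#'   plus aggregate `sensitivity_pct`, `specificity_pct`, counts, and the
#'   reference used.
#' @export
classify_cohort <- function(data, reference = "auto", threshold = 5) {
  stopifnot(is.data.frame(data))
  need <- c("scan_id", "pathologic", "volume_mm3")
  if (!all(need %in% names(data)))
    stop("need columns scan_id, pathologic, volume_mm3", call. = FALSE)
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (identical(reference, "auto")) {
    ctrl <- data$volume_mm3[!data$pathologic]
    if (length(ctrl) == 0)
      stop("no control scans to form the reference population mean",
           call. = FALSE)
    reference <- mean(ctrl)
  }
  if (!is.numeric(reference) || reference <= 0)
    stop("reference must be a positive volume or \"auto\"", call. = FALSE)
  scans <- dplyr::mutate(
    tibble::as_tibble(data[need]),
    deviation_pct = percent_deviation(.data$volume_mm3, reference),
    positive = .data$deviation_pct > threshold,
    class = dplyr::case_when(
      .data$pathologic & .data$positive ~ "TP",
      .data$pathologic & !.data$positive ~ "FN",
      !.data$pathologic & .data$positive ~ "FP",
      TRUE ~ "TN"))
  counts <- table(factor(scans$class, levels = c("TP", "FN", "FP", "TN")))
  sens <- 100 * counts[["TP"]] / (counts[["TP"]] + counts[["FN"]])
  spec <- 100 * counts[["TN"]] / (counts[["TN"]] + counts[["FP"]])
  structure(
    list(scans = scans, counts = as.list(counts),
         sensitivity_pct = sens, specificity_pct = spec,
         reference_mm3 = reference, threshold_pct = threshold),
    class = "deviation_classification")
}

#' @export
print.deviation_classification <- function(x, ...) {
  cat(sprintf(
    "<deviation_classification> reference %.2f mm3, threshold %g%%\n",
    x$reference_mm3, x$threshold_pct))
  cat(sprintf("  TP %d  FN %d  FP %d  TN %d -> sensitivity %.2f%%, specificity %.2f%%\n",
              x$counts$TP, x$counts$FN, x$counts$FP, x$counts$TN,
              x$sensitivity_pct, x$specificity_pct))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.deviation_classification <- function(x, ...) x$scans

#' @exportS3Method generics::glance
glance.deviation_classification <- function(x, ...) {
  tibble::tibble(sensitivity_pct = x$sensitivity_pct,
                 specificity_pct = x$specificity_pct,
                 tp = x$counts$TP, fn = x$counts$FN, fp = x$counts$FP,
                 tn = x$counts$TN, reference_mm3 = x$reference_mm3,
                 threshold_pct = x$threshold_pct)
}
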