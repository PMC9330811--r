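#' CT volume container
#'
#' A 3-D scalar grid with isotropic-or-not voxel spacing in millimetres and a
#' units tag. Raw scanner volumes carry non-negative integer grey values
#' (`units = "raw_grey"`); Hounsfield-calibrated volumes (`units = "HU"`) are
#' real-valued and may be negative (air = -1000 HU, water = 0 HU).
#'
#' Axis convention: axis 1 runs cranio-caudal (axial slice index), axis 2
#' dorso-ventral (coronal), axis 3 left-right (sagittal). The physical
#' coordinate of a voxel centre is `(index - 1) * spacing`, in mm.
#'
#' @param data 3-D numeric array, each dimension at least 2 voxels.
#' @param spacing Voxel size in mm; a single number (isotropic) or one value
#'   per axis. All components must be positive.
#' @param units `"raw_grey"` or `"HU"`.
#' @param orientation Character vector of length 3 labelling the axes.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, units = c("raw_grey", "HU"),
                      orientation = c("axial", "coronal", "sagittal")) {
  units <- match.arg(units)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume must be 3-D", call. = FALSE)
  if (any(dim(data) < 2L))
    stop("each axis must span at least 2 voxels", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)", call. = FALSE)
  if (units == "raw_grey") {
    rng <- range(data)
    if (rng[1] < 0)
      stop("raw_grey volumes must be non-negative; negative values imply HU",
           call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, units = units,
         orientation = as.character(orientation)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm [%s]\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "), x$units))
  cat(sprintf("  extent %s mm, grey range [%.4g, %.4g]\n",
              paste(signif(d * x$spacing, 4), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' Binary volume-of-interest mask
#'
#' A VOI on the grid of a [ct_volume()]: same shape, same spacing, values in
#' \{0, 1\} (stored as integer).
#'
#' @param data 3-D array of 0/1 (or logical) values.
#' @param spacing Voxel size in mm, as for [ct_volume()].
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask must be 3-D", call. = FALSE)
  if (is.logical(data)) {
    storage.mode(data) <- "integer"
  } else {
    u <- unique(as.vector(data))
    if (!all(u %in% c(0, 1)))
      stop("mask values must be 0 or 1", call. = FALSE)
    storage.mode(data) <- "integer"
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing), class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voi_mask> %d x %d x %d voxels, %d set (%.4g mm3)\n",
              d[1], d[2], d[3], sum(x$data), mask_volume_mm3(x)))
  invisible(x)
}

#' @export
dim.voi_mask <- function(x) dim(x$data)

#' Voxel volume in cubic millimetres
#' @param x A `ct_volume` or `voi_mask`.
#' @return Volume of one voxel, mm^3.
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing)

#' Mask volume in cubic millimetres
#'
#' Count of set voxels times the voxel volume. This is the volumetry primitive
#' every segmentation-derived volume in the protocol reduces to.
#'
#' @param mask A [voi_mask()].
#' @return Volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  sum(mask$data) * prod(mask$spacing)
}

check_same_grid <- function(vol, mask, what = "mask") {
  if (!all(dim(vol$data) == dim(mask$data)))
    stop(sprintf("%s shape does not match volume grid", what), call. = FALSE)
  if (max(abs(vol$spacing - mask$spacing)) > 1e-9)
    stop(sprintf("%s spacing does not match volume spacing", what),
         call. = FALSE)
  invisible(TRUE)
}
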