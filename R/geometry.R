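#' Landmark set for the truncated-cone thoracic measurement
#'
#' Three point-pairs in physical (mm) coordinates, each a 2 x 3 matrix with
#' one endpoint per row and columns ordered (axial, coronal, sagittal):
#' the carina-level small base (lung limit to contralateral lung limit, read
#' in coronal view), the diaphragm-level large base (ventral aspect of the
#' vertebrae to the abdominal wall, read in sagittal view), and the
#' carina-to-diaphragm height line.
#'
#' @param small_base,large_base,height 2 x 3 numeric matrices, mm.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(small_base, large_base, height) {
  pairs <- list(small_base = small_base, large_base = large_base,
                height = height)
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    if (!is.matrix(p) || !all(dim(p) == c(2L, 3L)) || any(!is.finite(p)))
      stop(sprintf("%s must be a finite 2 x 3 matrix (mm)", nm), call. = FALSE)
    if (sqrt(sum((p[1, ] - p[2, ])^2)) < 1e-12)
      stop(sprintf("%s endpoints are coincident", nm), call. = FALSE)
  }
  structure(pairs, class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  m <- measure_thorax(x)
  cat(sprintf(
    "<landmark_set> d_small %.3f mm, d_large %.3f mm, height %.3f mm\n",
    m$d_small, m$d_large, m$height))
  invisible(x)
}

#' Landmark JSON input/output
#'
#' Landmarks are stored as `{"small_base": [[z,y,x],[z,y,x]], "large_base":
#' ..., "height": ...}` with coordinates in mm.
#'
#' @param path JSON file path.
#' @return [read_landmarks()] returns a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_pair <- function(x) {
    rbind(as.numeric(unlist(x[[1]])), as.numeric(unlist(x[[2]])))
  }
  landmark_set(as_pair(j$small_base), as_pair(j$large_base),
               as_pair(j$height))
}

#' @rdname read_landmarks
#' @param landmarks A [landmark_set()].
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  j <- lapply(unclass(landmarks), function(p) list(p[1, ], p[2, ]))
  jsonlite::write_json(j, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Thoracic landmark distances
#'
#' Reduces a [landmark_set()] to the three Euclidean distances that
#' parameterise the truncated-cone model: small base diameter at the carina,
#' large base diameter at the diaphragmatic cupola, and the height between
#' the two planes. All in mm.
#'
#' @param landmarks A [landmark_set()].
#' @return An object of class `thorax_measure` with fields `d_small`,
#'   `d_large`, `height`.
#' @export
measure_thorax <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  d <- function(p) sqrt(sum((p[1, ] - p[2, ])^2))
  out <- list(d_small = d(landmarks$small_base),
              d_large = d(landmarks$large_base),
              height = d(landmarks$height))
  if (any(unlist(out) <= 0))
    stop("landmark endpoints are coincident", call. = FALSE)
  structure(out, class = "thorax_measure")
}

#' @export
print.thorax_measure <- function(x, ...) {
  cat(sprintf(
    "<thorax_measure> d_small %.3f, d_large %.3f, height %.3f mm -> %.2f mm3\n",
    x$d_small, x$d_large, x$height, truncated_cone_volume(x)))
  invisible(x)
}

#' Conical-frustum (truncated cone) thoracic volume
#'
#' V = (pi * h / 3) * (R1^2 + R2^2 + R1 * R2), with R1 and R2 the carina- and
#' diaphragm-level base radii. The measured landmark spans run across the
#' whole thorax, so by default they are halved to radii
#' (`halve_diameters = TRUE`); the flag is exposed for sensitivity analysis
#' of that convention.
#'
#' @param m A `thorax_measure`, or a data frame with columns `d_small`,
#'   `d_large`, `height` (mm).
#' @param halve_diameters Treat the measured distances as diameters (default)
#'   rather than radii.
#' @return Volume(s) in mm^3 (numeric vector for data-frame input).
#' @export
truncated_cone_volume <- function(m, halve_diameters = TRUE) {
  if (inherits(m, "thorax_measure")) {
    d_small <- m$d_small; d_large <- m$d_large; height <- m$height
  } else if (is.data.frame(m)) {
    d_small <- m$d_small; d_large <- m$d_large; height <- m$height
    if (is.null(d_small) || is.null(d_large) || is.null(height))
      stop("need columns d_small, d_large, height", call. = FALSE)
  } else {
    stop("m must be a thorax_measure or data frame", call. = FALSE)
  }
  if (any(c(d_small, d_large, height) <= 0))
    stop("measurements must be positive", call. = FALSE)
  half <- if (halve_diameters) 2 else 1
  r1 <- d_small / half
  r2 <- d_large / half
  pi * height / 3 * (r1^2 + r2^2 + r1 * r2)
}

#' Thoracic volume of an image from its landmark set
#'
#' Composition of [measure_thorax()] and [truncated_cone_volume()] with a
#' bounds check of the landmarks against the image extent. The volume is
#' expected to be reoriented to the standard anatomical frame first (see
#' [reorient()]).
#'
#' @param vol A [ct_volume()].
#' @param landmarks A [landmark_set()] in mm coordinates on the grid of `vol`.
#' @param halve_diameters See [truncated_cone_volume()].
#' @return A list with elements `measure` (`thorax_measure`) and
#'   `volume_mm3`.
#' @export
thoracic_volume_from_image <- function(vol, landmarks, halve_diameters = TRUE) {
  stopifnot(inherits(vol, "ct_volume"), inherits(landmarks, "landmark_set"))
  extent <- (dim(vol$data) - 1) * vol$spacing
  pts <- do.call(rbind, unclass(landmarks)[c("small_base", "large_base",
                                             "height")])
  inside <- pts >= -1e-9 & sweep(pts, 2, extent + 1e-9) <= 0
  if (!all(inside))
    stop("landmarks outside volume extent", call. = FALSE)
  m <- measure_thorax(landmarks)
  list(measure = m,
       volume_mm3 = truncated_cone_volume(m, halve_diameters))
}
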