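#' Hounsfield-unit window
#'
#' Inclusive radiodensity window used for aerated-lung threshold
#' segmentation. Two presets are shipped: the reference window
#' `hu_window(-700, -300)` and the alternate `hu_window(-700, -400)`; the
#' reference brackets the aerated-parenchyma air/tissue mixture around its
#' modal density of about -500 HU while excluding pure air (-1000 HU) and
#' soft tissue (around 0 HU and above).
#'
#' @param low,high Window bounds in HU, `low < high`; both endpoints
#'   inclusive.
#' @return An object of class `hu_window`.
#' @export
hu_window <- function(low = -700, high = -300) {
  if (!is.finite(low) || !is.finite(high) || low >= high)
    stop("window requires low < high", call. = FALSE)
  structure(list(low = low, high = high), class = "hu_window")
}

#' @rdname hu_window
#' @export
hu_window_reference <- function() hu_window(-700, -300)

#' @rdname hu_window
#' @export
hu_window_alternate <- function() hu_window(-700, -400)

#' Threshold segmentation of aerated lung
#'
#' Selects voxels whose HU value lies inside the window (endpoints
#' inclusive), optionally intersects with a thoracic restriction mask, then
#' drops connected components that touch the volume border (exterior air)
#' and components smaller than `min_size` voxels (noise specks). Connectivity
#' is 3-D.
#'
#' @param vol A [ct_volume()] in HU.
#' @param window A [hu_window()]; default is the reference window
#'   (-700, -300).
#' @param thorax_restrict Optional [voi_mask()] restricting the search.
#' @param min_size Minimum component size in voxels (default 27).
#' @return A [voi_mask()] of aerated lung.
#' @export
threshold_segment <- function(vol, window = hu_window_reference(),
                              thorax_restrict = NULL, min_size = 27L) {
  stopifnot(inherits(vol, "ct_volume"), inherits(window, "hu_window"))
  if (vol$units != "HU")
    stop("threshold segmentation requires an HU-calibrated volume",
         call. = FALSE)
  inwin <- vol$data >= window$low & vol$data <= window$high
  if (!is.null(thorax_restrict)) {
    check_same_grid(vol, thorax_restrict, "thorax_restrict")
    inwin <- inwin & (thorax_restrict$data == 1L)
  }
  if (!any(inwin))
    stop("no voxels in window - check calibration", call. = FALSE)
  lab <- label_components_3d(inwin)
  border <- unique(c(lab[1, , ], lab[dim(lab)[1], , ],
                     lab[, 1, ], lab[, dim(lab)[2], ],
                     lab[, , 1], lab[, , dim(lab)[3]]))
  border <- setdiff(border, 0L)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_size)
  keep <- setdiff(keep, border)
  if (length(keep) == 0L)
    stop("no interior components remain after border and size filtering",
         call. = FALSE)
  mask <- array(as.integer(lab %in% keep), dim(vol$data))
  voi_mask(mask, vol$spacing)
}

# 3-D connected-component labelling: in-plane labels from EBImage::bwlabel
# per axial slice, merged across adjacent slices with union-find (bwlabel
# itself labels 2-D frames independently).
label_components_3d <- function(mask3d) {
  dims <- dim(mask3d)
  labs <- array(0L, dims)
  offset <- 0L
  for (iz in seq_len(dims[1])) {
    sl <- mask3d[iz, , ]
    if (!any(sl)) next
    l <- EBImage::bwlabel(matrix(as.numeric(sl), dims[2], dims[3]))
    l <- as.integer(l)
    nl <- max(l)
    l[l > 0L] <- l[l > 0L] + offset
    dim(l) <- c(dims[2], dims[3])
    labs[iz, , ] <- l
    offset <- offset + nl
  }
  if (offset == 0L) return(labs)
  parent <- seq_len(offset)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (iz in seq_len(dims[1] - 1L)) {
    a <- labs[iz, , ]; b <- labs[iz + 1L, , ]
    both <- a > 0L & b > 0L
    if (!any(both)) next
    pairs <- unique(cbind(a[both], b[both]))
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  relab <- match(roots, unique(roots))
  pos <- labs > 0L
  labs[pos] <- relab[labs[pos]]
  labs
}

#' Slice-wise contour annotations
#'
#' The emulated manual-delineation input: closed polygons drawn on a subset
#' of axial slices, in in-plane mm coordinates `(coronal, sagittal)` with the
#' convention that voxel centre j has coordinate `(j - 1) * spacing`.
#' Slice indices are 1-based axial indices and must be strictly increasing.
#'
#' @param contours Named list: names are axial slice indices, each element a
#'   polygon (n x 2 matrix, columns y then x, mm) or a list of polygons.
#' @return An object of class `slice_contours`.
#' @export
slice_contours <- function(contours) {
  idx <- as.integer(names(contours))
  if (length(idx) < 2L)
    stop("need at least 2 annotated slices", call. = FALSE)
  if (any(is.na(idx)) || any(diff(idx) <= 0L))
    stop("slice indices must be strictly increasing integers", call. = FALSE)
  norm <- lapply(contours, function(cs) {
    if (is.matrix(cs)) cs <- list(cs)
    lapply(cs, function(p) {
      p <- as.matrix(p)
      if (ncol(p) != 2L || nrow(p) < 3L)
        stop("each polygon needs >= 3 vertices with 2 coordinates",
             call. = FALSE)
      if (polygon_self_intersects(p))
        stop("polygon is self-intersecting", call. = FALSE)
      p
    })
  })
  names(norm) <- idx
  structure(list(slices = norm, index = idx), class = "slice_contours")
}

# Segment-pair crossing test over non-adjacent edges (simple-polygon check).
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  if (n < 4L) return(FALSE)
  a <- p; b <- p[c(2:n, 1), ]
  cross <- function(o, u, v) {
    (u[, 1] - o[, 1]) * (v[, 2] - o[, 2]) - (u[, 2] - o[, 2]) * (v[, 1] - o[, 1])
  }
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]
    if (length(js) == 0L) next
    oi <- a[rep(i, length(js)), , drop = FALSE]
    ui <- b[rep(i, length(js)), , drop = FALSE]
    d1 <- cross(oi, ui, a[js, , drop = FALSE])
    d2 <- cross(oi, ui, b[js, , drop = FALSE])
    d3 <- cross(a[js, , drop = FALSE], b[js, , drop = FALSE], oi)
    d4 <- cross(a[js, , drop = FALSE], b[js, , drop = FALSE], ui)
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Contour JSON input/output
#'
#' Contours are stored as `{"<slice index>": [[[y, x], ...], ...]}` with
#' vertex coordinates in mm.
#'
#' @param path JSON file path.
#' @return [read_contours()] returns a [slice_contours()].
#' @export
read_contours <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  contours <- lapply(j, function(polys) {
    lapply(polys, function(p) {
      do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
    })
  })
  slice_contours(contours)
}

#' @rdname read_contours
#' @param contours A [slice_contours()].
#' @export
write_contours <- function(contours, path) {
  stopifnot(inherits(contours, "slice_contours"))
  j <- lapply(contours$slices, function(polys) {
    lapply(polys, function(p) lapply(seq_len(nrow(p)), function(i) p[i, ]))
  })
  jsonlite::write_json(j, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# Even-odd scan-line rasterisation of polygons onto pixel centres
# (j - 1) * spacing. Crossing counts accumulate over all polygons, so
# overlapping contours carve holes, matching even-odd fill.
rasterize_polygons <- function(polys, ny, nx, sy, sx) {
  yc <- (seq_len(ny) - 1) * sy
  xc <- (seq_len(nx) - 1) * sx
  crossings <- matrix(0L, ny, nx)
  for (p in polys) {
    n <- nrow(p)
    y1 <- p[, 1]; x1 <- p[, 2]
    y2 <- p[c(2:n, 1), 1]; x2 <- p[c(2:n, 1), 2]
    for (e in seq_len(n)) {
      if (y1[e] == y2[e]) next
      ylo <- min(y1[e], y2[e]); yhi <- max(y1[e], y2[e])
      rows <- which(yc >= ylo & yc < yhi)   # half-open: vertex counted once
      if (length(rows) == 0L) next
      xi <- x1[e] + (yc[rows] - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
      for (k in seq_along(rows)) {
        cols <- xc < xi[k]
        crossings[rows[k], cols] <- crossings[rows[k], cols] + 1L
      }
    }
  }
  crossings %% 2L == 1L
}

# Signed distance (mm): positive inside the mask, negative outside.
signed_distance_2d <- function(mask, spacing) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  inside <- EBImage::distmap(m)
  outside <- EBImage::distmap(1 - m)
  (as.matrix(inside) - as.matrix(outside)) * spacing
}

#' Emulated manual delineation with inter-slice interpolation
#'
#' Annotated slices are rasterised exactly (even-odd fill at voxel centres);
#' slices between two annotated ones are filled by linear interpolation of
#' the signed-distance transforms of the bounding annotations, thresholded at
#' zero. No mask is produced outside the annotated extent. This emulates the
#' manual slice-wise drawing plus automatic interpolation used to obtain the
#' gold-standard total lung volume.
#'
#' @param contours A [slice_contours()].
#' @param grid A [ct_volume()] (or [voi_mask()]) defining the output grid.
#' @return A [voi_mask()] on the grid.
#' @export
delineate_from_contours <- function(contours, grid) {
  stopifnot(inherits(contours, "slice_contours"))
  dims <- dim(grid$data)
  sp <- grid$spacing
  idx <- contours$index
  if (min(idx) < 1L || max(idx) > dims[1])
    stop("annotated slice index out of grid bounds", call. = FALSE)
  extent_y <- (dims[2] - 1) * sp[2]
  extent_x <- (dims[3] - 1) * sp[3]
  for (polys in contours$slices) for (p in polys) {
    if (min(p) < -1e-9 || max(p[, 1]) > extent_y + 1e-9 ||
        max(p[, 2]) > extent_x + 1e-9)
      stop("polygon out of bounds", call. = FALSE)
  }
  if (max(abs(sp[2] - sp[3])) > 1e-9)
    warning("anisotropic in-plane spacing; distances use the coronal spacing")
  out <- array(0L, dims)
  rast <- lapply(contours$slices, rasterize_polygons,
                 ny = dims[2], nx = dims[3], sy = sp[2], sx = sp[3])
  for (k in seq_along(idx)) out[idx[k], , ] <- as.integer(rast[[k]])
  for (k in seq_len(length(idx) - 1L)) {
    z0 <- idx[k]; z1 <- idx[k + 1L]
    if (z1 - z0 < 2L) next
    s0 <- signed_distance_2d(rast[[k]], sp[2])
    s1 <- signed_distance_2d(rast[[k + 1L]], sp[2])
    for (z in (z0 + 1L):(z1 - 1L)) {
      t <- (z - z0) / (z1 - z0)
      out[z, , ] <- as.integer((1 - t) * s0 + t * s1 > 0)
    }
  }
  voi_mask(out, sp)
}
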