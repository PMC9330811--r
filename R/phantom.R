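#' Synthetic mouse-thorax phantom specification
#'
#' Parameterises the digital thorax phantom that stands in for animal scans.
#' The thoracic cavity is a smooth solid of revolution with an elliptical
#' cross-section interpolated from the carina plane to the diaphragm plane
#' (a truncated-cone-like body with a mild barrel bulge, so the frustum model
#' fits well but not perfectly). The cavity is split into lung and
#' mediastinum/heart; the lung into aerated parenchyma, non-aerated hilar
#' tissue, and optional lesions.
#'
#' Intensity model (HU): background air -1000; body soft tissue 40; bone 700;
#' aerated parenchyma drawn from a Gaussian of mean -500 and sd 80 truncated
#' to (-700, -300); lesions 30; plus additive Gaussian noise of `noise_sd`.
#'
#' @param shape Grid dimensions (axial, coronal, sagittal); default 256^3.
#' @param spacing Isotropic voxel size, mm (default 0.05).
#' @param carina_width Inner thoracic width at the carina level, mm (the
#'   small-base diameter of the frustum model).
#' @param diaphragm_depth Dorso-ventral depth at the diaphragm level, mm (the
#'   large-base diameter).
#' @param height Carina-to-diaphragm distance, mm.
#' @param lung_fraction Lung share of the thoracic cavity volume, in `[0, 1]`.
#' @param aeration_fraction Aerated share of the lung volume, in `[0, 1]`.
#' @param pathology `"none"`, `"nodules"` or `"consolidation"`.
#' @param burden Lesion share of the lung volume; must not exceed
#'   `aeration_fraction`.
#' @param noise_sd Additive Gaussian noise, HU.
#' @param seed Integer seed; identical specs give bit-identical phantoms.
#' @param lung_target_mm3 Optional absolute lung-volume target (mm^3)
#'   overriding `lung_fraction`; used when a cohort imposes a lung/thoracic
#'   relationship.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(256L, 256L, 256L), spacing = 0.05,
                         carina_width = 7.5, diaphragm_depth = 9.5,
                         height = 9.5, lung_fraction = 0.62,
                         aeration_fraction = 0.88,
                         pathology = c("none", "nodules", "consolidation"),
                         burden = 0, noise_sd = 25, seed = 1L,
                         lung_target_mm3 = NULL) {
  pathology <- match.arg(pathology)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("shape must be 3 dimensions of at least 16 voxels", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  geom <- c(carina_width = carina_width, diaphragm_depth = diaphragm_depth,
            height = height)
  if (any(geom <= 0)) stop("geometric parameters must be positive", call. = FALSE)
  for (f in c(lung_fraction, aeration_fraction, burden))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (pathology == "none" && burden > 0)
    stop("burden > 0 requires a pathology", call. = FALSE)
  if (pathology != "none" && burden > aeration_fraction)
    stop("burden exceeds aeration headroom", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  spec <- structure(
    list(shape = shape, spacing = spacing, carina_width = carina_width,
         diaphragm_depth = diaphragm_depth, height = height,
         lung_fraction = lung_fraction, aeration_fraction = aeration_fraction,
         pathology = pathology, burden = burden, noise_sd = noise_sd,
         seed = as.integer(seed), lung_target_mm3 = lung_target_mm3),
    class = "phantom_spec")
  check_phantom_fit(spec)
  spec
}

# anatomy layout constants (mm)
ph_wall <- 1.2      # chest-wall soft-tissue thickness
ph_cap_top <- 1.0   # soft tissue cranial of the carina plane
ph_cap_bot <- 1.5   # abdominal soft tissue caudal of the diaphragm plane
ph_bulge <- 0.08    # barrel bulge of the cavity profile

ph_geometry <- function(spec) {
  extent <- (spec$shape - 1L) * spec$spacing
  a0 <- spec$carina_width / 2
  a1 <- 1.15 * a0
  b1 <- spec$diaphragm_depth / 2
  b0 <- 0.75 * b1
  # centre the whole body (cavity plus asymmetric caps) along the axial axis
  z0 <- (extent[1] - spec$height - ph_cap_top - ph_cap_bot) / 2 + ph_cap_top
  list(extent = extent, a0 = a0, a1 = a1, b0 = b0, b1 = b1,
       z0 = z0, z1 = z0 + spec$height,
       yc = extent[2] / 2, xc = extent[3] / 2)
}

check_phantom_fit <- function(spec) {
  g <- ph_geometry(spec)
  ok <- g$z0 >= ph_cap_top + 0.15 &&
    g$z1 + ph_cap_bot + 0.15 <= g$extent[1] &&
    g$yc + g$b1 + ph_wall + 0.15 <= g$extent[2] &&
    g$yc - g$b1 - ph_wall - 0.15 >= 0 &&
    g$xc + g$a1 + ph_wall + 0.15 <= g$extent[3] &&
    g$xc - g$a1 - ph_wall - 0.15 >= 0
  if (!ok) stop("phantom geometry does not fit grid", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %s @ %.3g mm; carina %.3g / diaphragm %.3g / height %.3g mm\n",
    paste(x$shape, collapse = "x"), x$spacing[1], x$carina_width,
    x$diaphragm_depth, x$height))
  cat(sprintf("  lung %.2f of cavity, aeration %.2f, pathology %s (burden %.2f), noise %.3g HU, seed %d\n",
              x$lung_fraction, x$aeration_fraction, x$pathology, x$burden,
              x$noise_sd, x$seed))
  invisible(x)
}

# smooth carina->diaphragm interpolation with a barrel bulge; s(0)=0, s(1)=1
ph_profile <- function(t) t + ph_bulge * sin(pi * t)

#' Generate a synthetic mouse-thorax microCT phantom
#'
#' Builds the HU volume described in [phantom_spec()] together with a
#' ground-truth manifest whose volumes are exactly the voxel counts of the
#' internal generator masks times the voxel volume, and exact landmark
#' coordinates for the frustum measurement (both the lung-limit small base
#' and the rib-to-rib fallback).
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` ([ct_volume()], HU), `truth`
#'   (`phantom_truth`), and `masks` (list of [voi_mask()]: `body`, `cavity`,
#'   `lung`, `aerated`, `lesion`).
#' @export
generate_thorax_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_phantom_fit(spec)
  g <- ph_geometry(spec)
  dims <- spec$shape
  sp <- spec$spacing
  vv <- prod(sp)
  zmm <- (seq_len(dims[1]) - 1) * sp[1]
  ymm <- (seq_len(dims[2]) - 1) * sp[2]
  xmm <- (seq_len(dims[3]) - 1) * sp[3]

  ellipse_slice <- function(b, a) {
    outer(((ymm - g$yc) / b)^2, ((xmm - g$xc) / a)^2, "+") <= 1
  }
  tr_r <- 0.28  # trachea radius, mm
  trachea_slice <- outer((ymm - g$yc)^2, (xmm - g$xc)^2, "+") <= tr_r^2

  vol <- array(-1000, dims)
  body <- array(FALSE, dims)
  cavity <- array(FALSE, dims)

  z_body <- which(zmm >= g$z0 - ph_cap_top & zmm <= g$z1 + ph_cap_bot)
  z_cav <- which(zmm >= g$z0 & zmm <= g$z1)
  rib_centers <- seq(g$z0 + 0.35, g$z1 - 0.1, by = 0.9)
  spine_r <- 0.45

  for (iz in z_body) {
    t <- min(max((zmm[iz] - g$z0) / spec$height, 0), 1)
    s <- ph_profile(t)
    a <- g$a0 + (g$a1 - g$a0) * s
    b <- g$b0 + (g$b1 - g$b0) * s
    body_sl <- ellipse_slice(b + ph_wall, a + ph_wall)
    body[iz, , ] <- body_sl
    sl <- vol[iz, , ]
    sl[body_sl] <- 40
    in_cav <- zmm[iz] >= g$z0 && zmm[iz] <= g$z1
    if (in_cav) {
      cav_sl <- ellipse_slice(b, a) & !trachea_slice
      cavity[iz, , ] <- cav_sl
    }
    # vertebral body: dorsal circle inside the wall
    ysp <- g$yc - (b + 0.7)
    spine_sl <- outer((ymm - ysp)^2, (xmm - g$xc)^2, "+") <= spine_r^2
    sl[spine_sl & body_sl] <- 700
    # rib rings: thin high-density shells in the wall at periodic z bands
    if (in_cav && any(abs(zmm[iz] - rib_centers) <= 0.15)) {
      ring <- ellipse_slice(b + 0.45, a + 0.45) & !ellipse_slice(b + 0.15, a + 0.15)
      sl[ring] <- 700
    }
    # trachea air down to just below the carina plane
    if (zmm[iz] <= g$z0 + 0.8) sl[trachea_slice & body_sl] <- -1000
    vol[iz, , ] <- sl
  }

  n_cav <- sum(cavity)
  thoracic_mm3 <- n_cav * vv

  # lung / mediastinum split: exact voxel-count control by ranking cavity
  # voxels on their (z-elongated) distance from the heart centre
  if (!is.null(spec$lung_target_mm3)) {
    k <- as.integer(round(spec$lung_target_mm3 / vv))
    if (k < 0.05 * n_cav || k > 0.92 * n_cav)
      stop("requested lung volume infeasible for this thorax size",
           call. = FALSE)
  } else {
    k <- as.integer(round(spec$lung_fraction * n_cav))
  }
  idx_cav <- which(cavity)
  ai <- arrayInd(idx_cav, dims)
  cz <- zmm[ai[, 1]]; cy <- ymm[ai[, 2]]; cx <- xmm[ai[, 3]]
  heart <- c(g$z0 + 0.60 * spec$height, g$yc + 0.30 * g$b1, g$xc)
  d_heart <- ((cz - heart[1]) / 1.4)^2 + (cy - heart[2])^2 + (cx - heart[3])^2
  ord <- order(d_heart, idx_cav, decreasing = TRUE)
  idx_lung <- idx_cav[ord[seq_len(k)]]
  idx_heart <- idx_cav[ord[seq.int(k + 1L, n_cav)]]
  vol[idx_heart] <- 40

  truth <- with_seed(spec$seed, {
    # non-aerated hilar/vascular tissue: nearest lung voxels to the hilum
    li <- arrayInd(idx_lung, dims)
    lz <- zmm[li[, 1]]; ly <- ymm[li[, 2]]; lx <- xmm[li[, 3]]
    n_na <- as.integer(round((1 - spec$aeration_fraction) * k))
    hil <- c(g$z0 + 0.40 * spec$height, g$yc, g$xc)
    d_hil <- ((lz - hil[1]) / 2.5)^2 + (ly - hil[2])^2 + (lx - hil[3])^2
    ord_na <- order(d_hil, idx_lung)
    idx_na <- idx_lung[ord_na[seq_len(n_na)]]
    aer_pool <- ord_na[seq.int(n_na + 1L, k)]   # positions into idx_lung

    n_le <- if (spec$pathology == "none") 0L else
      as.integer(round(spec$burden * k))
    if (n_le > length(aer_pool))
      stop("burden exceeds aeration headroom", call. = FALSE)
    idx_les <- integer(0)
    if (n_le > 0L) {
      pz <- lz[aer_pool]; py <- ly[aer_pool]; px <- lx[aer_pool]
      if (spec$pathology == "nodules") {
        ctrs <- sample(length(aer_pool), 4L)
        d_le <- Reduce(pmin, lapply(ctrs, function(cc) {
          (pz - pz[cc])^2 + (py - py[cc])^2 + (px - px[cc])^2
        }))
      } else {
        cc <- which.max(pz + py)  # dependent ventro-caudal consolidation
        d_le <- (pz - pz[cc])^2 + (py - py[cc])^2 + (px - px[cc])^2
      }
      take <- order(d_le, aer_pool)[seq_len(n_le)]
      idx_les <- idx_lung[aer_pool[take]]
      aer_pool <- aer_pool[-take]
    }
    idx_aer <- idx_lung[aer_pool]

    vol[idx_na] <- 40
    vol[idx_les] <- 30
    # aerated parenchyma: Gaussian(-500, 80) truncated to (-700, -300)
    plo <- stats::pnorm(-2.5); phi <- stats::pnorm(2.5)
    u <- stats::runif(length(idx_aer), plo, phi)
    vol[idx_aer] <- stats::qnorm(u) * 80 - 500
    if (spec$noise_sd > 0)
      vol <- vol + array(stats::rnorm(length(vol), 0, spec$noise_sd), dims)

    lesion <- array(FALSE, dims); lesion[idx_les] <- TRUE
    aerated <- array(FALSE, dims); aerated[idx_aer] <- TRUE
    lung <- array(FALSE, dims); lung[idx_lung] <- TRUE
    masks <- list(body = voi_mask(body, sp), cavity = voi_mask(cavity, sp),
                  lung = voi_mask(lung, sp), aerated = voi_mask(aerated, sp),
                  lesion = voi_mask(lesion, sp))

    lm <- landmark_set(
      small_base = rbind(c(g$z0, g$yc, g$xc - g$a0), c(g$z0, g$yc, g$xc + g$a0)),
      large_base = rbind(c(g$z1, g$yc - g$b1, g$xc), c(g$z1, g$yc + g$b1, g$xc)),
      height = rbind(c(g$z0, g$yc, g$xc), c(g$z1, g$yc, g$xc)))
    lm_ribs <- landmark_set(
      small_base = rbind(c(g$z0, g$yc, g$xc - (g$a0 + 0.15)),
                         c(g$z0, g$yc, g$xc + (g$a0 + 0.15))),
      large_base = lm$large_base, height = lm$height)
    structure(
      list(thoracic_mm3 = thoracic_mm3, lung_mm3 = k * vv,
           aerated_mm3 = length(idx_aer) * vv, lesion_mm3 = length(idx_les) * vv,
           landmarks = lm, landmarks_ribs = lm_ribs,
           pathologic = spec$pathology != "none",
           d_small = spec$carina_width, d_large = spec$diaphragm_depth,
           height = spec$height,
           lung_fraction_realized = k / n_cav),
      class = "phantom_truth")
  })

  list(volume = ct_volume(vol, sp, units = "HU"), truth = truth, masks = masks)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth> thoracic %.2f, lung %.2f, aerated %.2f mm3%s\n",
    x$thoracic_mm3, x$lung_mm3, x$aerated_mm3,
    if (x$pathologic) sprintf(", pathologic (lesion %.2f mm3)", x$lesion_mm3)
    else ""))
  invisible(x)
}

#' Generate the air/water calibration tube phantom
#'
#' A raw-grey scan of a plastic tube whose lower compartment is water and
#' upper compartment air, with cylindrical VOIs placed strictly inside each
#' compartment, emulating the two-point HU calibration scan.
#'
#' @param shape Grid dimensions; default 128^3.
#' @param spacing Voxel size, mm.
#' @param air_grey,water_grey Designed compartment grey values.
#' @param noise_sd Additive Gaussian noise, grey units.
#' @param seed Integer seed.
#' @return A list with elements `volume` (raw-grey [ct_volume()]),
#'   `air_voi`, `water_voi` ([voi_mask()]s), `air_grey`, `water_grey`.
#' @export
generate_calibration_phantom <- function(shape = c(128L, 128L, 128L),
                                         spacing = 0.05,
                                         air_grey = 5000, water_grey = 25000,
                                         noise_sd = 50, seed = 1L) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  extent <- (shape - 1L) * spacing
  r_tube <- 0.35 * min(extent[2], extent[3])
  if (r_tube < 6 * max(spacing))
    stop("grid too small for two tube compartments", call. = FALSE)
  yc <- extent[2] / 2; xc <- extent[3] / 2
  zmm <- (seq_len(shape[1]) - 1) * spacing[1]
  ymm <- (seq_len(shape[2]) - 1) * spacing[2]
  xmm <- (seq_len(shape[3]) - 1) * spacing[3]
  z_lo <- 0.1 * extent[1]; z_hi <- 0.9 * extent[1]
  z_split <- z_lo + 0.45 * (z_hi - z_lo)
  r2 <- outer((ymm - yc)^2, (xmm - xc)^2, "+")
  in_tube2d <- r2 <= r_tube^2
  wall2d <- r2 <= (r_tube + 0.25)^2 & !in_tube2d

  vol <- array(air_grey, shape)
  for (iz in which(zmm >= z_lo & zmm <= z_hi)) {
    sl <- vol[iz, , ]
    sl[wall2d] <- water_grey * 1.06
    sl[in_tube2d] <- if (zmm[iz] <= z_split) water_grey else air_grey
    vol[iz, , ] <- sl
  }
  vol <- with_seed(seed, {
    if (noise_sd > 0) vol + array(stats::rnorm(length(vol), 0, noise_sd), shape)
    else vol
  })
  voi2d <- r2 <= (0.55 * r_tube)^2
  margin <- 0.5
  make_voi <- function(zmin, zmax) {
    m <- array(FALSE, shape)
    for (iz in which(zmm >= zmin & zmm <= zmax)) m[iz, , ] <- voi2d
    voi_mask(m, spacing)
  }
  water_voi <- make_voi(z_lo + margin, z_split - margin)
  air_voi <- make_voi(z_split + margin, z_hi - margin)
  stopifnot(sum(air_voi$data * water_voi$data) == 0L)
  list(volume = ct_volume(vol, spacing, units = "raw_grey"),
       air_voi = air_voi, water_voi = water_voi,
       air_grey = air_grey, water_grey = water_grey)
}

#' Default cohort population for [generate_cohort()]
#'
#' Thorax geometry varies through a latent animal-size factor that scales
#' all three dimensions together (allometric size variation) plus small
#' independent shape jitters. With the default base geometry (carina width
#' 8.75 mm, diaphragm depth 11.25 mm, height 11.75 mm), size
#' ~ U(0.875, 1.125) and 4 percent shape jitter, the thoracic-volume spread
#' of a simulated healthy cohort matches the scale reported for in-vivo
#' healthy mice (mean near 890 mm^3, SD near 190 mm^3), on a
#' 168 x 164 x 148 grid at 0.1 mm.
#'
#' @param shape,spacing Phantom grid.
#' @param carina_width,diaphragm_depth,height Base geometry, mm.
#' @param size_range `c(min, max)` of the uniform latent size factor.
#' @param jitter Half-width of the per-dimension uniform shape jitter
#'   (fractional).
#' @param aeration_fraction,noise_sd,pathology,burden Passed to every
#'   [phantom_spec()].
#' @return A list of population parameters.
#' @export
cohort_population <- function(shape = c(168L, 164L, 148L), spacing = 0.1,
                              carina_width = 8.75, diaphragm_depth = 11.25,
                              height = 11.75, size_range = c(0.875, 1.125),
                              jitter = 0.04,
                              aeration_fraction = 0.88, noise_sd = 25,
                              pathology = "none", burden = 0) {
  list(shape = shape, spacing = spacing, carina_width = carina_width,
       diaphragm_depth = diaphragm_depth, height = height,
       size_range = size_range, jitter = jitter,
       aeration_fraction = aeration_fraction, noise_sd = noise_sd,
       pathology = pathology, burden = burden)
}

#' Generate a seeded phantom cohort with a linear lung/thorax relationship
#'
#' Draws `n` thorax geometries from the population ranges and adjusts each
#' phantom's lung fraction so that, across the cohort, true total lung volume
#' equals `slope * true thoracic volume + intercept + eps` with
#' `eps ~ Normal(0, noise_sd^2)` (in mm^3). This reproduces the linear
#' structure that the regression-calibration stage is designed to estimate.
#'
#' @param n Number of phantoms (>= 3).
#' @param population See [cohort_population()].
#' @param slope Lung-on-thoracic slope, in `(0, 1]`.
#' @param intercept Intercept, mm^3 (>= 0).
#' @param noise_sd Residual SD of the lung/thorax line, mm^3.
#' @param seed Integer master seed; per-phantom sub-seeds are derived from it.
#' @param keep_volumes Keep the generated `ct_volume`s in the result (set
#'   `FALSE` to save memory when only truths are needed).
#' @return A tibble with one row per phantom: geometry draws, truth volumes,
#'   `pathologic`, a `truth` list-column, and (optionally) a `volume`
#'   list-column.
#' @export
generate_cohort <- function(n, population = cohort_population(),
                            slope = 0.20, intercept = 300, noise_sd = 20,
                            seed = 1L, keep_volumes = TRUE) {
  if (n < 3) stop("need >= 3 phantoms", call. = FALSE)
  if (slope <= 0 || slope > 1) stop("slope must lie in (0, 1]", call. = FALSE)
  if (intercept < 0) stop("intercept must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  rows <- purrr::map(seq_len(n), function(i) {
    si <- sub_seed(seed, i)
    draws <- with_seed(si, {
      size <- stats::runif(1, population$size_range[1],
                           population$size_range[2])
      j <- stats::runif(3, 1 - population$jitter, 1 + population$jitter)
      list(cw = population$carina_width * size * j[1],
           dd = population$diaphragm_depth * size * j[2],
           hh = population$height * size * j[3],
           eps = stats::rnorm(1, 0, noise_sd))
    })
    # two-stage: measure the cavity volume of this geometry, then rebuild
    # with the lung volume the regression line dictates
    base_spec <- phantom_spec(
      shape = population$shape, spacing = population$spacing,
      carina_width = draws$cw, diaphragm_depth = draws$dd, height = draws$hh,
      aeration_fraction = population$aeration_fraction,
      pathology = population$pathology, burden = population$burden,
      noise_sd = population$noise_sd, seed = sub_seed(si, 7L))
    ph <- generate_thorax_phantom(ph_with_target(base_spec, draws$eps,
                                                 slope, intercept))
    tibble::tibble(
      scan_id = sprintf("phantom_%03d", i),
      carina_width = draws$cw, diaphragm_depth = draws$dd, height = draws$hh,
      thoracic_mm3 = ph$truth$thoracic_mm3, lung_mm3 = ph$truth$lung_mm3,
      aerated_mm3 = ph$truth$aerated_mm3, pathologic = ph$truth$pathologic,
      truth = list(ph$truth),
      volume = if (keep_volumes) list(ph$volume) else list(NULL))
  })
  out <- dplyr::bind_rows(rows)
  if (!keep_volumes) out$volume <- NULL
  out
}

# Resolve the cohort lung target: the cavity voxel count depends only on the
# deterministic geometry, so it can be computed cheaply before generation.
ph_with_target <- function(spec, eps, slope, intercept) {
  vthor <- cavity_volume_mm3(spec)
  target <- slope * vthor + intercept + eps
  if (target < 0.05 * vthor || target > 0.92 * vthor)
    stop("requested (slope, intercept) infeasible for the thorax size distribution",
         call. = FALSE)
  spec$lung_target_mm3 <- target
  spec
}

# Voxel-count cavity volume of a spec, without building the full phantom.
cavity_volume_mm3 <- function(spec) {
  g <- ph_geometry(spec)
  sp <- spec$spacing
  zmm <- (seq_len(spec$shape[1]) - 1) * sp[1]
  ymm <- (seq_len(spec$shape[2]) - 1) * sp[2]
  xmm <- (seq_len(spec$shape[3]) - 1) * sp[3]
  tr2 <- outer((ymm - g$yc)^2, (xmm - g$xc)^2, "+") <= 0.28^2
  n <- 0L
  for (iz in which(zmm >= g$z0 & zmm <= g$z1)) {
    t <- (zmm[iz] - g$z0) / spec$height
    s <- ph_profile(t)
    a <- g$a0 + (g$a1 - g$a0) * s
    b <- g$b0 + (g$b1 - g$b0) * s
    sl <- outer(((ymm - g$yc) / b)^2, ((xmm - g$xc) / a)^2, "+") <= 1
    n <- n + sum(sl & !tr2)
  }
  n * prod(sp)
}
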