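#' Rigid rotation matrix from yaw/pitch/roll angles
#'
#' Angles are in degrees: yaw rotates about the cranio-caudal axis (axis 1),
#' pitch about the dorso-ventral axis (axis 2), roll about the left-right
#' axis (axis 3), composed as yaw %*% pitch %*% roll.
#'
#' @param yaw,pitch,roll Rotation angles, degrees.
#' @return A 3 x 3 orthonormal rotation matrix.
#' @export
rotation_matrix <- function(yaw = 0, pitch = 0, roll = 0) {
  ax <- function(theta, k) {
    th <- theta * pi / 180
    R <- diag(3)
    ij <- setdiff(1:3, k)
    R[ij[1], ij[1]] <- cos(th); R[ij[2], ij[2]] <- cos(th)
    R[ij[1], ij[2]] <- -sin(th); R[ij[2], ij[1]] <- sin(th)
    R
  }
  ax(yaw, 1) %*% ax(pitch, 2) %*% ax(roll, 3)
}

check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)))
    stop("rotation must be a 3 x 3 matrix or yaw/pitch/roll angles",
         call. = FALSE)
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("rotation matrix not orthonormal within tolerance 1e-6",
         call. = FALSE)
  R
}

as_rotation <- function(rotation) {
  if (is.matrix(rotation)) return(check_rotation(rotation))
  if (is.numeric(rotation) && length(rotation) == 3L)
    return(rotation_matrix(rotation[1], rotation[2], rotation[3]))
  stop("rotation must be a 3 x 3 matrix or c(yaw, pitch, roll) degrees",
       call. = FALSE)
}

is_signed_permutation <- function(R, tol = 1e-9) {
  near <- abs(abs(R) - 1) < tol | abs(R) < tol
  all(near) && all(colSums(abs(R) > 0.5) == 1L) && all(rowSums(abs(R) > 0.5) == 1L)
}

#' Reorient a CT volume by a rigid rotation
#'
#' Emulates the manual reorientation step of the protocol (vertebrae and
#' sternum aligned in the axial plane, contralateral ribs aligned in coronal
#' view). Axis-aligned 90/180 degree rotations are applied as exact voxel
#' permutations; any other rotation is resampled trilinearly on the original
#' grid about the volume centre. Masks should be reoriented with
#' [reorient_mask()], which uses nearest-neighbour sampling to stay binary.
#'
#' @param vol A [ct_volume()].
#' @param rotation A 3 x 3 proper rotation matrix, or `c(yaw, pitch, roll)` in
#'   degrees (see [rotation_matrix()]).
#' @param fill Value for voxels sampled outside the original grid; defaults to
#'   -1000 for HU volumes (air) and the volume minimum for raw grey.
#' @return A [ct_volume()] on the same spacing.
#' @export
reorient <- function(vol, rotation, fill = NULL) {
  stopifnot(inherits(vol, "ct_volume"))
  R <- as_rotation(rotation)
  check_rotation(R)
  if (is.null(fill))
    fill <- if (vol$units == "HU") -1000 else min(vol$data)
  out <- resample_rigid(vol$data, vol$spacing, R, fill, nearest = FALSE)
  orient <- vol$orientation
  if (!is.null(attr(out, "perm"))) orient <- orient[attr(out, "perm")]
  ct_volume(strip_attrs(out), vol$spacing, units = vol$units,
            orientation = orient)
}

#' @rdname reorient
#' @param mask A [voi_mask()].
#' @export
reorient_mask <- function(mask, rotation) {
  stopifnot(inherits(mask, "voi_mask"))
  R <- as_rotation(rotation)
  check_rotation(R)
  out <- resample_rigid(mask$data, mask$spacing, R, 0L, nearest = TRUE)
  voi_mask(strip_attrs(out), mask$spacing)
}

strip_attrs <- function(a) { attr(a, "perm") <- NULL; a }

# Rigid resampling about the volume centre. Output grid keeps the input
# spacing; for signed-permutation rotations the voxel lattice maps onto
# itself and the permutation is applied exactly (no interpolation).
resample_rigid <- function(arr, spacing, R, fill, nearest) {
  dims <- dim(arr)
  if (is_signed_permutation(R)) {
    Rp <- round(R)
    # output axis i draws from input axis j where Rp[i, j] != 0
    j_of_i <- apply(abs(Rp) > 0L, 1L, which)
    if (max(abs(spacing[j_of_i] - spacing)) < 1e-12) {
      dims_out <- dims[j_of_i]
      idx <- vector("list", 3L)     # per input axis: index vector over output
      exact <- TRUE
      for (i in 1:3) {
        j <- j_of_i[i]
        s <- Rp[i, j]
        # x_in_j = s * (o_i - c_out_i) + c_in_j   (0-based voxel coordinates)
        ci_out <- (dims_out[i] - 1) / 2
        ci_in <- (dims[j] - 1) / 2
        v <- s * ((seq_len(dims_out[i]) - 1) - ci_out) + ci_in + 1
        if (max(abs(v - round(v))) > 1e-9) { exact <- FALSE; break }
        idx[[j]] <- as.integer(round(v))
      }
      if (exact) {
        tmp <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
        # tmp axis m (input axis m) is indexed by output axis i_of_j[m]
        i_of_j <- apply(abs(Rp) > 0L, 2L, which)
        out <- aperm(tmp, match(1:3, i_of_j))
        attr(out, "perm") <- j_of_i
        return(out)
      }
    }
  }
  # general path: inverse-map output voxel centres through t(R)
  ctr <- (dims - 1) / 2 * spacing
  g1 <- ((seq_len(dims[1]) - 1) * spacing[1]) - ctr[1]
  g2 <- ((seq_len(dims[2]) - 1) * spacing[2]) - ctr[2]
  g3 <- ((seq_len(dims[3]) - 1) * spacing[3]) - ctr[3]
  n <- prod(dims)
  p1 <- rep(g1, times = dims[2] * dims[3])
  p2 <- rep(rep(g2, each = dims[1]), times = dims[3])
  p3 <- rep(g3, each = dims[1] * dims[2])
  Rt <- t(R)
  s1 <- (Rt[1, 1] * p1 + Rt[1, 2] * p2 + Rt[1, 3] * p3 + ctr[1]) / spacing[1]
  s2 <- (Rt[2, 1] * p1 + Rt[2, 2] * p2 + Rt[2, 3] * p3 + ctr[2]) / spacing[2]
  s3 <- (Rt[3, 1] * p1 + Rt[3, 2] * p2 + Rt[3, 3] * p3 + ctr[3]) / spacing[3]
  rm(p1, p2, p3)
  out <- if (nearest) {
    sample_nearest(arr, s1, s2, s3, fill)
  } else {
    sample_trilinear(arr, s1, s2, s3, fill)
  }
  array(out, dims)
}

sample_nearest <- function(arr, s1, s2, s3, fill) {
  dims <- dim(arr)
  i1 <- as.integer(round(s1)) + 1L
  i2 <- as.integer(round(s2)) + 1L
  i3 <- as.integer(round(s3)) + 1L
  ok <- i1 >= 1L & i1 <= dims[1] & i2 >= 1L & i2 <= dims[2] &
    i3 >= 1L & i3 <= dims[3]
  out <- rep(fill, length(s1))
  lin <- (i3[ok] - 1L) * (dims[1] * dims[2]) + (i2[ok] - 1L) * dims[1] + i1[ok]
  out[ok] <- arr[lin]
  out
}

sample_trilinear <- function(arr, s1, s2, s3, fill) {
  dims <- dim(arr)
  f1 <- floor(s1); f2 <- floor(s2); f3 <- floor(s3)
  w1 <- s1 - f1; w2 <- s2 - f2; w3 <- s3 - f3
  ok <- f1 >= 0 & f1 <= dims[1] - 1 & f2 >= 0 & f2 <= dims[2] - 1 &
    f3 >= 0 & f3 <= dims[3] - 1 &
    (f1 + 1) <= dims[1] - 1e-9 + 1 & TRUE
  # corner indices, clamped so that voxels exactly on the upper face work
  c1 <- pmin(f1 + 1, dims[1] - 1); c2 <- pmin(f2 + 1, dims[2] - 1)
  c3 <- pmin(f3 + 1, dims[3] - 1)
  ok <- f1 >= 0 & c1 <= dims[1] - 1 & f2 >= 0 & c2 <= dims[2] - 1 &
    f3 >= 0 & c3 <= dims[3] - 1 & s1 <= dims[1] - 1 + 1e-9 &
    s2 <= dims[2] - 1 + 1e-9 & s3 <= dims[3] - 1 + 1e-9
  out <- rep(as.numeric(fill), length(s1))
  if (!any(ok)) return(out)
  gi <- function(a, b, c) {
    arr[(c - 1) * (dims[1] * dims[2]) + (b - 1) * dims[1] + a]
  }
  a0 <- as.integer(f1[ok]) + 1L; a1 <- as.integer(c1[ok]) + 1L
  b0 <- as.integer(f2[ok]) + 1L; b1 <- as.integer(c2[ok]) + 1L
  d0 <- as.integer(f3[ok]) + 1L; d1 <- as.integer(c3[ok]) + 1L
  u <- w1[ok]; v <- w2[ok]; w <- w3[ok]
  val <-
    gi(a0, b0, d0) * (1 - u) * (1 - v) * (1 - w) +
    gi(a1, b0, d0) * u       * (1 - v) * (1 - w) +
    gi(a0, b1, d0) * (1 - u) * v       * (1 - w) +
    gi(a1, b1, d0) * u       * v       * (1 - w) +
    gi(a0, b0, d1) * (1 - u) * (1 - v) * w +
    gi(a1, b0, d1) * u       * (1 - v) * w +
    gi(a0, b1, d1) * (1 - u) * v       * w +
    gi(a1, b1, d1) * u       * v       * w
  out[ok] <- val
  out
}
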