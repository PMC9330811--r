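# Small, fast phantom used across unit tests (~0.9 M voxels, < 1 s to build).
small_spec <- function(...) {
  args <- list(shape = c(96L, 96L, 96L), spacing = 0.12,
               carina_width = 6, diaphragm_depth = 7.5, height = 7.5,
               noise_sd = 0, seed = 42L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

# Circle contours of radius r (mm) around the in-plane centre of `grid`,
# drawn on the given axial slices.
circle_contours <- function(grid, r, slices, n_vertices = 181) {
  sp <- grid$spacing
  cy <- (dim(grid$data)[2] - 1) / 2 * sp[2]
  cx <- (dim(grid$data)[3] - 1) / 2 * sp[3]
  cz <- (dim(grid$data)[1] - 1) / 2 * sp[1]
  theta <- seq(0, 2 * pi, length.out = n_vertices)[-n_vertices]
  out <- list()
  for (iz in slices) {
    dz <- (iz - 1) * sp[1] - cz
    if (abs(dz) >= r) next
    rad <- sqrt(r^2 - dz^2)
    if (rad < 2 * sp[2]) next
    out[[as.character(iz)]] <- cbind(cy + rad * sin(theta),
                                     cx + rad * cos(theta))
  }
  slice_contours(out)
}

# Independent voxelisation oracle for the frustum volume: counts lattice
# points (voxel centres at `sp` spacing) inside the solid of revolution with
# linearly interpolated radius, slice by slice, without using the closed form.
voxelized_frustum_mm3 <- function(d_small, d_large, height, sp = 0.05) {
  r1 <- d_small / 2; r2 <- d_large / 2
  zc <- seq(sp / 2, height, by = sp)
  zc <- zc[zc <= height]
  total <- 0
  for (z in zc) {
    r <- r1 + (r2 - r1) * z / height
    yc <- seq(0, r, by = sp)
    yc <- yc[yc <= r]
    half <- sqrt(pmax(r^2 - yc^2, 0))
    counts <- 2 * floor(half / sp) + 1
    # row y=0 counted once, rows y>0 mirrored
    total <- total + counts[1] + 2 * sum(counts[-1])
  }
  total * sp^3
}
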