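# Shared fixtures, built in code at test time.

# uniform mu volume on a small grid
uniform_mu <- function(value, dim = c(9, 9, 3), spacing = 2) {
  g <- voxel_grid(dim, spacing)
  mu_volume(array(value, g$dim), g)
}

# a slab whose last voxel centre along +y sits exactly `depth_mm` from `y0`
slab_for_depth <- function(mu, depth_mm, spacing = 2) {
  ny <- depth_mm / spacing + 16
  g <- voxel_grid(c(5, ny, 3), spacing, origin = c(-4, -30, -2))
  mu_volume(array(mu, g$dim), g)
}

# world y of the slab's last voxel centre (the effective surface for rays)
slab_surface_y <- function(vol) {
  g <- vol$grid
  g$origin[2] + (g$dim[2] - 1) * g$spacing[2]
}

# uniform disk of radius R in one axial slice
disk_mu <- function(mu, R_mm = 60, n = 81, spacing = 2) {
  g <- voxel_grid(c(n, n, 1), spacing)
  X <- matrix(axis_coords(g, 1), n, n)
  Y <- matrix(axis_coords(g, 2), n, n, byrow = TRUE)
  mu_volume(array(mu * ((X^2 + Y^2) <= R_mm^2), g$dim), g)
}

# small three-insert phantom with distinct materials
mini_layout <- function() {
  insert_layout(
    tibble::tibble(material = c("lung_inhale", "muscle", "bone_ha800"),
                   x_mm = c(-40, 40, 0), y_mm = c(0, 0, 45),
                   r_mm = 15, ring = c("inner", "inner", "outer")),
    body_half_axes_mm = c(90, 80), body_z_mm = c(-30, 30),
    insert_z_mm = c(-30, 30), homogeneous_z_mm = c(-30, -30))
}

mini_grid <- function(spacing = 3) {
  voxel_grid(c(ceiling(200 / spacing), ceiling(200 / spacing), 10), spacing)
}

# single-voxel mask helper
one_voxel_mask <- function(grid, i, j, k) {
  m <- array(FALSE, grid$dim)
  m[i, j, k] <- TRUE
  m
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
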