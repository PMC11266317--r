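test_that("bilinear conversion hits the water, air and half-water anchors", {
  g <- voxel_grid(c(4, 4, 2), 4)
  m <- bilinear_model()
  hu <- hu_volume(array(c(0, -1000, -500, 200), g$dim), g)
  mu <- hu_to_mu(hu, m, kvp = 130)
  expect_equal(mu$data[1, 1, 1], m$mu_water)
  expect_equal(mu$data[2, 1, 1], 0)
  expect_equal(mu$data[3, 1, 1], m$mu_water / 2)
  expect_equal(mu$data[4, 1, 1],
               m$mu_water + 200 * m$bone_slope[["130"]])
  expect_equal(mu$energy_keV, 208.4)
})

test_that("the conversion is continuous at the breakpoint and order preserving", {
  m <- bilinear_model()
  g <- voxel_grid(c(101, 1, 1), 1)
  hus <- sort(stats::runif(101, -1000, 1500))
  mu <- hu_to_mu(hu_volume(array(hus, g$dim), g), m, 110)
  expect_true(all(diff(as.vector(mu$data)) >= 0))
  eps <- hu_to_mu(hu_volume(array(c(-1e-9, 1e-9), voxel_grid(c(2, 1, 1), 1)$dim),
                            voxel_grid(c(2, 1, 1), 1)), m, 110)
  expect_lt(abs(diff(as.vector(eps$data))), 1e-9)
})

test_that("uncalibrated tube voltages are rejected", {
  g <- voxel_grid(c(2, 2, 1), 4)
  hu <- hu_volume(array(0, g$dim), g)
  expect_error(hu_to_mu(hu, bilinear_model(), kvp = 100), "kVp")
})

test_that("resampling is exact on identity, uniform and affine fields", {
  g <- voxel_grid(c(20, 20, 6), c(2, 2, 4))
  ident <- resample_mu(uniform_mu(0.1, c(20, 20, 6), 2), voxel_grid(c(20, 20, 6), 2))
  expect_identical(ident$data, uniform_mu(0.1, c(20, 20, 6), 2)$data)

  coarse <- voxel_grid(c(7, 7, 3), c(5, 5, 7))
  uni <- mu_volume(array(0.2, g$dim), g)
  expect_true(all(abs(resample_mu(uni, coarse)$data - 0.2) < 1e-12))

  # trilinear interpolation reproduces an affine ramp exactly
  xs <- axis_coords(g, 1); ys <- axis_coords(g, 2); zs <- axis_coords(g, 3)
  ramp <- outer(outer(2 + 0.01 * xs, 0.02 * ys, "+"), 0.005 * zs, "+") / 100
  rv <- mu_volume(ramp, g)
  out <- resample_mu(rv, coarse)
  ox <- axis_coords(coarse, 1); oy <- axis_coords(coarse, 2); oz <- axis_coords(coarse, 3)
  expected <- outer(outer(2 + 0.01 * ox, 0.02 * oy, "+"), 0.005 * oz, "+") / 100
  expect_equal(out$data, expected, tolerance = 1e-12)
})

test_that("targets beyond the source extent error unless zero-filled", {
  src <- uniform_mu(0.1, c(10, 10, 4), 2)
  big <- voxel_grid(c(10, 10, 4), 4)
  expect_error(resample_mu(src, big), "outside")
  padded <- resample_mu(src, big, outside = "zero")
  expect_equal(padded$data[5, 5, 2], 0.1)
  expect_equal(padded$data[1, 1, 1], 0)   # outside the CT field of view
})

test_that("noise-free CT emulation round-trips soft-tissue mu within 3 percent", {
  reg <- material_registry()
  soft <- c("lung_inhale", "lung_exhale", "adipose", "breast", "muscle",
            "liver", "plastic_water")
  g <- voxel_grid(c(4, 4, 2), 4)
  model <- bilinear_model()
  for (kvp in c(80, 110, 130)) {
    s0 <- scan_setting(kvp, 20, sigma_hu = 0, drift_hu = 0)
    for (m in soft) {
      lv <- label_volume(array(1L, g$dim), g,
                         tibble::tibble(label = 1L, material = m))
      mu <- hu_to_mu(emulate_ct(lv, s0, reg, smooth_sigma_vox = 0), model, kvp)
      truth <- linear_attenuation(reg[[m]], 208.4)
      expect_lt(abs(mu$data[1, 1, 1] / truth - 1), 0.03)
    }
  }
})
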