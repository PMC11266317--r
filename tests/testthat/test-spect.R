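quant_test_grid <- voxel_grid(c(48, 48, 8), 4.8)

test_that("syringe voxelisation conserves the nominal activities exactly", {
  for (src in c("1mL", "10mL")) {
    ph <- build_quant_phantom(src, quant_test_grid,
                              body_half_axes_mm = c(110, 90),
                              cylinder_ring_mm = 55)
    vv <- voxel_volume_ml(quant_test_grid)
    for (nm in names(ph$activity$nominal_MBq)) {
      lab <- ph$labels$legend$label[ph$labels$legend$segment == paste0("syringe_", nm)]
      tot <- sum(ph$activity$data[ph$labels$data == lab]) * vv
      expect_equal(tot, ph$activity$nominal_MBq[[nm]], tolerance = 1e-9)
    }
  }
})

test_that("the 1-mL syringe spans at most two voxels transaxially", {
  ph <- build_quant_phantom("1mL", quant_test_grid,
                            body_half_axes_mm = c(110, 90),
                            cylinder_ring_mm = 55)
  for (lab in 6:9) {
    hit <- which(ph$labels$data == lab, arr.ind = TRUE)
    expect_lte(diff(range(hit[, 1])) + 1, 2)
    expect_lte(diff(range(hit[, 2])) + 1, 2)
  }
})

test_that("zero requested activity produces an all-zero activity volume", {
  ph <- build_quant_phantom("10mL", quant_test_grid,
                            activities_MBq = c(PS = 0, PTFE = 0, PA = 0, PP = 0),
                            body_half_axes_mm = c(110, 90),
                            cylinder_ring_mm = 55)
  expect_true(all(ph$activity$data == 0))
})

test_that("a syringe wider than its bore is a geometry error", {
  expect_error(build_quant_phantom("10mL", quant_test_grid, syringe_r_mm = 20),
               "bore")
})

test_that("projection is zero for zero activity and isotropic for a point in vacuum", {
  g <- voxel_grid(c(17, 17, 1), 4)
  zero <- activity_volume(array(0, g$dim), g)
  vac <- mu_volume(array(0, g$dim), g)
  sys <- system_config(n_views = 12, psf_sigma_mm = 0)
  expect_true(all(forward_project(zero, vac, sys)$counts == 0))

  pt <- array(0, g$dim); pt[9, 9, 1] <- 1
  sino <- forward_project(activity_volume(pt, g), vac, sys)
  per_view <- apply(sino$counts, 2, sum)
  expect_rel_equal(per_view, per_view[1], 1e-9)
})

test_that("a uniform slab attenuates a view by the Beer-Lambert factor", {
  g <- voxel_grid(c(17, 17, 1), 4)
  pt <- array(0, g$dim); pt[9, 9, 1] <- 2
  mu <- array(0, g$dim)
  mu[, 12:14, 1] <- 0.1   # slab above the source (+y)
  sys <- system_config(n_views = 8, psf_sigma_mm = 0)
  sino <- forward_project(activity_volume(pt, g), mu_volume(mu, g), sys)
  through <- sum(sino$counts[, 1, ])            # view at 0: project along +y
  opposite <- sum(sino$counts[, 5, ])           # view at 90 deg misses the slab
  expect_rel_equal(through / opposite, exp(-0.1 * 3 * 0.4), 1e-9)
})

test_that("OSEM reconstructs zero data to zero and scales with duration", {
  g <- voxel_grid(c(16, 16, 1), 4)
  act <- array(0, g$dim); act[6:8, 6:8, 1] <- 0.5
  vac <- mu_volume(array(0, g$dim), g)
  sys1 <- system_config(n_views = 12, view_time_s = 10, psf_sigma_mm = 0)
  sys2 <- system_config(n_views = 12, view_time_s = 20, psf_sigma_mm = 0)
  av <- activity_volume(act, g)
  s1 <- forward_project(av, vac, sys1)
  s2 <- forward_project(av, vac, sys2)
  expect_equal(s2$counts, 2 * s1$counts, tolerance = 1e-12)

  z <- s1; z$counts[] <- 0
  expect_true(all(osem(z, vac, sys1, 2, 3)$data == 0))

  c1 <- osem(s1, vac, sys1, 3, 3, value = "counts")
  c2 <- osem(s2, vac, sys2, 3, 3, value = "counts")
  expect_equal(c2$data, 2 * c1$data, tolerance = 1e-6)
})

test_that("subset counts must divide the views", {
  g <- voxel_grid(c(8, 8, 1), 4)
  vac <- mu_volume(array(0, g$dim), g)
  sino <- forward_project(activity_volume(array(0, g$dim), g), vac,
                          system_config(n_views = 10, psf_sigma_mm = 0))
  expect_error(osem(sino, vac, subsets = 4), "divide")
  expect_error(system_config(n_views = 4), "n_views")
  expect_error(system_config(icf_cps_per_MBq = 0), "ICF")
})

test_that("quantification recovers ground truth and flags spill-out direction", {
  g <- voxel_grid(c(24, 24, 8), 4.8)
  act <- array(0, g$dim)
  act[11:13, 11:13, 4:5] <- 2
  av <- activity_volume(act, g)
  vv <- voxel_volume_ml(g)
  nominal <- sum(act) * vv
  sys <- system_config(psf_sigma_mm = 5)
  q <- quantify(av, c(0, 0, 0), radius_mm = 40, half_len_mm = 18,
                nominal_MBq = nominal, source_r_mm = 7, sys = sys)
  expect_equal(q$rel_error_pct, 0, tolerance = 1e-9)

  # blur the truth: a tight VOI must under-recover relative to an extended one
  blurred <- spectac:::gaussian_smooth_inplane(act, 1.2)
  bv <- activity_volume(blurred, g)
  tight <- suppressWarnings(
    quantify(bv, c(0, 0, 0), radius_mm = 7, half_len_mm = 5,
             nominal_MBq = nominal, source_r_mm = 7, sys = sys))
  wide <- quantify(bv, c(0, 0, 0), radius_mm = 40, half_len_mm = 18,
                   nominal_MBq = nominal, source_r_mm = 7, sys = sys)
  expect_lt(tight$recovered_MBq, wide$recovered_MBq)
  expect_true(tight$clipped)
  expect_false(wide$clipped)
})

test_that("mu-map errors propagate sublinearly into recovered activity", {
  g <- voxel_grid(c(48, 48, 8), 4.8)
  ph <- build_quant_phantom("10mL", g, body_half_axes_mm = c(110, 90),
                            cylinder_ring_mm = 55)
  mu_true <- labels_to_mu(ph$labels)
  sys <- system_config(n_views = 24, psf_sigma_mm = 5)
  sino <- forward_project(ph$activity, mu_true, sys)
  ptfe_lab <- ph$labels$legend$label[ph$labels$legend$segment == "cylinder_PTFE"]
  src <- ph$sources[ph$sources$name == "PTFE", ]
  rec <- function(mu_map) {
    r <- osem(sino, mu_map, sys, 4, 6)
    quantify(r, c(src$x_mm, src$y_mm, 0), src$syringe_r_mm + 2 * 2.355 * 5,
             src$syringe_len_mm / 2 + 2 * 2.355 * 5,
             ph$activity$nominal_MBq[["PTFE"]], src$syringe_r_mm, sys,
             "PTFE")$recovered_MBq
  }
  base <- rec(mu_true)
  for (f in c(0.9, 1.1)) {
    pert <- mu_true$data
    pert[ph$labels$data == ptfe_lab] <- pert[ph$labels$data == ptfe_lab] * f
    change <- abs(rec(mu_volume(pert, g)) / base - 1) * 100
    expect_lt(change, 5)  # far below the 10 percent mu perturbation
  }
})
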