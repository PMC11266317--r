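# coarse grid that still covers the whole default phantom
phantom_test_grid <- voxel_grid(c(74, 74, 20), c(4.8, 4.8, 6.5))

test_that("the default phantom voxelises to 19 segments on a small grid", {
  ph <- build_density_phantom(default_density_layout(), phantom_test_grid)
  expect_length(unique(as.vector(ph$data)), 19L)
  expect_setequal(unique(as.vector(ph$data)), 0:18)
})

test_that("a layout without inserts yields body and air only", {
  lay <- insert_layout(default_density_layout()$inserts[0, ])
  ph <- build_density_phantom(lay, phantom_test_grid)
  expect_setequal(unique(as.vector(ph$data)), c(0L, 1L))
})

test_that("phantom generation is deterministic", {
  a <- build_density_phantom(mini_layout(), mini_grid())
  b <- build_density_phantom(mini_layout(), mini_grid())
  expect_identical(a$data, b$data)
})

test_that("voxelised insert volume matches the analytic cylinder volume", {
  g <- voxel_grid(c(120, 120, 40), c(2, 2, 2))
  lay <- mini_layout()
  ph <- build_density_phantom(lay, g)
  vv <- prod(g$spacing)
  for (i in seq_len(nrow(lay$inserts))) {
    ins <- lay$inserts[i, ]
    len <- diff(lay$insert_z_mm) + g$spacing[3]  # centre-membership spans
    analytic <- pi * ins$r_mm^2 * len
    counted <- sum(ph$data == i + 1L) * vv
    shell <- (2 * pi * ins$r_mm * len + 2 * pi * ins$r_mm^2) * min(g$spacing)
    expect_lt(abs(counted - analytic), shell)
  }
})

test_that("invalid layouts are rejected", {
  bad <- tibble::tibble(material = c("muscle", "liver"),
                        x_mm = c(0, 10), y_mm = c(0, 0), r_mm = 15,
                        ring = "inner")
  expect_error(insert_layout(bad), "overlap")
  far <- tibble::tibble(material = "muscle", x_mm = 200, y_mm = 0, r_mm = 15,
                        ring = "inner")
  expect_error(insert_layout(far), "outside the body")
})

test_that("majority downsampling preserves uniform and identity inputs", {
  g <- mini_grid()
  legend <- tibble::tibble(label = c(0L, 5L), material = c("air", "water"))
  uni <- label_volume(array(5L, g$dim), g, legend)
  coarse <- voxel_grid(c(11, 11, 5), c(6, 6, 6))
  down <- downsample_labels(uni, coarse)
  expect_true(all(down$data == 5L))
  same <- downsample_labels(uni, g)
  expect_identical(same$data, uni$data)
})

test_that("majority downsampling matches a brute-force overlap count", {
  src_g <- voxel_grid(c(40, 40, 8), c(2, 2, 4))
  tgt <- voxel_grid(c(12, 12, 4), c(7, 7, 8))
  ph <- build_density_phantom(mini_layout(), src_g)
  down <- downsample_labels(ph, tgt)
  # brute force: nested loops over source voxels
  counts <- array(0L, c(prod(tgt$dim), 19))
  xs <- axis_coords(src_g, 1); ys <- axis_coords(src_g, 2); zs <- axis_coords(src_g, 3)
  for (k in seq_len(src_g$dim[3])) for (j in seq_len(src_g$dim[2]))
    for (i in seq_len(src_g$dim[1])) {
      ti <- round((xs[i] - tgt$origin[1]) / tgt$spacing[1]) + 1
      tj <- round((ys[j] - tgt$origin[2]) / tgt$spacing[2]) + 1
      tk <- round((zs[k] - tgt$origin[3]) / tgt$spacing[3]) + 1
      if (ti < 1 || ti > tgt$dim[1] || tj < 1 || tj > tgt$dim[2] ||
          tk < 1 || tk > tgt$dim[3]) next
      cell <- ti + (tj - 1) * tgt$dim[1] + (tk - 1) * tgt$dim[1] * tgt$dim[2]
      lab <- ph$data[i, j, k]
      counts[cell, lab + 1L] <- counts[cell, lab + 1L] + 1L
    }
  expected <- apply(counts, 1, function(r) {
    if (all(r == 0)) 0L else which.max(r) - 1L  # which.max: first = smallest label
  })
  expect_identical(as.vector(down$data), as.integer(expected))
})

test_that("downsampling to a finer grid is rejected", {
  g <- mini_grid()
  ph <- build_density_phantom(mini_layout(), g)
  expect_error(downsample_labels(ph, voxel_grid(c(100, 100, 10), c(1, 1, 1))),
               "coarse")
})

test_that("label substitution produces the theoretical mu-map", {
  g <- mini_grid()
  reg <- material_registry()
  ph <- build_density_phantom(mini_layout(), g)
  mu <- labels_to_mu(ph, reg)
  expect_equal(length(unique(as.vector(mu$data))),
               length(unique(as.vector(ph$data))))
  pw <- linear_attenuation(reg$plastic_water, 208.4)
  expect_true(all(mu$data[ph$data == 1L] == pw))
  air_only <- label_volume(array(0L, g$dim), g,
                           tibble::tibble(label = 0L, material = "air"))
  expect_lt(max(labels_to_mu(air_only, reg)$data), 2e-4)
})

test_that("unresolvable materials are reported by name", {
  g <- mini_grid()
  lv <- label_volume(array(1L, g$dim), g,
                     tibble::tibble(label = 1L, material = "kryptonite"))
  expect_error(labels_to_mu(lv), "kryptonite")
})
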