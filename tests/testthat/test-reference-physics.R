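test_that("interpolation reproduces tabulated values exactly at grid energies", {
  tab <- attenuation_tables()
  for (el in c("H", "O", "Ca")) {
    rows <- tab[tab$element == el, ]
    expect_identical(lookup_mass_attenuation(el, rows$energy_keV),
                     rows$mu_over_rho_cm2_g)
  }
})

test_that("log-log interpolation matches an independent hand evaluation", {
  tab <- attenuation_tables()
  h <- tab[tab$element == "H", ]
  # bracketing points around 250 keV
  lo <- h[h$energy_keV == 200, ]; hi <- h[h$energy_keV == 300, ]
  byhand <- exp(log(lo$mu_over_rho_cm2_g) +
                  (log(hi$mu_over_rho_cm2_g) - log(lo$mu_over_rho_cm2_g)) *
                  log(250 / 200) / log(300 / 200))
  expect_equal(lookup_mass_attenuation("H", 250), byhand, tolerance = 1e-12)
})

test_that("Compton-dominated values decrease monotonically through 208.4 keV", {
  v <- lookup_mass_attenuation("O", c(200, 208.4, 300))
  expect_true(v[2] < v[1] && v[2] > v[3])
})

test_that("unknown elements and out-of-grid energies are rejected", {
  expect_error(lookup_mass_attenuation("Xx", 200), "not found")
  expect_error(lookup_mass_attenuation("O", 30), "outside")
  expect_error(lookup_mass_attenuation("O", 500), "outside")
})

test_that("mixture rule reduces to the element for a pure material", {
  m <- material("pure_oxygen", 1.14, c(O = 1))
  expect_identical(mixture_mass_attenuation(m, 180),
                   lookup_mass_attenuation("O", 180))
})

test_that("water mixture matches a brute-force two-element summation", {
  w <- material("w", 1, c(H = 0.1119, O = 0.8881))
  oracle <- 0.1119 * lookup_mass_attenuation("H", 208.4) +
            0.8881 * lookup_mass_attenuation("O", 208.4)
  expect_equal(mixture_mass_attenuation(w, 208.4), oracle, tolerance = 1e-15)
})

test_that("mixture value lies within the elemental convex hull", {
  reg <- material_registry()
  for (m in reg[c("muscle", "ptfe", "bone_ha1250")]) {
    els <- vapply(names(m$mass_fractions), lookup_mass_attenuation,
                  numeric(1), energy_keV = 208.4)
    v <- mixture_mass_attenuation(m, 208.4)
    expect_gte(v, min(els)); expect_lte(v, max(els))
  }
})

test_that("linear attenuation is homogeneous of degree 1 in density", {
  w1 <- material("a", 0.5, c(H = 0.1119, O = 0.8881))
  w2 <- material("b", 1.0, c(H = 0.1119, O = 0.8881))
  w0 <- material("c", 0.0, c(H = 0.1119, O = 0.8881))
  expect_equal(2 * linear_attenuation(w1, 208.4), linear_attenuation(w2, 208.4))
  expect_identical(linear_attenuation(w0, 208.4), 0)
})

test_that("material validation catches bad compositions", {
  expect_error(material("bad", 1, c(H = 0.5, O = 0.4)), "sum")
  expect_error(material("bad", -1, c(O = 1)), "density")
  expect_error(material("bad", 1, c(Xx = 1)), "missing")
})

test_that("theoretical mu table covers the full 19-segment phantom", {
  reg <- material_registry()
  legend <- build_density_phantom(default_density_layout(),
                                  mini_grid(4))$legend
  segs <- lapply(seq_len(nrow(legend)), function(i) {
    base <- reg[[legend$material[i]]]
    material(legend$segment[i], base$density_g_cm3, base$mass_fractions)
  })
  tab <- theoretical_mu_table(segs)
  expect_equal(nrow(tab), 19L)
  expect_lt(tab$mu_cm1[tab$material == "air"], 2e-4)  # computed, not asserted 0
  expect_gt(tab$mu_cm1[tab$material == "air"], 0)
})

test_that("theoretical mu table rejects empty and duplicated inputs", {
  reg <- material_registry()
  expect_error(theoretical_mu_table(list()), "empty")
  expect_error(theoretical_mu_table(list(reg$water, reg$water)), "duplicate")
  one <- theoretical_mu_table(list(reg$liver))
  expect_equal(one$mu_cm1, linear_attenuation(reg$liver, 208.4))
})

test_that("soft tissues sit in the Compton-regime mass-attenuation band", {
  reg <- material_registry()
  soft <- c("lung_inhale", "lung_exhale", "adipose", "breast", "muscle",
            "liver", "plastic_water", "water")
  for (m in soft) {
    v <- mixture_mass_attenuation(reg[[m]], 208.4)
    expect_gt(v, 0.12); expect_lt(v, 0.15)
  }
})
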