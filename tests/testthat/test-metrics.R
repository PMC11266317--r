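test_that("VOI means honour the box contract", {
  g <- voxel_grid(c(12, 12, 12), 4)
  vol <- mu_volume(array(0.3, g$dim), g)
  expect_equal(voi_mean(vol, box_voi(c(2, 2, 2), c(3, 3, 8))), 0.3)

  # checkerboard averages to the midpoint over an even box
  chk <- array(0, g$dim)
  chk[] <- (outer(outer(1:12, 1:12, "+"), 1:12, "+") %% 2) * 2 + 1  # 1 or 3
  vol2 <- mu_volume(chk, g)
  expect_equal(voi_mean(vol2, box_voi(c(1, 1, 1), c(4, 4, 4))), 2)

  # the study VOI really covers 72 voxels
  ind <- array(0, g$dim)
  ind[3:5, 3:5, 2:9] <- 1
  vol3 <- mu_volume(ind, g)
  expect_equal(voi_mean(vol3, box_voi(c(3, 3, 2), c(3, 3, 8))), 1)
  expect_equal(sum(ind), 72)

  expect_error(voi_mean(vol, box_voi(c(11, 11, 11), c(3, 3, 8))), "outside")
})

test_that("relative error is a plain percent difference", {
  expect_equal(relative_error(5, 5), 0)
  expect_equal(relative_error(1.18 * 0.027, 0.027), 18)
  expect_equal(relative_error(0.027 * 1.32, 0.027), 32)
  expect_error(relative_error(1, 0), "nonzero")
})

test_that("ring averaging handles the single-ring insert", {
  r <- inner_outer_mean(c(0.026, 0.2, NA), c(0.028, NA, 0.1))
  expect_equal(r$mu_mean, c(0.027, 0.2, 0.1))
  expect_equal(r$single_ring, c(FALSE, TRUE, TRUE))
  expect_equal(inner_outer_mean(0.05, 0.05)$mu_mean, 0.05)
  expect_error(inner_outer_mean(NA, NA), "missing")
})

test_that("the COV chain is zero for identical repetitions and exact on offsets", {
  g <- voxel_grid(c(12, 12, 12), 4.8)
  vois <- list(box_voi(c(1, 1, 1), 10), box_voi(c(3, 3, 3), 10))
  base <- 0.1355
  same <- lapply(1:10, function(j) mu_volume(array(base, g$dim), g))
  expect_equal(cov_chain(same, vois)$cov, 0)

  set.seed(9)
  eps <- stats::rnorm(10, 0, 4e-4)
  reps <- lapply(eps, function(e) mu_volume(array(base + e, g$dim), g))
  na <- cov_chain(reps, vois)
  expect_equal(na$cov, stats::sd(base + eps) / mean(base + eps), tolerance = 1e-12)
  expect_equal(na$mu_mean, mean(base + eps), tolerance = 1e-12)
  expect_equal(nrow(tidy(na)), 10)
  expect_equal(glance(na)$n_vois, 2)

  expect_error(cov_chain(same[1], vois), "two repetitions")
  expect_error(cov_chain(same, list()), "VOI")
})

test_that("a constant shift moves mean and COV consistently", {
  g <- voxel_grid(c(6, 6, 6), 4.8)
  set.seed(10)
  eps <- stats::rnorm(10, 0, 3e-4)
  voi <- list(box_voi(c(1, 1, 1), 6))
  reps0 <- lapply(eps, function(e) mu_volume(array(0.1 + e, g$dim), g))
  reps1 <- lapply(eps, function(e) mu_volume(array(0.15 + e, g$dim), g))
  a <- cov_chain(reps0, voi); b <- cov_chain(reps1, voi)
  expect_equal(a$mu_sd, b$mu_sd, tolerance = 1e-12)
  expect_equal(b$cov, a$cov * a$mu_mean / b$mu_mean, tolerance = 1e-12)
})

test_that("group comparison gates on normality and finds what it should", {
  set.seed(1)
  x <- stats::rnorm(20)
  same <- compare_groups(list(a = x, b = x))
  expect_equal(tidy(same)$p_value, 1, tolerance = 1e-9)
  expect_true(tidy(same)$parametric)
  expect_equal(tidy(same)$test, "unpaired t-test")

  shifted <- compare_groups(list(a = x, b = x + 5))
  expect_lt(tidy(shifted)$p_value, 1e-6)

  set.seed(3)
  heavy <- list(a = stats::rcauchy(30), b = stats::rcauchy(30))
  rep <- compare_groups(heavy)
  expect_false(tidy(rep)$parametric)
  expect_equal(tidy(rep)$test, "Mann-Whitney U")

  three <- compare_groups(list(a = x, b = x + 0.1, c = x - 0.1))
  expect_equal(tidy(three)$test, "one-way ANOVA")

  expect_error(compare_groups(list(a = 1:2, b = 1:5)), "n >= 3")
  df <- data.frame(value = c(x, x + 5), group = rep(c("a", "b"), each = 20))
  expect_lt(tidy(compare_groups(df))$p_value, 1e-6)
})

test_that("activity change and relative error agree on ACF scalars", {
  th <- 6.1; ms <- 6.7
  expect_equal(delta_activity(th, ms), relative_error(th, ms))
})
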