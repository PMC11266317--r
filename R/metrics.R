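#' Box volume of interest
#'
#' A box VOI anchored at a voxel index with a per-axis extent. The study uses
#' 3 x 3 x 8-voxel VOIs (72 voxels) for insert attenuation readout and
#' 10 x 10 x 10-voxel VOIs (1000 voxels) for the noise analysis.
#'
#' @param anchor Integer voxel index (1-based) of the VOI corner.
#' @param extent Integer extent in voxels per axis.
#' @return An object of class `box_voi`.
#' @export
box_voi <- function(anchor, extent) {
  anchor <- as.integer(rep_len(anchor, 3))
  extent <- as.integer(rep_len(extent, 3))
  if (any(extent < 1)) stop("extent must be >= 1", call. = FALSE)
  structure(list(anchor = anchor, extent = extent), class = "box_voi")
}

#' @rdname box_voi
#' @param grid A [voxel_grid()].
#' @param center_mm World position (mm) on which to centre the VOI.
#' @export
centered_voi <- function(grid, center_mm, extent) {
  extent <- as.integer(rep_len(extent, 3))
  ctr <- round((center_mm - grid$origin) / grid$spacing) + 1
  box_voi(as.integer(ctr) - extent %/% 2, extent)
}

voi_values <- function(vol, voi) {
  stopifnot(inherits(vol, "vox_volume"), inherits(voi, "box_voi"))
  hi <- voi$anchor + voi$extent - 1L
  if (any(voi$anchor < 1L) || any(hi > vol$grid$dim)) {
    stop("VOI extends outside the grid", call. = FALSE)
  }
  vol$data[voi$anchor[1]:hi[1], voi$anchor[2]:hi[2], voi$anchor[3]:hi[3]]
}

#' Mean over a box VOI
#'
#' @param vol A `vox_volume`.
#' @param voi A [box_voi()] fully inside the grid.
#' @return Arithmetic mean of the VOI voxels.
#' @export
voi_mean <- function(vol, voi) mean(voi_values(vol, voi))

#' Relative error in percent
#'
#' `(measured - theoretical) / theoretical * 100`, vectorised.
#'
#' @param measured,theoretical Numeric; `theoretical` must be nonzero.
#' @return Percent error.
#' @export
relative_error <- function(measured, theoretical) {
  if (any(theoretical == 0)) stop("theoretical value must be nonzero", call. = FALSE)
  (measured - theoretical) / theoretical * 100
}

#' Inner/outer ring mean of an insert readout
#'
#' Averages the inner-ring and outer-ring measured attenuation of an insert;
#' when a material is present in only one ring (the densest bone insert), the
#' available ring value is returned with `single_ring = TRUE`.
#'
#' @param inner,outer Ring means (cm^-1); exactly one may be `NA`.
#' @return A tibble with columns `mu_mean` and `single_ring`.
#' @export
inner_outer_mean <- function(inner, outer) {
  if (length(inner) != length(outer)) stop("length mismatch", call. = FALSE)
  both_missing <- is.na(inner) & is.na(outer)
  if (any(both_missing)) stop("both ring values missing", call. = FALSE)
  single <- xor(is.na(inner), is.na(outer))
  mu <- ifelse(single, dplyr::coalesce(inner, outer), (inner + outer) / 2)
  tibble::tibble(mu_mean = mu, single_ring = single)
}

#' Coefficient-of-variation noise chain
#'
#' The four-step noise statistic of the mu-map analysis: for each repetition
#' `j`, the mean over the VOI means of the (by default eight 1000-voxel) VOIs
#' in the homogeneous plastic-water section; then the grand mean over the (by
#' default ten) repetitions; the sample standard deviation with divisor
#' `n - 1`; and `COV = SD / mean`.
#'
#' @param mu_maps List of [mu_volume()]s, one per repetition (>= 2).
#' @param vois List of [box_voi()]s (>= 1) positioned in the homogeneous
#'   section.
#' @return An object of class `noise_analysis` with fields `rep_means`
#'   (tibble: `repetition`, `mu_mean`), `mu_mean`, `mu_sd`, `cov`,
#'   `n_repetitions`, `n_vois`.
#' @export
cov_chain <- function(mu_maps, vois) {
  if (length(mu_maps) < 2) {
    stop("at least two repetitions are required (SD undefined otherwise)",
         call. = FALSE)
  }
  if (length(vois) < 1) stop("at least one VOI is required", call. = FALSE)
  rep_means <- vapply(mu_maps, function(m) {
    mean(vapply(vois, function(v) voi_mean(m, v), numeric(1)))
  }, numeric(1))
  grand <- mean(rep_means)
  sdev <- stats::sd(rep_means)
  structure(list(
    rep_means = tibble::tibble(repetition = seq_along(rep_means),
                               mu_mean = rep_means),
    mu_mean = grand, mu_sd = sdev, cov = sdev / grand,
    n_repetitions = length(mu_maps), n_vois = length(vois)
  ), class = "noise_analysis")
}

#' @export
print.noise_analysis <- function(x, ...) {
  cat(sprintf(
    "<noise_analysis> %d repetitions x %d VOIs: mu = %.4f cm^-1, SD = %.2e, COV = %.2e\n",
    x$n_repetitions, x$n_vois, x$mu_mean, x$mu_sd, x$cov))
  invisible(x)
}

#' Normality-gated group comparison
#'
#' The statistical procedure of the study: Shapiro-Wilk normality per group at
#' alpha = 0.05; if every group is compatible with normality, a parametric
#' location test is used (Welch unpaired t-test for two groups, one-way ANOVA
#' for more), otherwise the rank-based analogue (Mann-Whitney / Kruskal-Wallis).
#'
#' @param data A data frame with a numeric `value` column and a `group` column,
#'   or a named list of numeric vectors. Every group needs n >= 3.
#' @param alpha Significance level of the normality gate.
#' @return An object of class `stats_report`: a list with `test` (tibble with
#'   `test`, `statistic`, `p_value`, `parametric`) and `normality` (tibble with
#'   per-group Shapiro-Wilk results).
#' @export
compare_groups <- function(data, alpha = 0.05) {
  if (is.data.frame(data)) {
    stopifnot(all(c("value", "group") %in% names(data)))
    groups <- split(data$value, data$group)
  } else {
    groups <- data
  }
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  n <- vapply(groups, length, integer(1))
  if (any(n < 3)) stop("every group needs n >= 3", call. = FALSE)
  sw <- purrr::map_dfr(names(groups), function(g) {
    x <- groups[[g]]
    if (stats::sd(x) == 0) {  # degenerate: Shapiro undefined on constants
      return(tibble::tibble(group = g, W = NA_real_, p_value = 0, normal = FALSE))
    }
    s <- stats::shapiro.test(x)
    tibble::tibble(group = g, W = unname(s$statistic), p_value = s$p.value,
                   normal = s$p.value > alpha)
  })
  parametric <- all(sw$normal)
  two <- length(groups) == 2
  if (parametric && two) {
    t <- stats::t.test(groups[[1]], groups[[2]])
    res <- tibble::tibble(test = "unpaired t-test",
                          statistic = unname(t$statistic), p_value = t$p.value)
  } else if (parametric) {
    df <- data.frame(value = unlist(groups),
                     group = rep(names(groups), times = n))
    a <- summary(stats::aov(value ~ group, data = df))[[1]]
    res <- tibble::tibble(test = "one-way ANOVA", statistic = a$`F value`[1],
                          p_value = a$`Pr(>F)`[1])
  } else if (two) {
    w <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]]))
    res <- tibble::tibble(test = "Mann-Whitney U",
                          statistic = unname(w$statistic), p_value = w$p.value)
  } else {
    df <- data.frame(value = unlist(groups),
                     group = rep(names(groups), times = n))
    k <- stats::kruskal.test(value ~ group, data = df)
    res <- tibble::tibble(test = "Kruskal-Wallis",
                          statistic = unname(k$statistic), p_value = k$p.value)
  }
  res$parametric <- parametric
  structure(list(test = res, normality = sw), class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("<stats_report> %s: statistic = %.3f, p = %.3g (%s branch)\n",
              x$test$test, x$test$statistic, x$test$p_value,
              if (x$test$parametric) "parametric" else "nonparametric"))
  invisible(x)
}
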