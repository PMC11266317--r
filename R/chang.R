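#' Attenuation path integral along a ray
#'
#' Integrates the attenuation coefficient from a world point to the volume
#' boundary along a direction, by fixed-step sampling (step = half the smallest
#' voxel spacing) with trilinear lookup and trapezoid accumulation. Attenuation
#' outside the volume is zero. Lengths are converted from mm to cm so the
#' result is the dimensionless optical path `integral of mu dl`.
#'
#' @param mu A [mu_volume()].
#' @param point World position in mm (length 3).
#' @param direction Direction vector (length 3); normalised internally, must be
#'   nonzero.
#' @param step_mm Sampling step; default half the smallest voxel spacing.
#' @return The dimensionless path integral.
#' @export
#' @examples
#' g <- voxel_grid(c(11, 11, 3), c(10, 10, 10))
#' mu <- mu_volume(array(0.1355, g$dim), g)
#' ray_path_integral(mu, c(0, 0, 0), c(1, 0, 0))  # 0.1355 * 5 cm
ray_path_integral <- function(mu, point, direction,
                              step_mm = min(mu$grid$spacing) / 2) {
  stopifnot(inherits(mu, "mu_volume"))
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction vector must be nonzero", call. = FALSE)
  d <- direction / nrm
  g <- mu$grid
  lo <- g$origin; hi <- g$origin + (g$dim - 1) * g$spacing
  if (any(point < lo - 1e-9) || any(point > hi + 1e-9)) {
    stop("point must lie inside the grid", call. = FALSE)
  }
  # exit distance from the voxel-centre bounding box
  tmax <- min(ifelse(abs(d) > 1e-12,
                     pmax((lo - point) / d, (hi - point) / d), Inf))
  n <- max(1L, ceiling(tmax / step_mm))
  t <- seq(0, tmax, length.out = n + 1)
  pts <- cbind(point[1] + t * d[1], point[2] + t * d[2], point[3] + t * d[3])
  v <- interp_trilinear(mu, pts)
  dt <- t[2] - t[1]
  sum((v[-1] + v[-length(v)]) / 2) * dt / 10  # mm -> cm
}

#' First-order Chang attenuation-correction-factor image
#'
#' For each voxel the attenuation correction factor is the inverse of the mean
#' survival over `M` equally spaced in-plane directions:
#' `ACF = 1 / mean_m exp(-path_m)` with `path_m` the attenuation path integral
#' from the voxel to the body surface along direction `m`. This is the one-shot
#' (non-iterative) Chang correction, evaluated here as an analysis image rather
#' than as a reconstruction step. Paths are sampled with a fixed step of half
#' the smallest in-plane spacing and trapezoid accumulation; halving the step
#' roughly halves the discretisation error.
#'
#' @param mu A [mu_volume()].
#' @param M Number of in-plane directions (>= 1; 64 by default).
#' @param mask Optional logical array (same dim as `mu`): compute the ACF only
#'   at `TRUE` voxels (others are set to 1). Saves time when only VOIs matter.
#' @param provenance Provenance tag for the result.
#' @param step_mm Ray sampling step.
#' @return An [acf_volume()].
#' @export
chang_acf_volume <- function(mu, M = 64, mask = NULL,
                             provenance = c("theoretical", "measured"),
                             step_mm = min(mu$grid$spacing[1:2]) / 2) {
  stopifnot(inherits(mu, "mu_volume"))
  provenance <- match.arg(provenance)
  M <- as.integer(M)
  if (M < 1) stop("M must be >= 1", call. = FALSE)
  g <- mu$grid
  xs <- axis_coords(g, 1); ys <- axis_coords(g, 2)
  lo <- g$origin[1:2]; hi <- g$origin[1:2] + (g$dim[1:2] - 1) * g$spacing[1:2]
  angles <- 2 * pi * (seq_len(M) - 1) / M
  acf <- array(1, g$dim)
  nxy <- g$dim[1] * g$dim[2]

  for (k in seq_len(g$dim[3])) {
    sl <- matrix(mu$data[, , k], g$dim[1], g$dim[2])
    if (all(sl == 0)) next
    if (is.null(mask)) {
      sel <- rep(TRUE, nxy)
    } else {
      sel <- as.vector(mask[, , k])
      if (!any(sel)) next
    }
    px <- rep(xs, times = g$dim[2])[sel]
    py <- rep(ys, each = g$dim[1])[sel]
    surv <- numeric(sum(sel))
    for (th in angles) {
      dx <- cos(th); dy <- sin(th)
      tx <- if (abs(dx) > 1e-12) pmax((lo[1] - px) / dx, (hi[1] - px) / dx) else Inf
      ty <- if (abs(dy) > 1e-12) pmax((lo[2] - py) / dy, (hi[2] - py) / dy) else Inf
      texit <- pmin(tx, ty)
      nstep <- max(1L, ceiling(max(texit) / step_mm))
      dt <- max(texit) / nstep
      path <- numeric(length(px))
      prev <- bilinear_slice(sl, g, px, py)
      for (s in seq_len(nstep)) {
        t <- s * dt
        cur <- bilinear_slice(sl, g, px + t * dx, py + t * dy)
        path <- path + (prev + cur) / 2 * dt
        prev <- cur
      }
      surv <- surv + exp(-path / 10)
    }
    a <- rep(1, nxy)
    a[sel] <- M / surv
    acf[, , k] <- a
  }
  acf_volume(acf, g, angles = M, provenance = provenance)
}

# 2-D bilinear sample of one slice at in-plane world coordinates (outside -> 0)
bilinear_slice <- function(sl, g, px, py) {
  ix <- (px - g$origin[1]) / g$spacing[1] + 1
  iy <- (py - g$origin[2]) / g$spacing[2] + 1
  n <- length(px)
  inside <- ix >= 1 & ix <= g$dim[1] & iy >= 1 & iy <= g$dim[2]
  out <- numeric(n)
  if (!any(inside)) return(out)
  ix <- ix[inside]; iy <- iy[inside]
  i0 <- pmin(pmax(floor(ix), 1), g$dim[1] - 1); fx <- ix - i0
  j0 <- pmin(pmax(floor(iy), 1), g$dim[2] - 1); fy <- iy - j0
  i1 <- i0 + 1; j1 <- j0 + 1
  nx <- g$dim[1]
  out[inside] <-
    sl[i0 + (j0 - 1) * nx] * (1 - fx) * (1 - fy) +
    sl[i1 + (j0 - 1) * nx] * fx * (1 - fy) +
    sl[i0 + (j1 - 1) * nx] * (1 - fx) * fy +
    sl[i1 + (j1 - 1) * nx] * fx * fy
  out
}

#' Expected change in activity quantification from two ACFs
#'
#' `Delta A [%] = (ACF_theoretical / ACF_measured - 1) * 100`, evaluated
#' elementwise on volumes, vectors or scalars (typically on VOI means of the
#' theoretical and measured ACF images).
#'
#' @param acf_theoretical,acf_measured Numeric scalars/vectors or
#'   [acf_volume()]s of the same shape. `acf_measured` must be strictly
#'   positive.
#' @return Percent change, same shape as the inputs.
#' @export
#' @examples
#' delta_activity(8.7, 8.7 / 0.965)  # -3.5
delta_activity <- function(acf_theoretical, acf_measured) {
  a <- if (inherits(acf_theoretical, "vox_volume")) acf_theoretical$data else acf_theoretical
  b <- if (inherits(acf_measured, "vox_volume")) acf_measured$data else acf_measured
  if (any(b <= 0)) stop("ACF_measured must be strictly positive", call. = FALSE)
  (a / b - 1) * 100
}
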