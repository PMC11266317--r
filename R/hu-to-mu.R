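#' Bilinear HU-to-mu conversion model
#'
#' The standard CT-AC conversion: below the water breakpoint (HU = 0) the
#' attenuation coefficient scales linearly between air (-1000 HU, mu = 0) and
#' water; above it a per-kVp bone slope applies. The bone slopes are calibrated
#' in-repo from two materials (water and a cortical-bone-like calibration
#' material) at each tube voltage's effective energy: the calibration point is
#' the bone material's ideal HU at the effective CT energy paired with its
#' attenuation at the target energy, so
#' `slope(kVp) = (mu_bone(E_target) - mu_water(E_target)) / HU_bone(E_eff)`.
#'
#' @param target_energy_keV Emission energy of the mu-map (208.4 keV default).
#' @param kvps Tube voltages to calibrate bone slopes for.
#' @param registry Material registry providing `water` and the calibration
#'   material.
#' @param bone_material Name of the cortical-bone-like calibration material.
#' @param tables Attenuation table.
#' @return An object of class `bilinear_model` with fields `mu_water` (cm^-1 at
#'   the target energy), `soft_slope` (cm^-1 per HU), `bone_slope` (named by
#'   kVp), `breakpoint` (0 HU) and `energy_keV`.
#' @export
bilinear_model <- function(target_energy_keV = 208.4,
                           kvps = c(80, 110, 130),
                           registry = material_registry(),
                           bone_material = "cortical_bone",
                           tables = attenuation_tables()) {
  mu_w <- linear_attenuation(registry$water, target_energy_keV, tables)
  mu_b <- linear_attenuation(registry[[bone_material]], target_energy_keV, tables)
  slopes <- vapply(kvps, function(kvp) {
    e <- effective_energy(kvp)
    mu_w_e <- linear_attenuation(registry$water, e, tables)
    mu_b_e <- linear_attenuation(registry[[bone_material]], e, tables)
    hu_bone <- 1000 * (mu_b_e - mu_w_e) / mu_w_e
    (mu_b - mu_w) / hu_bone
  }, numeric(1))
  if (any(slopes <= 0)) stop("bone slope calibration failed (slope <= 0)")
  structure(list(mu_water = mu_w, soft_slope = mu_w / 1000,
                 bone_slope = stats::setNames(slopes, kvps),
                 breakpoint = 0, energy_keV = target_energy_keV),
            class = "bilinear_model")
}

#' @export
print.bilinear_model <- function(x, ...) {
  cat(sprintf("<bilinear_model> mu_water = %.4f cm^-1 at %.1f keV; bone slopes: %s\n",
              x$mu_water, x$energy_keV,
              paste(sprintf("%s kVp: %.3e", names(x$bone_slope), x$bone_slope),
                    collapse = ", ")))
  invisible(x)
}

#' Convert a HU volume to a mu-map
#'
#' Piecewise-linear conversion with breakpoint at HU = 0: below,
#' `mu = mu_water (HU + 1000) / 1000` clipped at zero; above,
#' `mu = mu_water + HU * bone_slope(kVp)`. The output is tagged with the
#' model's target energy (208.4 keV by default).
#'
#' @param hu An [hu_volume()].
#' @param model A [bilinear_model()].
#' @param kvp Tube voltage selecting the bone slope.
#' @return A [mu_volume()].
#' @export
hu_to_mu <- function(hu, model = bilinear_model(), kvp = 130) {
  stopifnot(inherits(hu, "hu_volume"), inherits(model, "bilinear_model"))
  slope <- model$bone_slope[as.character(kvp)]
  if (is.na(slope)) {
    stop("no bone slope calibrated for kVp = ", kvp, call. = FALSE)
  }
  h <- hu$data
  mu <- ifelse(h <= model$breakpoint,
               pmax(model$mu_water * (h + 1000) / 1000, 0),
               model$mu_water + h * slope)
  mu_volume(array(mu, hu$grid$dim), hu$grid, energy_keV = model$energy_keV)
}

#' Resample a mu-map to another grid
#'
#' Values-based trilinear resampling at the target voxel centres, matching the
#' smoothing behaviour of scanner CT-to-mu-map chains (as opposed to
#' label-majority resampling of segmentations). The target grid must lie within
#' the source extent.
#'
#' @param mu A [mu_volume()].
#' @param target A [voxel_grid()].
#' @param outside `"error"` requires the target to lie within the source
#'   extent; `"zero"` fills target voxels outside the source field of view
#'   with 0 (air), which matches a SPECT field of view larger than the CT one.
#' @return A [mu_volume()] on `target`.
#' @export
resample_mu <- function(mu, target, outside = c("error", "zero")) {
  stopifnot(inherits(mu, "mu_volume"), inherits(target, "voxel_grid"))
  outside <- match.arg(outside)
  if (grid_equal(mu$grid, target)) {
    return(mu_volume(mu$data, target, energy_keV = mu$energy_keV))
  }
  g <- mu$grid
  lo_t <- target$origin; hi_t <- target$origin + (target$dim - 1) * target$spacing
  lo_s <- g$origin - g$spacing / 2
  hi_s <- g$origin + (g$dim - 1) * g$spacing + g$spacing / 2
  if (outside == "error" &&
      (any(lo_t < lo_s - 1e-9) || any(hi_t > hi_s + 1e-9))) {
    stop("target grid extends outside the source extent", call. = FALSE)
  }
  pts <- as.matrix(expand.grid(x = axis_coords(target, 1),
                               y = axis_coords(target, 2),
                               z = axis_coords(target, 3)))
  idx <- world_to_index(g, pts)
  in_fov <- idx[, 1] >= 0.5 & idx[, 1] <= g$dim[1] + 0.5 &
            idx[, 2] >= 0.5 & idx[, 2] <= g$dim[2] + 0.5 &
            idx[, 3] >= 0.5 & idx[, 3] <= g$dim[3] + 0.5
  # clamp the outer half-voxel band onto the boundary voxel centres
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 1), g$dim[a])
  vals <- interp_trilinear_idx(mu$data, g$dim, idx)
  vals[!in_fov] <- 0
  mu_volume(array(vals, target$dim), target, energy_keV = mu$energy_keV)
}
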