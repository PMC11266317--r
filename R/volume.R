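#' Voxel grid geometry
#'
#' A voxel grid describes a regular 3-D lattice in a right-handed world frame:
#' axial slices lie in the xy plane, and `origin` is the world position (mm) of
#' the centre of the first voxel. Voxel `(i, j, k)` (1-based) has its centre at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param dim Integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing Numeric vector of length 3, voxel size in mm (all > 0).
#' @param origin World position (mm) of the centre of voxel (1, 1, 1). The
#'   default `"centered"` centres the grid on the world origin.
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' voxel_grid(c(128, 128, 55), spacing = 4.8)
voxel_grid <- function(dim, spacing, origin = "centered") {
  dim <- as.integer(rep_len(dim, 3L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(dim < 1L)) stop("all grid dimensions must be >= 1", call. = FALSE)
  if (any(spacing <= 0)) stop("all voxel spacings must be > 0", call. = FALSE)
  if (identical(origin, "centered")) {
    origin <- -(dim - 1L) / 2 * spacing
  }
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(dim = dim, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels @ %s mm, origin (%s) mm\n",
              paste(x$dim, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
format.voxel_grid <- function(x, ...) {
  sprintf("%s @ %s mm", paste(x$dim, collapse = "x"),
          paste(signif(x$spacing, 4), collapse = "x"))
}

grid_equal <- function(a, b, tol = 1e-9) {
  identical(a$dim, b$dim) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' World coordinates of voxel centres along one axis
#' @param grid A [voxel_grid()].
#' @param axis Axis index 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of world coordinates in mm.
#' @export
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dim[axis]) - 1) * grid$spacing[axis]
}

#' Voxel volume of a grid in millilitres
#' @param grid A [voxel_grid()].
#' @return Voxel volume in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(grid) prod(grid$spacing) / 1000

# continuous (1-based, fractional) voxel index of world points; pts is n x 3
world_to_index <- function(grid, pts) {
  pts <- matrix(pts, ncol = 3)
  sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/") + 1
}

new_volume <- function(data, grid, kind, ...) {
  stopifnot(inherits(grid, "voxel_grid"))
  data <- array(data, dim = grid$dim)
  structure(list(data = data, grid = grid, kind = kind, ...),
            class = c(paste0(kind, "_volume"), "vox_volume"))
}

#' Voxel volume constructors
#'
#' Thin containers pairing a numeric array with its [voxel_grid()] geometry.
#' `label_volume()` carries an integer segmentation and a legend mapping label
#' ids to material names; `hu_volume()` carries Hounsfield units;
#' `mu_volume()` carries linear attenuation coefficients (cm^-1) at a recorded
#' reference energy; `acf_volume()` carries dimensionless Chang attenuation
#' correction factors; `activity_volume()` carries activity concentration in
#' MBq/mL together with the nominal activity of each source.
#'
#' @param data Numeric (or integer for labels) array matching `grid$dim`;
#'   scalars are recycled.
#' @param grid A [voxel_grid()].
#' @param legend Tibble with columns `label`, `material` (and optionally
#'   `segment`); label 0 is reserved for air.
#' @param energy_keV Reference photon energy of a mu-map (208.4 keV default,
#'   the principal 177Lu gamma emission).
#' @param angles Number of in-plane directions used to compute an ACF volume.
#' @param provenance `"theoretical"` or `"measured"`.
#' @param nominal_MBq Named numeric vector of nominal source activities.
#' @return An object of class `vox_volume` with kind-specific subclass.
#' @name volumes
NULL

#' @rdname volumes
#' @export
label_volume <- function(data, grid, legend) {
  stopifnot(is.data.frame(legend), all(c("label", "material") %in% names(legend)))
  v <- new_volume(as.integer(data), grid, "label", legend = tibble::as_tibble(legend))
  present <- sort(unique(as.vector(v$data)))
  if (!all(present %in% legend$label)) {
    stop("labels present in volume but missing from legend: ",
         paste(setdiff(present, legend$label), collapse = ", "), call. = FALSE)
  }
  v
}

#' @rdname volumes
#' @export
hu_volume <- function(data, grid) {
  v <- new_volume(data, grid, "hu")
  if (any(v$data < -1024)) stop("HU values below -1024 are not allowed", call. = FALSE)
  v
}

#' @rdname volumes
#' @export
mu_volume <- function(data, grid, energy_keV = 208.4) {
  if (any(data < 0)) stop("attenuation coefficients must be >= 0", call. = FALSE)
  new_volume(data, grid, "mu", energy_keV = energy_keV)
}

#' @rdname volumes
#' @export
acf_volume <- function(data, grid, angles,
                       provenance = c("theoretical", "measured")) {
  new_volume(data, grid, "acf", angles = as.integer(angles),
             provenance = match.arg(provenance))
}

#' @rdname volumes
#' @export
activity_volume <- function(data, grid, nominal_MBq = NULL) {
  if (any(data < 0)) stop("activity concentrations must be >= 0", call. = FALSE)
  new_volume(data, grid, "activity", nominal_MBq = nominal_MBq)
}

#' @export
print.vox_volume <- function(x, ...) {
  cat(sprintf("<%s_volume> %s; range [%s, %s]\n", x$kind, format(x$grid),
              signif(min(x$data), 4), signif(max(x$data), 4)))
  invisible(x)
}

#' Trilinear interpolation of a volume at world points
#'
#' Samples the volume at arbitrary world positions by trilinear interpolation
#' between the eight surrounding voxel centres. Points outside the bounding box
#' of voxel centres return `outside`.
#'
#' @param vol A `vox_volume` (any kind with numeric data).
#' @param pts An n x 3 matrix of world coordinates in mm.
#' @param outside Value returned outside the grid (default 0).
#' @return Numeric vector of length n.
#' @export
interp_trilinear <- function(vol, pts, outside = 0) {
  g <- vol$grid
  idx <- world_to_index(g, pts)
  interp_trilinear_idx(vol$data, g$dim, idx, outside)
}

# core: idx is fractional 1-based index, n x 3
interp_trilinear_idx <- function(arr, dim, idx, outside = 0) {
  n <- nrow(idx)
  inside <- idx[, 1] >= 1 & idx[, 1] <= dim[1] &
            idx[, 2] >= 1 & idx[, 2] <= dim[2] &
            idx[, 3] >= 1 & idx[, 3] <= dim[3]
  out <- rep(outside, n)
  if (!any(inside)) return(out)
  p <- idx[inside, , drop = FALSE]
  i0 <- pmin(pmax(floor(p[, 1]), 1), dim[1] - 1); fx <- p[, 1] - i0
  j0 <- pmin(pmax(floor(p[, 2]), 1), dim[2] - 1); fy <- p[, 2] - j0
  k0 <- pmin(pmax(floor(p[, 3]), 1), dim[3] - 1); fz <- p[, 3] - k0
  if (dim[1] == 1) { i0 <- rep(1, nrow(p)); fx <- rep(0, nrow(p)) }
  if (dim[2] == 1) { j0 <- rep(1, nrow(p)); fy <- rep(0, nrow(p)) }
  if (dim[3] == 1) { k0 <- rep(1, nrow(p)); fz <- rep(0, nrow(p)) }
  nx <- dim[1]; nxy <- dim[1] * dim[2]
  i1 <- pmin(i0 + 1, dim[1]); j1 <- pmin(j0 + 1, dim[2]); k1 <- pmin(k0 + 1, dim[3])
  b000 <- i0 + (j0 - 1) * nx + (k0 - 1) * nxy
  b100 <- i1 + (j0 - 1) * nx + (k0 - 1) * nxy
  b010 <- i0 + (j1 - 1) * nx + (k0 - 1) * nxy
  b110 <- i1 + (j1 - 1) * nx + (k0 - 1) * nxy
  b001 <- i0 + (j0 - 1) * nx + (k1 - 1) * nxy
  b101 <- i1 + (j0 - 1) * nx + (k1 - 1) * nxy
  b011 <- i0 + (j1 - 1) * nx + (k1 - 1) * nxy
  b111 <- i1 + (j1 - 1) * nx + (k1 - 1) * nxy
  v <- arr[b000] * (1 - fx) * (1 - fy) * (1 - fz) +
       arr[b100] * fx * (1 - fy) * (1 - fz) +
       arr[b010] * (1 - fx) * fy * (1 - fz) +
       arr[b110] * fx * fy * (1 - fz) +
       arr[b001] * (1 - fx) * (1 - fy) * fz +
       arr[b101] * fx * (1 - fy) * fz +
       arr[b011] * (1 - fx) * fy * fz +
       arr[b111] * fx * fy * fz
  out[inside] <- v
  out
}

#' Read and write volumes as NIfTI
#'
#' Volumes are stored as NIfTI-1 images with the grid spacing in `pixdim`.
#' The kind-specific metadata (legend, reference energy, ...) is not stored in
#' the NIfTI header and must be re-attached by the caller if needed.
#'
#' @param vol A `vox_volume`.
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @param kind Volume kind to construct on read (`"hu"`, `"mu"`, ...).
#' @param origin Grid origin to attach on read (NIfTI offsets are not
#'   round-tripped); default recentres the grid on the world origin.
#' @param ... Passed on to the kind constructor (e.g. `energy_keV`).
#' @return `read_volume()` returns a `vox_volume`; `write_volume()` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, kind = "mu", origin = "centered", ...) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  grid <- voxel_grid(dim(arr), RNifti::pixdim(img), origin = origin)
  constructor <- switch(kind,
    hu = hu_volume, mu = mu_volume, acf = acf_volume,
    activity = activity_volume,
    stop("unsupported kind: ", kind, call. = FALSE))
  constructor(arr, grid, ...)
}

#' Tidy a volume slice into a tibble
#'
#' @param x A `vox_volume`.
#' @param slice Axial slice index (default: middle slice).
#' @return A tibble with world coordinates `x`, `y`, `z` (mm) and `value`.
#' @export
slice_tibble <- function(x, slice = NULL) {
  g <- x$grid
  if (is.null(slice)) slice <- ceiling(g$dim[3] / 2)
  vals <- as.vector(x$data[, , slice])
  tibble::tibble(
    x = rep(axis_coords(g, 1), times = g$dim[2]),
    y = rep(axis_coords(g, 2), each = g$dim[1]),
    z = axis_coords(g, 3)[slice],
    value = vals
  )
}

#' Plot an axial slice of a volume
#'
#' @param object A `vox_volume`.
#' @param slice Axial slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vox_volume <- function(object, slice = NULL, ...) {
  df <- slice_tibble(object, slice)
  lab <- switch(object$kind, mu = "μ (cm⁻¹)", hu = "HU",
                acf = "ACF", label = "label", activity = "MBq/mL", "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("%s volume, z = %.1f mm", object$kind,
                                  df$z[1]))
}
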