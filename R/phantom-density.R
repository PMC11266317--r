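#' Electron-density phantom insert layout
#'
#' Geometry of the digital electron-density phantom: an elliptical plastic-water
#' body (half-axes 160 mm lateral and 130 mm anterior-posterior, matching the
#' 16 cm / 13 cm half-dimensions of the physical phantom) carrying cylindrical
#' tissue-equivalent inserts in an inner and an outer ring, plus an insert-free
#' homogeneous plastic-water section along z used for the noise analysis.
#' Insert coordinates are an emulation: the manufacturer does not publish them,
#' so the defaults place the 3-cm inserts on an inner circle of radius 60 mm
#' and on an ellipse 25 mm inside the body contour, all configurable.
#'
#' @param inserts A tibble with columns `material`, `x_mm`, `y_mm`, `r_mm`,
#'   `ring` (`"inner"`/`"outer"`).
#' @param body_half_axes_mm Half-axes (x lateral, y anterior-posterior) in mm.
#' @param body_z_mm Axial extent of the body, `c(min, max)` in mm.
#' @param insert_z_mm Axial extent of the inserts.
#' @param homogeneous_z_mm Axial extent of the insert-free plastic-water
#'   section.
#' @return An object of class `insert_layout`.
#' @export
insert_layout <- function(inserts,
                          body_half_axes_mm = c(160, 130),
                          body_z_mm = c(-120, 120),
                          insert_z_mm = c(25, 75),
                          homogeneous_z_mm = c(-120, -10)) {
  inserts <- tibble::as_tibble(inserts)
  a <- body_half_axes_mm[1]; b <- body_half_axes_mm[2]
  if (nrow(inserts) > 0) {
    outside <- (inserts$x_mm / (a - inserts$r_mm))^2 +
               (inserts$y_mm / (b - inserts$r_mm))^2 > 1
    if (any(outside)) {
      stop("inserts extend outside the body: rows ",
           paste(which(outside), collapse = ", "), call. = FALSE)
    }
    if (nrow(inserts) > 1) {
      d <- as.matrix(stats::dist(inserts[, c("x_mm", "y_mm")]))
      rsum <- outer(inserts$r_mm, inserts$r_mm, "+")
      diag(d) <- Inf
      if (any(d < rsum)) stop("overlapping inserts in layout", call. = FALSE)
    }
  }
  structure(list(inserts = inserts, body_half_axes_mm = body_half_axes_mm,
                 body_z_mm = body_z_mm, insert_z_mm = insert_z_mm,
                 homogeneous_z_mm = homogeneous_z_mm),
            class = "insert_layout")
}

#' @rdname insert_layout
#' @param insert_r_mm Insert radius in mm (3-cm diameter default).
#' @export
default_density_layout <- function(insert_r_mm = 15) {
  mats <- c("lung_inhale", "lung_exhale", "adipose", "breast", "muscle",
            "liver", "bone_ha200", "bone_ha800", "bone_ha1250")
  th_in <- 2 * pi * (seq_len(9) - 1) / 9
  inner <- tibble::tibble(material = mats,
                          x_mm = 60 * cos(th_in), y_mm = 60 * sin(th_in),
                          r_mm = insert_r_mm, ring = "inner")
  # outer positions follow the elliptical contour 25 mm inside the body;
  # the densest bone insert (1250 mg/cm3 HA) appears only once, in the inner ring
  th_out <- 2 * pi * (seq_len(8) - 1) / 8 + pi / 8
  outer <- tibble::tibble(material = mats[mats != "bone_ha1250"],
                          x_mm = 135 * cos(th_out), y_mm = 105 * sin(th_out),
                          r_mm = insert_r_mm, ring = "outer")
  insert_layout(dplyr::bind_rows(inner, outer))
}

#' Standard grids of the acquisition chain
#'
#' `ct_grid()` is the high-resolution CT grid (512 x 512 x 86 voxels at
#' 0.977 x 0.977 x 3 mm) and `spect_grid()` the SPECT / mu-map grid
#' (128 x 128 x 55 at 4.8 mm). `scale` shrinks the in-plane dimension while
#' enlarging spacing to keep the field of view, for scaled-down runs.
#'
#' @param scale Integer downscale factor for quick runs (1 = full size).
#' @return A [voxel_grid()].
#' @export
ct_grid <- function(scale = 1) {
  voxel_grid(c(512 / scale, 512 / scale, 86),
             c(0.977 * scale, 0.977 * scale, 3))
}

#' @rdname ct_grid
#' @export
spect_grid <- function(scale = 1) {
  voxel_grid(c(128 / scale, 128 / scale, 55),
             c(4.8 * scale, 4.8 * scale, 4.8))
}

#' Build the digital electron-density phantom
#'
#' Voxelises the layout on a grid by voxel-centre membership: a voxel belongs
#' to an insert if its centre lies inside the insert cylinder, else to the
#' plastic-water body if inside the elliptical body, else to air. Each insert
#' gets its own label, so the default 17-insert layout yields 19 segments
#' (17 inserts + plastic water + air). Deterministic: the same layout and grid
#' always produce bit-identical labels.
#'
#' @param layout An [insert_layout()].
#' @param grid A [voxel_grid()].
#' @return A [label_volume()] whose legend has columns `label`, `segment`,
#'   `material`, `ring`.
#' @export
build_density_phantom <- function(layout = default_density_layout(),
                                  grid = ct_grid()) {
  stopifnot(inherits(layout, "insert_layout"))
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  a <- layout$body_half_axes_mm[1]; b <- layout$body_half_axes_mm[2]
  X <- matrix(xs, nrow = grid$dim[1], ncol = grid$dim[2])
  Y <- matrix(ys, nrow = grid$dim[1], ncol = grid$dim[2], byrow = TRUE)
  body2d <- (X / a)^2 + (Y / b)^2 <= 1

  ins <- layout$inserts
  insert2d <- matrix(0L, grid$dim[1], grid$dim[2])
  for (i in seq_len(nrow(ins))) {
    m <- (X - ins$x_mm[i])^2 + (Y - ins$y_mm[i])^2 <= ins$r_mm[i]^2
    insert2d[m] <- i + 1L  # labels 2..(1+n); later wins never happens (no overlap)
  }
  slice_body <- ifelse(body2d, 1L, 0L)
  slice_insert <- ifelse(insert2d > 0L, insert2d, slice_body)

  lab <- array(0L, grid$dim)
  in_body_z <- zs >= layout$body_z_mm[1] & zs <= layout$body_z_mm[2]
  in_ins_z <- zs >= layout$insert_z_mm[1] & zs <= layout$insert_z_mm[2]
  for (k in seq_len(grid$dim[3])) {
    if (!in_body_z[k]) next
    lab[, , k] <- if (in_ins_z[k]) slice_insert else slice_body
  }

  legend <- dplyr::bind_rows(
    tibble::tibble(label = 0L, segment = "air", material = "air", ring = NA_character_),
    tibble::tibble(label = 1L, segment = "body", material = "plastic_water",
                   ring = NA_character_),
    tibble::tibble(label = seq_len(nrow(ins)) + 1L,
                   segment = paste(ins$material, ins$ring, sep = "_"),
                   material = ins$material, ring = ins$ring)
  )
  label_volume(lab, grid, legend)
}

#' Majority-vote label downsampling
#'
#' Maps each source voxel centre into the target grid and assigns every target
#' voxel the most frequent source label among the source voxels it covers.
#' Ties break deterministically toward the smallest label id; target voxels
#' covering no source voxel become air (label 0). Mirrors the downscaling of a
#' high-resolution segmentation to the mu-map voxel size.
#'
#' @param src A [label_volume()].
#' @param target A [voxel_grid()] at least as coarse as the source on every
#'   axis and sharing the source's world frame.
#' @return A [label_volume()] on `target` with the source legend.
#' @export
downsample_labels <- function(src, target) {
  stopifnot(inherits(src, "label_volume"), inherits(target, "voxel_grid"))
  if (any(target$spacing < src$grid$spacing - 1e-9)) {
    stop("target grid must be at least as coarse as the source on every axis",
         call. = FALSE)
  }
  if (grid_equal(src$grid, target)) {
    return(label_volume(src$data, target, src$legend))
  }
  g <- src$grid
  tx <- round((axis_coords(g, 1) - target$origin[1]) / target$spacing[1]) + 1
  ty <- round((axis_coords(g, 2) - target$origin[2]) / target$spacing[2]) + 1
  tz <- round((axis_coords(g, 3) - target$origin[3]) / target$spacing[3]) + 1
  okx <- tx >= 1 & tx <= target$dim[1]
  oky <- ty >= 1 & ty <= target$dim[2]
  okz <- tz >= 1 & tz <= target$dim[3]
  ncell <- prod(target$dim)
  # linear target cell index for every source voxel (NA outside)
  ix <- ifelse(okx, tx, NA_integer_)
  iy <- ifelse(oky, ty, NA_integer_)
  iz <- ifelse(okz, tz, NA_integer_)
  cell <- outer(outer(ix, (iy - 1L) * target$dim[1], "+"),
                (iz - 1L) * target$dim[1] * target$dim[2], "+")
  labs <- sort(unique(as.vector(src$data)))
  best_count <- integer(ncell)
  best_label <- integer(ncell)  # 0 = air default
  src_vec <- as.vector(src$data)
  cell_vec <- as.vector(cell)
  keep <- !is.na(cell_vec)
  src_vec <- src_vec[keep]; cell_vec <- cell_vec[keep]
  for (l in labs) {
    cnt <- tabulate(cell_vec[src_vec == l], nbins = ncell)
    win <- cnt > best_count  # strict: ties keep the earlier (smaller) label
    best_count[win] <- cnt[win]
    best_label[win] <- l
  }
  label_volume(array(best_label, target$dim), target, src$legend)
}

#' Assign theoretical attenuation coefficients to a segmentation
#'
#' Substitutes each label with the linear attenuation coefficient of its
#' material at the given energy, producing the theoretical mu-map.
#'
#' @param labels A [label_volume()].
#' @param registry Named list of materials (see [material_registry()]).
#' @param energy_keV Photon energy (default 208.4 keV).
#' @param tables Attenuation table.
#' @return A [mu_volume()].
#' @export
labels_to_mu <- function(labels, registry = material_registry(),
                         energy_keV = 208.4, tables = attenuation_tables()) {
  stopifnot(inherits(labels, "label_volume"))
  legend <- labels$legend
  missing <- setdiff(legend$material, names(registry))
  if (length(missing) > 0) {
    stop("materials missing from registry: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mu_by_label <- vapply(legend$material, function(m) {
    linear_attenuation(registry[[m]], energy_keV, tables)
  }, numeric(1))
  lut <- numeric(max(legend$label) + 1L)
  lut[legend$label + 1L] <- mu_by_label
  mu_volume(lut[labels$data + 1L], labels$grid, energy_keV = energy_keV)
}
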