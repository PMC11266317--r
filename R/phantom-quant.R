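#' Build the NEMA-body quantification phantom
#'
#' A water-filled NEMA-style body carrying four attenuation cylinders, each with
#' an axial syringe bore holding a 177Lu source: polystyrene (lung-equivalent,
#' 5 cm diameter, expanded to 0.023 g/cm^3), PTFE (bone, 3 cm, 2.18 g/cm^3),
#' polyamide (soft tissue, 3 cm, 1.02 g/cm^3) and polypropylene (fat, 3 cm,
#' 0.91 g/cm^3). Syringes are 0.7 cm diameter (1 mL) or 1.6 cm diameter
#' (10 mL); the activity volume is uniform inside each syringe and normalised
#' so the voxelised total matches the nominal activity exactly.
#'
#' @param source `"1mL"` or `"10mL"`.
#' @param grid A [voxel_grid()].
#' @param activities_MBq Named nominal activities (names `PS`, `PTFE`, `PA`,
#'   `PP`), in MBq.
#' @param body_half_axes_mm NEMA-style body half-axes (x, y) in mm.
#' @param body_z_mm Axial extent of the body.
#' @param cylinder_ring_mm Radius of the ring on which the four cylinders sit.
#' @param cylinder_z_mm Axial extent of the attenuation cylinders.
#' @param syringe_r_mm Override of the syringe radius (testing/what-if only);
#'   must stay below the bore cylinder radius.
#' @return A list with elements `labels` (a [label_volume()]) and `activity`
#'   (an [activity_volume()]).
#' @export
build_quant_phantom <- function(source = c("1mL", "10mL"),
                                grid = spect_grid(),
                                activities_MBq = c(PS = 20, PTFE = 20,
                                                   PA = 20, PP = 20),
                                body_half_axes_mm = c(150, 110),
                                body_z_mm = c(-90, 90),
                                cylinder_ring_mm = 62,
                                cylinder_z_mm = c(-50, 50),
                                syringe_r_mm = NULL) {
  source <- match.arg(source)
  stopifnot(all(c("PS", "PTFE", "PA", "PP") %in% names(activities_MBq)))
  syr_r <- syringe_r_mm %||% if (source == "1mL") 3.5 else 8    # mm
  syr_vol_ml <- if (source == "1mL") 1 else 10
  syr_len <- syr_vol_ml * 1000 / (pi * syr_r^2)

  cyl <- tibble::tibble(
    name = c("PS", "PTFE", "PA", "PP"),
    material = c("polystyrene", "ptfe", "polyamide", "polypropylene"),
    r_mm = c(25, 15, 15, 15),
    angle = pi / 4 + (0:3) * pi / 2
  )
  cyl$x_mm <- cylinder_ring_mm * cos(cyl$angle)
  cyl$y_mm <- cylinder_ring_mm * sin(cyl$angle)
  if (syr_r >= min(cyl$r_mm)) {
    stop("syringe larger than its bore cylinder", call. = FALSE)
  }

  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  X <- matrix(xs, grid$dim[1], grid$dim[2])
  Y <- matrix(ys, grid$dim[1], grid$dim[2], byrow = TRUE)
  body2d <- (X / body_half_axes_mm[1])^2 + (Y / body_half_axes_mm[2])^2 <= 1

  cyl2d <- matrix(0L, grid$dim[1], grid$dim[2])
  syr2d <- matrix(0L, grid$dim[1], grid$dim[2])
  for (i in 1:4) {
    d2 <- (X - cyl$x_mm[i])^2 + (Y - cyl$y_mm[i])^2
    cyl2d[d2 <= cyl$r_mm[i]^2] <- i
    syr2d[d2 <= syr_r^2] <- i
  }

  lab <- array(0L, grid$dim)
  act <- array(0, grid$dim)
  in_body_z <- zs >= body_z_mm[1] & zs <= body_z_mm[2]
  in_cyl_z <- zs >= cylinder_z_mm[1] & zs <= cylinder_z_mm[2]
  in_syr_z <- zs >= -syr_len / 2 & zs <= syr_len / 2
  for (k in seq_len(grid$dim[3])) {
    if (!in_body_z[k]) next
    sl <- ifelse(body2d, 1L, 0L)
    if (in_cyl_z[k]) sl <- ifelse(cyl2d > 0L, cyl2d + 1L, sl)
    if (in_syr_z[k]) sl <- ifelse(syr2d > 0L, syr2d + 5L, sl)
    lab[, , k] <- sl
  }
  # uniform concentration inside each syringe, exactly normalised to nominal
  vv <- voxel_volume_ml(grid)
  for (i in 1:4) {
    nvox <- sum(lab == i + 5L)
    if (nvox == 0 && activities_MBq[[cyl$name[i]]] > 0) {
      stop("syringe ", cyl$name[i], " not resolved on this grid", call. = FALSE)
    }
    if (nvox > 0) act[lab == i + 5L] <- activities_MBq[[cyl$name[i]]] / (nvox * vv)
  }

  legend <- dplyr::bind_rows(
    tibble::tibble(label = 0L, segment = "air", material = "air"),
    tibble::tibble(label = 1L, segment = "body_water", material = "water"),
    tibble::tibble(label = 2:5, segment = paste0("cylinder_", cyl$name),
                   material = cyl$material),
    tibble::tibble(label = 6:9, segment = paste0("syringe_", cyl$name),
                   material = "water")
  )
  sources <- stats::setNames(as.numeric(activities_MBq[cyl$name]), cyl$name)
  list(labels = label_volume(lab, grid, legend),
       activity = activity_volume(act, grid, nominal_MBq = sources),
       sources = dplyr::mutate(cyl, syringe_r_mm = syr_r,
                               syringe_len_mm = syr_len, source = source))
}
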