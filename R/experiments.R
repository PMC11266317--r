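#' Experiment configuration
#'
#' Bundles the four study pipelines into reproducible configurations. The
#' `"paper"` grid preset uses the full acquisition-chain grids (512 x 512 x 86
#' CT, 128 x 128 x 55 SPECT); `"reduced"` scales the CT grid down fourfold
#' in-plane for quick runs while keeping the field of view and the SPECT voxel
#' size, which leaves VOI statistics essentially unchanged.
#'
#' @param experiment One of `"mu_comparison"`, `"acf_delta"`, `"noise_cov"`,
#'   `"quantification"`.
#' @param settings Tibble of scan settings (default: all seven studied
#'   combinations, [scan_settings()]).
#' @param repetitions Repetitions per setting (default 10, the study design).
#' @param seed Master seed; per-acquisition seeds are derived deterministically
#'   from it.
#' @param grid_preset `"paper"` or `"reduced"`.
#' @param out_dir Optional directory: result tables (CSV), intermediate volumes
#'   (NIfTI) and a manifest (YAML, with seeds and a config hash) are written
#'   there.
#' @param ... Experiment-specific options (e.g. `zero_noise = TRUE`,
#'   `angles`, `source`, `poisson`).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment, settings = scan_settings(),
                              repetitions = 10, seed = 1,
                              grid_preset = c("reduced", "paper"),
                              out_dir = NULL, ...) {
  known <- c("mu_comparison", "acf_delta", "noise_cov", "quantification")
  if (!experiment %in% known) {
    stop("unknown experiment id: ", experiment, " (expected one of ",
         paste(known, collapse = ", "), ")", call. = FALSE)
  }
  grid_preset <- match.arg(grid_preset)
  structure(list(experiment = experiment, settings = settings,
                 repetitions = repetitions, seed = as.integer(seed),
                 grid_preset = grid_preset, out_dir = out_dir,
                 options = list(...)),
            class = "experiment_config")
}

config_hash <- function(config) {
  substr(rlang::hash(config[c("experiment", "settings", "repetitions",
                              "seed", "grid_preset", "options")]), 1, 12)
}

# deterministic per-(setting, repetition) seed below 2^31
derive_seed <- function(master, setting_idx, rep_idx) {
  as.integer((as.numeric(master) * 7919 + setting_idx * 601 + rep_idx * 13) %%
               2000000000)
}

#' Run a study experiment end-to-end
#'
#' Dispatches to the pipeline named in the configuration and decorates every
#' result row with provenance columns (`kvp`, `qrm`, `seed`, `config_hash`).
#' With `out_dir` set, tables are written as CSV together with a YAML manifest.
#'
#' @param config An [experiment_config()].
#' @return A list of result tibbles (pipeline-specific; see
#'   [run_mu_comparison()], [run_acf_delta()], [run_noise_cov()],
#'   [run_quantification()]).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  runner <- switch(config$experiment,
    mu_comparison = run_mu_comparison,
    acf_delta = run_acf_delta,
    noise_cov = run_noise_cov,
    quantification = run_quantification)
  t0 <- Sys.time()
  res <- runner(config)
  hash <- config_hash(config)
  res <- lapply(res, function(x) {
    if (is.data.frame(x)) dplyr::mutate(x, config_hash = hash) else x
  })
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res)) {
      if (is.data.frame(res[[nm]])) {
        utils::write.csv(res[[nm]],
                         file.path(config$out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    manifest <- list(experiment = config$experiment, seed = config$seed,
                     repetitions = config$repetitions,
                     grid_preset = config$grid_preset, config_hash = hash,
                     elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  }
  res
}

experiment_grids <- function(preset) {
  if (preset == "paper") list(ct = ct_grid(1), spect = spect_grid(1))
  else list(ct = ct_grid(4), spect = spect_grid(1))
}

insert_vois <- function(layout, grid, extent = c(3, 3, 8)) {
  ins <- layout$inserts
  zc <- mean(layout$insert_z_mm)
  purrr::map(seq_len(nrow(ins)), function(i) {
    centered_voi(grid, c(ins$x_mm[i], ins$y_mm[i], zc), extent)
  })
}

measured_mu_map <- function(labels, setting, spect_grid_, model,
                            registry = material_registry(), ...) {
  hu <- emulate_ct(labels, setting, registry, ...)
  resample_mu(hu_to_mu(hu, model, kvp = setting$kvp), spect_grid_,
              outside = "zero")
}

#' Attenuation-coefficient comparison experiment
#'
#' For every scan setting and repetition: emulate the CT, convert to the 177Lu
#' mu-map, resample to the SPECT grid and read out every insert with a
#' 3 x 3 x 8-voxel VOI. Returns per-insert measured attenuation, the
#' ring-averaged values with relative errors against the theoretical mu, and
#' the inner-vs-outer statistical comparison (Shapiro-Wilk gate + location
#' test).
#'
#' @param config An [experiment_config()] with `experiment = "mu_comparison"`.
#'   Option `zero_noise = TRUE` disables CT noise to isolate conversion bias.
#' @return List of tibbles: `measurements`, `insert_stats`, `ring_comparison`.
#' @export
run_mu_comparison <- function(config) {
  grids <- experiment_grids(config$grid_preset)
  layout <- default_density_layout()
  labels <- build_density_phantom(layout, grids$ct)
  model <- bilinear_model()
  registry <- material_registry()
  vois <- insert_vois(layout, grids$spect)
  zero_noise <- isTRUE(config$options$zero_noise)
  mu_th <- theoretical_mu_table(registry[unique(layout$inserts$material)])

  meas <- purrr::map_dfr(seq_len(nrow(config$settings)), function(si) {
    s <- config$settings[si, ]
    purrr::map_dfr(seq_len(config$repetitions), function(r) {
      seed <- derive_seed(config$seed, si, r)
      setting <- scan_setting(s$kvp, s$qrm, seed = seed,
                              sigma_hu = if (zero_noise) 0 else NULL,
                              drift_hu = if (zero_noise) 0 else NULL)
      # ideal CT: no noise and no reconstruction correlation either
      mu_map <- measured_mu_map(labels, setting, grids$spect, model, registry,
                                smooth_sigma_vox = if (zero_noise) 0 else 1)
      tibble::tibble(
        kvp = s$kvp, qrm = s$qrm, repetition = r, seed = seed,
        material = layout$inserts$material, ring = layout$inserts$ring,
        mu_measured = vapply(vois, function(v) voi_mean(mu_map, v), numeric(1))
      )
    })
  })

  stats <- meas |>
    dplyr::group_by(.data$kvp, .data$qrm, .data$material, .data$ring) |>
    dplyr::summarise(mu_measured = mean(.data$mu_measured), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "ring", values_from = "mu_measured") |>
    dplyr::mutate(inner_outer_mean(.data$inner, .data$outer)) |>
    dplyr::left_join(mu_th, by = "material") |>
    dplyr::mutate(rel_error_pct = relative_error(.data$mu_mean, .data$mu_cm1))

  ring_cmp <- meas |>
    dplyr::group_by(.data$kvp, .data$qrm) |>
    dplyr::group_modify(function(d, key) {
      # inner dataset excludes the single-ring densest bone insert
      inner <- d$mu_measured[d$ring == "inner" & d$material != "bone_ha1250"]
      outer <- d$mu_measured[d$ring == "outer"]
      rep <- compare_groups(list(inner = inner, outer = outer))
      rep$test
    }) |>
    dplyr::ungroup()

  list(measurements = dplyr::mutate(meas, seed = as.integer(.data$seed)),
       insert_stats = stats, ring_comparison = ring_cmp)
}

#' ACF change experiment
#'
#' Builds the theoretical mu-map (downsampled segmentation with theoretical
#' attenuation values) and a measured mu-map per setting, computes first-order
#' Chang ACF images restricted to the insert VOIs, and evaluates the expected
#' activity change `Delta A` per insert from the VOI means.
#'
#' @param config An [experiment_config()] with `experiment = "acf_delta"`.
#'   Options: `angles` (default 64), `repetitions` typically 1 here.
#' @return List of tibbles: `delta` with per-insert ACFs and `delta_pct`.
#' @export
run_acf_delta <- function(config) {
  grids <- experiment_grids(config$grid_preset)
  layout <- default_density_layout()
  labels <- build_density_phantom(layout, grids$ct)
  registry <- material_registry()
  model <- bilinear_model()
  angles <- config$options$angles %||% 64
  labels_sp <- downsample_labels(labels, grids$spect)
  mu_theo <- labels_to_mu(labels_sp, registry)
  vois <- insert_vois(layout, grids$spect)
  mask <- voi_mask(grids$spect, vois)
  acf_theo <- chang_acf_volume(mu_theo, M = angles, mask = mask,
                               provenance = "theoretical")

  delta <- purrr::map_dfr(seq_len(nrow(config$settings)), function(si) {
    s <- config$settings[si, ]
    purrr::map_dfr(seq_len(config$repetitions), function(r) {
      seed <- derive_seed(config$seed, si, r)
      setting <- scan_setting(s$kvp, s$qrm, seed = seed)
      mu_meas <- measured_mu_map(labels, setting, grids$spect, model, registry)
      acf_meas <- chang_acf_volume(mu_meas, M = angles, mask = mask,
                                   provenance = "measured")
      a_th <- vapply(vois, function(v) voi_mean(acf_theo, v), numeric(1))
      a_ms <- vapply(vois, function(v) voi_mean(acf_meas, v), numeric(1))
      tibble::tibble(
        kvp = s$kvp, qrm = s$qrm, repetition = r, seed = seed,
        material = layout$inserts$material, ring = layout$inserts$ring,
        acf_theoretical = a_th, acf_measured = a_ms,
        delta_pct = delta_activity(a_th, a_ms)
      )
    })
  })
  list(delta = delta)
}

voi_mask <- function(grid, vois) {
  m <- array(FALSE, grid$dim)
  for (v in vois) {
    hi <- v$anchor + v$extent - 1L
    m[v$anchor[1]:hi[1], v$anchor[2]:hi[2], v$anchor[3]:hi[3]] <- TRUE
  }
  m
}

#' Mu-map noise experiment
#'
#' Runs the coefficient-of-variation chain for each scan setting: a body-only
#' phantom section (the homogeneous plastic-water region), `repetitions`
#' emulated CT acquisitions, HU-to-mu conversion, resampling to the SPECT
#' voxel size, and eight 1000-voxel VOIs arranged on a ring.
#'
#' @param config An [experiment_config()] with `experiment = "noise_cov"`.
#' @return List with tibble `noise`: per setting `mu_mean`, `mu_sd`, `cov` and
#'   `ctdi_mgy`.
#' @export
run_noise_cov <- function(config) {
  g <- noise_grids(config$grid_preset)
  layout <- insert_layout(
    tibble::tibble(material = character(), x_mm = numeric(), y_mm = numeric(),
                   r_mm = numeric(), ring = character()),
    body_z_mm = c(-120, 120), insert_z_mm = c(999, 999),
    homogeneous_z_mm = c(-120, 120))
  labels <- build_density_phantom(layout, g$ct)
  model <- bilinear_model()
  registry <- material_registry()
  vois <- noise_vois(g$spect)

  noise <- purrr::map_dfr(seq_len(nrow(config$settings)), function(si) {
    s <- config$settings[si, ]
    maps <- purrr::map(seq_len(config$repetitions), function(r) {
      seed <- derive_seed(config$seed, si, r)
      setting <- scan_setting(s$kvp, s$qrm, seed = seed)
      measured_mu_map(labels, setting, g$spect, model, registry)
    })
    na <- cov_chain(maps, vois)
    tibble::tibble(kvp = s$kvp, qrm = s$qrm, seed = config$seed,
                   repetitions = config$repetitions,
                   mu_mean = na$mu_mean, mu_sd = na$mu_sd, cov = na$cov,
                   ctdi_mgy = ctdi_lookup(s$kvp, s$qrm))
  })
  list(noise = noise)
}

# grids covering only the homogeneous section interior, centred on z = 0;
# the reduced preset keeps the mu-map voxel size but restricts the field of
# view to the region the noise VOIs sample
noise_grids <- function(preset) {
  if (preset == "paper") {
    list(ct = ct_grid(1), spect = spect_grid(1))
  } else {
    list(ct = voxel_grid(c(56, 56, 26), c(3, 3, 4.6)),
         spect = voxel_grid(c(32, 32, 24), c(4.8, 4.8, 4.8)))
  }
}

# eight 10x10x10 VOIs on a 60-mm ring, two axial levels (ICRU-style scheme)
noise_vois <- function(grid) {
  nz <- grid$dim[3]
  zlev <- c(grid$origin[3] + (nz %/% 4) * grid$spacing[3],
            grid$origin[3] + (3 * nz %/% 4) * grid$spacing[3])
  ang <- pi / 4 + (0:3) * pi / 2
  purrr::flatten(purrr::map(zlev, function(z) {
    purrr::map(ang, function(a) {
      centered_voi(grid, c(60 * cos(a), 60 * sin(a), z), c(10, 10, 10))
    })
  }))
}

#' Activity-quantification experiment
#'
#' Simulates the quantification phantom for one source geometry, projects it
#' through the attenuated system model (Poisson noise optional), reconstructs
#' with OSEM using the mu-map of each scan setting, and recovers each source's
#' activity in an extended cylindrical VOI.
#'
#' @param config An [experiment_config()] with `experiment = "quantification"`.
#'   Options: `source` ("10mL" default), `poisson`, `iterations`, `subsets`,
#'   `sys` (a [system_config()]), `grid` (reconstruction [voxel_grid()]).
#' @return List with tibble `recovery` (per setting x source relative errors).
#' @export
run_quantification <- function(config) {
  opt <- config$options
  grid <- opt$grid %||% spect_grid(2)
  source <- opt$source %||% "10mL"
  sys <- opt$sys %||% system_config()
  registry <- material_registry()
  model <- bilinear_model()
  ph <- build_quant_phantom(source, grid)
  mu_true <- labels_to_mu(ph$labels, registry)

  recovery <- purrr::map_dfr(seq_len(nrow(config$settings)), function(si) {
    s <- config$settings[si, ]
    seed <- derive_seed(config$seed, si, 1L)
    setting <- scan_setting(s$kvp, s$qrm, seed = seed)
    mu_recon <- measured_mu_map(ph$labels, setting, grid, model, registry)
    sys_run <- sys; sys_run$seed <- seed
    sino <- forward_project(ph$activity, mu_true, sys_run,
                            poisson = isTRUE(opt$poisson))
    recon <- osem(sino, mu_recon, sys_run,
                  iterations = opt$iterations %||% 6,
                  subsets = opt$subsets %||% 6)
    purrr::map_dfr(seq_len(nrow(ph$sources)), function(i) {
      src <- ph$sources[i, ]
      dplyr::mutate(
        quantify(recon, c(src$x_mm, src$y_mm, 0),
                 radius_mm = src$syringe_r_mm + 2 * 2.355 * sys$psf_sigma_mm,
                 half_len_mm = src$syringe_len_mm / 2 + 2 * 2.355 * sys$psf_sigma_mm,
                 nominal_MBq = ph$activity$nominal_MBq[[src$name]],
                 source_r_mm = src$syringe_r_mm, sys = sys_run,
                 name = src$name),
        kvp = s$kvp, qrm = s$qrm, seed = seed, source_size = source)
    })
  })
  list(recovery = recovery)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
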