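#' Elemental mass attenuation tables
#'
#' Loads the packaged elemental photon mass-attenuation table (total cross
#' section with coherent scattering, cm^2/g, on a 40-400 keV grid). The table
#' follows the NIST Standard Reference Database 8 layout; see the fixture
#' header for how it was constructed. A drop-in replacement with the same
#' columns (`element`, `energy_keV`, `mu_over_rho_cm2_g`) can be supplied via
#' `path`.
#'
#' @param path Path to a tab-separated table; default is the packaged fixture.
#' @return A tibble with columns `element`, `energy_keV`, `mu_over_rho_cm2_g`.
#' @export
attenuation_tables <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.spectac_cache$tables)) return(.spectac_cache$tables)
    path <- system.file("extdata", "element_mass_attenuation_synthetic.tsv",
                        package = "spectac", mustWork = TRUE)
    tab <- load_attenuation_tsv(path)
    .spectac_cache$tables <- tab
    return(tab)
  }
  load_attenuation_tsv(path)
}

.spectac_cache <- new.env(parent = emptyenv())

load_attenuation_tsv <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("element", "energy_keV", "mu_over_rho_cm2_g") %in% names(tab)))
  if (any(tab$mu_over_rho_cm2_g <= 0)) stop("attenuation table values must be > 0")
  tab <- tab[order(tab$element, tab$energy_keV), ]
  rng <- vapply(split(tab$energy_keV, tab$element), range, numeric(2))
  if (any(rng[1, ] > 100) || any(rng[2, ] < 400)) {
    stop("each element's energy grid must cover at least 100-400 keV")
  }
  tibble::as_tibble(tab)
}

#' Mass attenuation coefficient of an element
#'
#' Log-log linear interpolation of the tabulated mass attenuation coefficient
#' (the standard scheme for photon cross sections, whose segments are close to
#' power laws in energy). Querying a tabulated grid energy returns the stored
#' value exactly; energies outside the grid are an error (no extrapolation).
#'
#' @param element Element symbol, e.g. `"O"`.
#' @param energy_keV Photon energy in keV (vectorised).
#' @param tables Attenuation table as returned by [attenuation_tables()].
#' @return Mass attenuation coefficient(s) in cm^2/g.
#' @export
#' @examples
#' lookup_mass_attenuation("O", 208.4)
lookup_mass_attenuation <- function(element, energy_keV,
                                    tables = attenuation_tables()) {
  rows <- tables[tables$element == element, ]
  if (nrow(rows) == 0) {
    stop("element not found in attenuation table: ", element, call. = FALSE)
  }
  e <- rows$energy_keV
  v <- rows$mu_over_rho_cm2_g
  if (any(energy_keV < min(e) | energy_keV > max(e))) {
    stop(sprintf("energy outside tabulated range [%g, %g] keV for %s",
                 min(e), max(e), element), call. = FALSE)
  }
  hit <- match(energy_keV, e)
  out <- numeric(length(energy_keV))
  exact <- !is.na(hit)
  out[exact] <- v[hit[exact]]
  if (any(!exact)) {
    q <- energy_keV[!exact]
    i <- findInterval(q, e)
    out[!exact] <- exp(log(v[i]) + (log(v[i + 1]) - log(v[i])) *
                         (log(q / e[i]) / log(e[i + 1] / e[i])))
  }
  out
}

#' Tissue-equivalent material specification
#'
#' @param name Material name.
#' @param density_g_cm3 Mass density in g/cm^3 (>= 0).
#' @param mass_fractions Named numeric vector of elemental mass fractions;
#'   must sum to 1 within 1e-6 and use elements present in `tables`.
#' @param tables Attenuation table used for validation.
#' @return An object of class `material_spec`.
#' @export
#' @examples
#' material("water", 1.0, c(H = 0.1119, O = 0.8881))
material <- function(name, density_g_cm3, mass_fractions,
                     tables = attenuation_tables()) {
  if (is.null(names(mass_fractions)) || any(names(mass_fractions) == "")) {
    stop("mass_fractions must be a named vector", call. = FALSE)
  }
  if (abs(sum(mass_fractions) - 1) > 1e-6) {
    stop(sprintf("mass fractions of '%s' sum to %.8f, not 1", name,
                 sum(mass_fractions)), call. = FALSE)
  }
  if (density_g_cm3 < 0) stop("density must be >= 0", call. = FALSE)
  missing <- setdiff(names(mass_fractions), unique(tables$element))
  if (length(missing) > 0) {
    stop("elements missing from attenuation table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, density_g_cm3 = density_g_cm3,
                 mass_fractions = mass_fractions),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material> %s, rho = %g g/cm3, elements: %s\n", x$name,
              x$density_g_cm3, paste(names(x$mass_fractions), collapse = " ")))
  invisible(x)
}

#' Packaged material registry
#'
#' Reads the packaged registry of tissue-equivalent and phantom materials
#' (ICRU-44-style tissue compositions, a generic plastic-water surrogate,
#' stoichiometric plastics and hydroxyapatite bone inserts). A drop-in file
#' with the same long-format schema (`material`, `density_g_cm3`, `element`,
#' `mass_fraction`) -- for instance transcribed manufacturer datasheet values --
#' can be supplied via `path`.
#'
#' @param path Path to a registry TSV; default is the packaged fixture.
#' @return A named list of [material()] objects.
#' @export
material_registry <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.spectac_cache$registry)) return(.spectac_cache$registry)
  if (default) {
    path <- system.file("extdata", "material_registry.tsv",
                        package = "spectac", mustWork = TRUE)
  }
  reg <- read_material_registry(path)
  if (default) .spectac_cache$registry <- reg
  reg
}

#' @rdname material_registry
#' @export
read_material_registry <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("material", "density_g_cm3", "element", "mass_fraction")
                %in% names(tab)))
  out <- lapply(split(tab, tab$material), function(d) {
    w <- stats::setNames(d$mass_fraction, d$element)
    material(d$material[1], d$density_g_cm3[1], w / sum(w))
  })
  out[unique(tab$material)]
}

#' Mass attenuation coefficient of a mixture
#'
#' Applies the mixture rule `sum_i w_i (mu/rho)_i(E)` over the material's
#' elemental mass fractions.
#'
#' @param mat A [material()] object.
#' @param energy_keV Photon energy in keV.
#' @param tables Attenuation table.
#' @return Mass attenuation coefficient in cm^2/g.
#' @export
mixture_mass_attenuation <- function(mat, energy_keV,
                                     tables = attenuation_tables()) {
  stopifnot(inherits(mat, "material_spec"))
  w <- mat$mass_fractions
  vals <- vapply(names(w), function(el) {
    lookup_mass_attenuation(el, energy_keV, tables)
  }, numeric(length(energy_keV)))
  if (length(energy_keV) == 1) sum(w * vals) else as.vector(vals %*% w)
}

#' Linear attenuation coefficient of a material
#'
#' `mu = rho * sum_i w_i (mu/rho)_i(E)`; at 208.4 keV this is the theoretical
#' attenuation coefficient used throughout the 177Lu attenuation-correction
#' analysis.
#'
#' @inheritParams mixture_mass_attenuation
#' @return Linear attenuation coefficient in cm^-1.
#' @export
#' @examples
#' reg <- material_registry()
#' linear_attenuation(reg$water, 208.4)
linear_attenuation <- function(mat, energy_keV,
                               tables = attenuation_tables()) {
  mat$density_g_cm3 * mixture_mass_attenuation(mat, energy_keV, tables)
}

#' Theoretical attenuation coefficients for a set of materials
#'
#' @param materials A named list of [material()] objects (e.g. a registry or a
#'   subset of one).
#' @param energy_keV Photon energy in keV (default 208.4, the principal 177Lu
#'   gamma emission).
#' @param tables Attenuation table.
#' @return A tibble with columns `material`, `density_g_cm3`, `mu_cm1`.
#' @export
theoretical_mu_table <- function(materials, energy_keV = 208.4,
                                 tables = attenuation_tables()) {
  if (length(materials) == 0) stop("empty material list", call. = FALSE)
  nm <- vapply(materials, function(m) m$name, character(1))
  if (anyDuplicated(nm)) {
    stop("duplicate material names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    material = unname(nm),
    density_g_cm3 = vapply(materials, function(m) m$density_g_cm3, numeric(1)),
    mu_cm1 = vapply(materials, linear_attenuation, numeric(1),
                    energy_keV = energy_keV, tables = tables)
  )
}
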