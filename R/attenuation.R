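# X-ray mass attenuation lookups.
#
# Elemental mass attenuation coefficients (total, with coherent scattering) are
# packaged as a plain-text table transcribed from the public NIST/XCOM
# tabulations, with extra grid points bracketing absorption edges (Al K, I K,
# W K).  Compounds are resolved through the standard mixture rule over a parsed
# chemical formula; interpolation is log-log, the convention for attenuation
# data on sparse energy grids.

.atten_env <- new.env(parent = emptyenv())

.atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, Be = 9.012,
  Al = 26.982, I = 126.904, W = 183.84, Air = 1
)

.load_atten_tables <- function() {
  if (!is.null(.atten_env$elements)) {
    return(invisible(NULL))
  }
  path <- system.file("extdata", "attenuation", package = "spectraln2i")
  el <- utils::read.csv(file.path(path, "elements.csv"), stringsAsFactors = FALSE)
  mat <- utils::read.csv(file.path(path, "materials.csv"), stringsAsFactors = FALSE)
  .atten_env$elements <- split(el[c("energy_kev", "mu_rho_cm2_g")], el$element)
  .atten_env$materials <- mat
  invisible(NULL)
}

#' Parse a chemical formula into element counts
#'
#' @param formula Formula string such as `"H2O"` or `"C6H5NO2"`. Element
#'   symbols are one capital letter optionally followed by one lowercase
#'   letter; counts default to 1.
#' @return Named numeric vector of atom counts.
#' @keywords internal
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  # symbols are 1-3 letters so the pseudo-element "Air" parses too
  m <- gregexpr("[A-Z][a-z]{0,2}[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (length(tokens) == 0L || sum(attr(m, "match.length")) != nchar(formula)) {
    stop("unknown_material: cannot parse chemical formula '", formula, "'",
         call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- as.numeric(sub("^[A-Za-z]+", "", tokens))
  cnts[is.na(cnts)] <- 1
  counts <- tapply(cnts, syms, sum)
  out <- as.numeric(counts)
  names(out) <- names(counts)
  out
}

# mass fractions of elements in a formula
.mass_fractions <- function(formula) {
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(.atomic_weights))
  if (length(unknown) > 0L) {
    stop("unknown_material: element(s) not in attenuation database: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mass <- counts * .atomic_weights[names(counts)]
  mass / sum(mass)
}

# log-log interpolation of a tabulated mu/rho curve
.interp_loglog <- function(tab, energy) {
  rng <- range(tab$energy_kev)
  if (any(energy < rng[1] | energy > rng[2])) {
    stop("energy_out_of_range: requested energy outside tabulated range [",
         rng[1], ", ", rng[2], "] keV", call. = FALSE)
  }
  y <- stats::approx(log(tab$energy_kev), log(tab$mu_rho_cm2_g),
                     xout = log(energy), ties = "ordered")$y
  exp(y)
}

#' Look up a material in the packaged material table
#'
#' @param material Material name (e.g. `"water"`), element symbol, or chemical
#'   formula.
#' @return List with `formula` and `density` (g/cm3; `NA` for raw formulas).
#' @export
resolve_material <- function(material) {
  .load_atten_tables()
  mat <- .atten_env$materials
  hit <- match(tolower(material), tolower(mat$name))
  if (is.na(hit)) hit <- match(material, mat$formula)
  if (!is.na(hit)) {
    return(list(name = mat$name[hit], formula = mat$formula[hit],
                density = mat$density_g_cm3[hit]))
  }
  # fall back to treating the input as a formula
  fr <- tryCatch(.mass_fractions(material), error = function(e) NULL)
  if (is.null(fr)) {
    stop("unknown_material: '", material, "' is neither a packaged material, ",
         "an element symbol, nor a parsable formula", call. = FALSE)
  }
  list(name = material, formula = material, density = NA_real_)
}

#' Mass attenuation coefficient of an element, compound or named material
#'
#' Elemental values come from the packaged NIST-style table; compounds use the
#' mixture rule \eqn{\mu/\rho = \sum_i w_i (\mu/\rho)_i} with mass fractions
#' \eqn{w_i} derived from the chemical formula.
#'
#' @param material Material name, element symbol, or chemical formula.
#' @param energy Photon energy (keV), scalar or vector; must lie inside the
#'   tabulated range of every constituent element.
#' @return Mass attenuation coefficient(s) in cm2/g.
#' @examples
#' get_mass_attenuation("water", 70)
#' get_mass_attenuation("Al", c(40, 80))
#' @export
get_mass_attenuation <- function(material, energy) {
  .load_atten_tables()
  stopifnot(is.numeric(energy), all(is.finite(energy)), all(energy > 0))
  info <- resolve_material(material)
  fr <- .mass_fractions(info$formula)
  out <- numeric(length(energy))
  for (sym in names(fr)) {
    out <- out + fr[[sym]] * .interp_loglog(.atten_env$elements[[sym]], energy)
  }
  out
}

#' Linear attenuation coefficient of a named material
#'
#' @inheritParams get_mass_attenuation
#' @param density Override density in g/cm3; defaults to the packaged nominal
#'   density (required for raw formulas).
#' @return Linear attenuation coefficient(s) in 1/cm.
#' @export
get_linear_attenuation <- function(material, energy, density = NULL) {
  info <- resolve_material(material)
  rho <- if (is.null(density)) info$density else density
  if (is.null(rho) || is.na(rho)) {
    stop("unknown_material: no packaged density for '", material,
         "'; supply `density`", call. = FALSE)
  }
  get_mass_attenuation(material, energy) * rho
}

#' Locate a K-edge in an attenuation profile
#'
#' Scans consecutive samples of an attenuation-versus-energy profile inside a
#' window and reports the energy of the largest positive jump, provided the
#' jump exceeds a relative threshold of the value just before it.  Absorption
#' edges are abrupt increases (the photoelectric cross-section jumps when the
#' photon energy crosses a shell binding energy), so on any reasonably fine
#' grid they dominate every other consecutive difference.
#'
#' @param energies Strictly increasing energy samples (keV).
#' @param values Attenuation values at `energies` (same length).
#' @param window Optional `c(lo, hi)` energy window (keV) to restrict the scan.
#' @param rel_threshold Minimum jump size as a fraction of the value before the
#'   jump (default 0.2).
#' @return The energy (keV) of the first sample after the jump, or `NA_real_`
#'   when no qualifying edge exists in the window.
#' @examples
#' e <- seq(25, 45, by = 0.05)
#' find_k_edge(e, get_mass_attenuation("iodine", e))
#' @export
find_k_edge <- function(energies, values, window = NULL, rel_threshold = 0.2) {
  stopifnot(length(energies) == length(values))
  if (is.unsorted(energies, strictly = TRUE)) {
    stop("nonmonotone_energies: energy grid must be strictly increasing",
         call. = FALSE)
  }
  if (!is.null(window)) {
    keep <- energies >= window[1] & energies <= window[2]
    energies <- energies[keep]
    values <- values[keep]
  }
  if (length(energies) < 3L) {
    stop("nonmonotone_energies: need at least 3 samples in the window",
         call. = FALSE)
  }
  jumps <- diff(values)
  rel <- jumps / abs(values[-length(values)])
  k <- which.max(jumps)
  if (jumps[k] <= 0 || rel[k] < rel_threshold) {
    return(NA_real_)
  }
  energies[k + 1L]
}

#' Names of the packaged materials
#'
#' @return Character vector of material names usable in
#'   [get_mass_attenuation()] and [build_phantom()].
#' @export
list_materials <- function() {
  .load_atten_tables()
  .atten_env$materials$name
}
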