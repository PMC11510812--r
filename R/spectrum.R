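# Poly-energetic X-ray source spectra.
#
# The tube model is semi-empirical: a Kramers-type bremsstrahlung continuum
# with target self-absorption (Thomson-Whiddington depth model) plus the
# tungsten K fluorescence lines from a thick-target yield parameterisation.
# Absolute constants are taken once from standard X-ray physics references and
# are exposed for inspection; the absolute fluence scale of such models is
# uncertain at the tens-of-percent level, while the spectral shape, line
# positions and filtration behaviour are robust.

# physics constants of the tube model
.tube_constants <- list(
  # bremsstrahlung number-spectrum constant (photons / keV / electron into 4*pi
  # per unit Z * (E0/E - 1)), from the thick-target efficiency eta ~ 1.1e-9 Z V
  kramers_c = 2.2e-6,
  # Thomson-Whiddington constant (keV^2 cm^2/g): electron mass-depth at which
  # the electron energy drops from E0 to E is (E0^2 - E^2) / c_tw
  thomson_whiddington = 7.5e5,
  # thick-target K-fluorescence yield: N_K = y_k * (U0 - 1)^1.63 photons per
  # electron into 4*pi, U0 = E0 / E_K; anchored at ~2e-4 photons/electron for
  # tungsten at 100 kV
  k_yield = 8.0e-4,
  k_yield_exponent = 1.63,
  # tungsten K shell
  w_k_edge_kev = 69.525,
  # Ka1, Ka2, Kb1(+Kb3), Kb2 energies (keV) and relative intensities
  w_lines_kev = c(59.318, 57.981, 67.244, 69.067),
  w_lines_rel = c(100, 58, 33, 9),
  electrons_per_mas = 6.2415e15,
  anode_z = 74
)

#' Construct an energy spectrum object
#'
#' @param bin_centers Strictly increasing, uniformly spaced bin centres (keV).
#' @param fluence Photons per bin (per cm2 per mAs at the reference distance);
#'   non-negative, same length as `bin_centers`.
#' @param bin_width Bin width (keV).
#' @return An `energy_spectrum` object (list with `bin_centers`, `fluence`,
#'   `bin_width`).
#' @export
energy_spectrum <- function(bin_centers, fluence, bin_width) {
  stopifnot(length(bin_centers) == length(fluence), bin_width > 0)
  if (any(fluence < 0)) {
    stop("invalid_spectrum: fluence must be non-negative", call. = FALSE)
  }
  if (length(bin_centers) > 1L) {
    d <- diff(bin_centers)
    if (any(d <= 0) || max(abs(d - bin_width)) > 1e-6 * bin_width) {
      stop("invalid_spectrum: bin centres must be uniform at bin_width",
           call. = FALSE)
    }
  }
  structure(list(bin_centers = as.numeric(bin_centers),
                 fluence = as.numeric(fluence),
                 bin_width = bin_width),
            class = "energy_spectrum")
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("<energy_spectrum> %d bins, %.4g-%.4g keV (width %.3g keV), total %.4g photons\n",
              length(x$bin_centers), min(x$bin_centers), max(x$bin_centers),
              x$bin_width, sum(x$fluence)))
  invisible(x)
}

#' Simulate a filtered tungsten-anode source spectrum
#'
#' Computes the photon fluence per energy bin of a reflection-target X-ray
#' tube: Kramers continuum with target self-absorption at the take-off angle,
#' plus the tungsten K lines when the tube potential exceeds the K edge, then
#' Beer-Lambert filtration through the listed attenuators.  Fluence is per cm2
#' per mAs at `distance_cm` from the focal spot.
#'
#' @param kvp Tube potential (kV); photon energies above it get zero fluence.
#' @param anode_angle_deg Anode take-off angle (degrees), default 12.
#' @param filtration List of `c(material, thickness_mm)` pairs, e.g.
#'   `list(c("Al", "4"), c("Be", "1"), c("air", "1000"))`.  Materials must be
#'   known to the attenuation database.
#' @param bin_width_kev Energy bin width (keV), default 0.5.
#' @param exposure_mas Tube exposure (mAs), default 1.
#' @param distance_cm Reference distance for the fluence (cm), default 100.
#' @return An [energy_spectrum()] with bins covering (0, kvp].
#' @examples
#' s <- build_source_spectrum(150)
#' max(s$fluence) / s$bin_width  # peak fluence density, photons/cm2/mAs/keV
#' @export
build_source_spectrum <- function(kvp,
                                  anode_angle_deg = 12,
                                  filtration = default_filtration(),
                                  bin_width_kev = 0.5,
                                  exposure_mas = 1,
                                  distance_cm = 100) {
  stopifnot(kvp > 0, bin_width_kev > 0, exposure_mas > 0, distance_cm > 0)
  cst <- .tube_constants
  if (kvp < 1.5 * bin_width_kev) {
    stop("kvp_below_grid: tube potential below the first energy bin",
         call. = FALSE)
  }
  centers <- seq(bin_width_kev / 2, kvp, by = bin_width_kev)
  # the tungsten table starts at 12.5 keV; photons this soft are irrelevant
  # after any realistic filtration, so the continuum starts there
  emin <- 12.5
  e <- centers
  live <- e >= emin & e < kvp

  # continuum: photons/keV/electron into 4*pi, with self-absorption
  n_e <- numeric(length(e))
  mu_w <- rep(NA_real_, length(e))
  mu_w[live] <- get_mass_attenuation("W", e[live])
  tw_depth <- pmax(kvp^2 - e^2, 0) / cst$thomson_whiddington   # g/cm2
  a <- mu_w * tw_depth / sin(anode_angle_deg * pi / 180)
  self_abs <- ifelse(a > 1e-12, (1 - exp(-a)) / a, 1)
  n_e[live] <- cst$kramers_c * cst$anode_z * (kvp / e[live] - 1) *
    self_abs[live]

  # geometry factor: photons/(cm2 mAs) at distance_cm per photon/electron/4pi
  geom <- cst$electrons_per_mas * exposure_mas / (4 * pi * distance_cm^2)
  fluence <- n_e * bin_width_kev * geom

  # characteristic K lines (delta lines deposited into their bins)
  if (kvp > cst$w_k_edge_kev) {
    u0 <- kvp / cst$w_k_edge_kev
    n_k <- cst$k_yield * (u0 - 1)^cst$k_yield_exponent
    depth_k <- (kvp^2 - cst$w_k_edge_kev^2) / cst$thomson_whiddington
    shares <- cst$w_lines_rel / sum(cst$w_lines_rel)
    for (i in seq_along(cst$w_lines_kev)) {
      el <- cst$w_lines_kev[i]
      if (el >= kvp) next
      al <- get_mass_attenuation("W", el) * depth_k /
        sin(anode_angle_deg * pi / 180)
      s_abs <- (1 - exp(-al)) / al
      idx <- which.min(abs(e - el))
      fluence[idx] <- fluence[idx] + n_k * shares[i] * s_abs * geom
    }
  }

  # filtration
  for (f in filtration) {
    mat <- f[[1]]
    thick_cm <- as.numeric(f[[2]]) / 10
    if (is.na(thick_cm) || thick_cm < 0) {
      stop("unknown_filtration: bad thickness for filter '", mat, "'",
           call. = FALSE)
    }
    info <- tryCatch(resolve_material(mat), error = function(e2) {
      stop("unknown_filtration: material '", mat, "' not in the attenuation ",
           "database", call. = FALSE)
    })
    if (is.na(info$density)) {
      stop("unknown_filtration: no density for filter material '", mat, "'",
           call. = FALSE)
    }
    mu <- numeric(length(e))
    mu[live] <- get_linear_attenuation(mat, e[live])
    fluence[live] <- fluence[live] * exp(-mu[live] * thick_cm)
  }
  fluence[!live] <- 0
  energy_spectrum(centers, fluence, bin_width_kev)
}

#' Reference filtration of the packaged tube configuration
#'
#' 4 mm aluminium, 1 mm beryllium and 1000 mm of air.
#' @return List of `c(material, thickness_mm)` pairs.
#' @export
default_filtration <- function() {
  list(c("Al", "4"), c("Be", "1"), c("air", "1000"))
}

#' Interpolate a spectrum onto a fine uniform grid
#'
#' Linear interpolation of the fluence density onto a new grid, returning
#' photons per (new) bin.  The default grid is 19.550 to 150.450 keV at
#' 0.1 keV, the staging grid from which ten-fold averaging produces 131 one-keV
#' channels between 20 and 150 keV.
#'
#' @param s An [energy_spectrum()].
#' @param from,to,by New grid limits and pitch (keV).
#' @return An [energy_spectrum()] on the new grid.
#' @export
interpolate_spectrum <- function(s, from = 19.550, to = 150.450, by = 0.1) {
  stopifnot(inherits(s, "energy_spectrum"))
  grid <- seq(from, to, by = by)
  dens <- s$fluence / s$bin_width
  d <- stats::approx(s$bin_centers, dens, xout = grid, rule = 2)$y
  energy_spectrum(grid, pmax(d, 0) * by, by)
}

#' Average neighbouring energy bins
#'
#' Reduces spectral resolution by replacing each consecutive block of `group`
#' bins with its arithmetic mean; bin centres become block means and the bin
#' width scales by `group`.
#'
#' @param s An [energy_spectrum()].
#' @param group Number of neighbouring bins per block; must divide the length.
#' @return An [energy_spectrum()] with `length(s)/group` bins.
#' @export
rebin_average <- function(s, group) {
  stopifnot(inherits(s, "energy_spectrum"), group >= 1)
  n <- length(s$fluence)
  if (n %% group != 0) {
    stop("indivisible_length: ", n, " bins not divisible by group=", group,
         call. = FALSE)
  }
  idx <- rep(seq_len(n %/% group), each = group)
  fl <- as.numeric(tapply(s$fluence, idx, mean))
  ce <- as.numeric(tapply(s$bin_centers, idx, mean))
  energy_spectrum(ce, fl, s$bin_width * group)
}

#' Rescale a spectrum to a fixed total photon count
#'
#' Multiplies every bin by a single factor so the fluence sums to `total`
#' (the per-detector-pixel photon budget of the simulation).
#'
#' @param s An [energy_spectrum()].
#' @param total Target total photon count (> 0).
#' @return An [energy_spectrum()] with `sum(fluence) == total`.
#' @export
normalize_total_counts <- function(s, total) {
  stopifnot(inherits(s, "energy_spectrum"), total > 0)
  tot <- sum(s$fluence)
  if (tot <= 0) {
    stop("zero_spectrum: cannot normalise an all-zero spectrum", call. = FALSE)
  }
  energy_spectrum(s$bin_centers, s$fluence * (total / tot), s$bin_width)
}

#' The full paper-style spectral channel set
#'
#' Convenience wrapper: build the 150 kVp reference spectrum, interpolate to
#' the 0.1 keV staging grid, average blocks of ten, and normalise to the total
#' photon budget.  Yields 131 channels centred at 20, 21, ..., 150 keV.
#'
#' @param total_counts Total photons per detector pixel (default 60000).
#' @param kvp Tube potential (kV), default 150.
#' @return An [energy_spectrum()] with 131 one-keV channels.
#' @export
reference_channel_spectrum <- function(total_counts = 60000, kvp = 150) {
  s <- build_source_spectrum(kvp)
  s <- interpolate_spectrum(s)
  s <- rebin_average(s, 10L)
  normalize_total_counts(s, total_counts)
}

#' Write / read a spectrum as two-column CSV
#'
#' @param s An [energy_spectrum()].
#' @param path CSV path (columns `energy_keV`, `photons_per_bin`).
#' @return `write_spectrum_csv` the path invisibly; `read_spectrum_csv` an
#'   [energy_spectrum()].
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "energy_spectrum"))
  utils::write.csv(data.frame(energy_keV = s$bin_centers,
                              photons_per_bin = s$fluence),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @param bin_width Bin width (keV); inferred from the grid when `NULL`.
#' @export
read_spectrum_csv <- function(path, bin_width = NULL) {
  df <- utils::read.csv(path)
  if (is.null(bin_width)) {
    bin_width <- stats::median(diff(df$energy_keV))
  }
  energy_spectrum(df$energy_keV, df$photons_per_bin, bin_width)
}
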