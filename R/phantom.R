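# Energy-resolved material phantoms.
#
# A spectral phantom is the ground truth of the simulation: a 3-way array of
# linear attenuation coefficients (energy x height x width, 1/cm) plus a label
# map of object ids.  Objects are hard-assigned circles with sinusoidally
# modulated density, mimicking relative density variations inside otherwise
# homogeneous materials.

#' Describe one phantom material
#'
#' @param name Material name resolvable by [get_mass_attenuation()].
#' @param density Nominal density (g/cm3); defaults to the packaged value.
#' @param modulation_amplitude Relative amplitude of the sinusoidal density
#'   modulation (`0 <= a < 1`), default 0.05.
#' @param modulation_period Spatial period of the modulation (pixels),
#'   default 25.
#' @return A `material_spec` list.
#' @export
material_spec <- function(name, density = NULL,
                          modulation_amplitude = 0.05,
                          modulation_period = 25) {
  info <- resolve_material(name)
  if (is.null(density)) density <- info$density
  stopifnot(is.finite(density), density > 0,
            modulation_amplitude >= 0, modulation_amplitude < 1,
            modulation_period > 0)
  structure(list(name = info$name, density = density,
                 modulation_amplitude = modulation_amplitude,
                 modulation_period = modulation_period),
            class = "material_spec")
}

#' Circle geometry helper for phantom objects
#'
#' @param cx,cy Centre (pixels, 1-based grid coordinates).
#' @param r Radius (pixels).
#' @return A list describing the circle.
#' @export
circle_shape <- function(cx, cy, r) {
  stopifnot(r > 0)
  list(type = "circle", cx = cx, cy = cy, r = r)
}

.default_shapes <- function(grid) {
  h <- grid[1]; w <- grid[2]
  radii <- round(c(0.14, 0.16, 0.12, 0.18) * min(h, w))
  list(circle_shape(0.25 * w, 0.25 * h, radii[1]),
       circle_shape(0.75 * w, 0.25 * h, radii[2]),
       circle_shape(0.25 * w, 0.75 * h, radii[3]),
       circle_shape(0.75 * w, 0.75 * h, radii[4]))
}

#' Material presets of the two reference phantoms
#'
#' Preset 1: water, olive oil, nitromethane, acetone.
#' Preset 2: methanol, ethylenediamine, aluminium, nitrobenzene.
#'
#' @param preset 1 or 2.
#' @param n_materials How many of the four materials to keep (reduced
#'   fixtures use 2).
#' @return List of [material_spec()].
#' @export
phantom_materials <- function(preset = 1, n_materials = 4) {
  names <- switch(as.character(preset),
    "1" = c("water", "olive_oil", "nitromethane", "acetone"),
    "2" = c("methanol", "ethylenediamine", "aluminium", "nitrobenzene"),
    stop("unknown_preset: preset must be 1 or 2", call. = FALSE))
  lapply(names[seq_len(n_materials)], material_spec)
}

#' Build an energy-resolved phantom
#'
#' Each object pixel gets `lac(E, r) = (mu/rho)(material, E) * rho(r)` with
#' `rho(r) = density * (1 + a * sin(2 * pi * x / period))` (modulation along
#' x); background pixels are exactly zero at every energy.
#'
#' @param materials List of [material_spec()], one per shape.
#' @param shapes List of [circle_shape()]; must be non-overlapping and inside
#'   the grid.  Defaults to four circles at the quadrant centres with radii
#'   between 12% and 18% of the grid size.
#' @param grid `c(height, width)` in pixels, default `c(100, 100)`.
#' @param energies Energy channel centres (keV), strictly increasing; default
#'   the 131 channels of [reference_channel_spectrum()].
#' @return A `spectral_phantom`: list with `lac` (E x H x W array, 1/cm),
#'   `energies`, `labels` (H x W integer map, 0 = background), `materials`,
#'   `shapes`.
#' @export
build_phantom <- function(materials,
                          shapes = NULL,
                          grid = c(100L, 100L),
                          energies = seq(20, 150, by = 1)) {
  if (is.unsorted(energies, strictly = TRUE)) {
    stop("invalid_energies: energies must be strictly increasing",
         call. = FALSE)
  }
  if (is.null(shapes)) {
    shapes <- .default_shapes(grid)[seq_along(materials)]
  }
  if (length(shapes) != length(materials)) {
    stop("invalid_shapes: need one material per shape", call. = FALSE)
  }
  h <- as.integer(grid[1]); w <- as.integer(grid[2])
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  labels <- matrix(0L, h, w)
  density_map <- matrix(0, h, w)
  for (i in seq_along(shapes)) {
    sh <- shapes[[i]]
    stopifnot(identical(sh$type, "circle"))
    if (sh$cx - sh$r < 0.5 || sh$cx + sh$r > w + 0.5 ||
        sh$cy - sh$r < 0.5 || sh$cy + sh$r > h + 0.5) {
      stop("invalid_shapes: shape ", i, " extends outside the grid",
           call. = FALSE)
    }
    inside <- (xs - sh$cx)^2 + (ys - sh$cy)^2 <= sh$r^2
    if (any(labels[inside] != 0L)) {
      stop("overlapping_shapes: shape ", i, " overlaps an earlier shape",
           call. = FALSE)
    }
    m <- materials[[i]]
    labels[inside] <- i
    mod <- 1 + m$modulation_amplitude *
      sin(2 * pi * xs[inside] / m$modulation_period)
    density_map[inside] <- m$density * mod
  }
  ne <- length(energies)
  lac <- matrix(0, ne, h * w)
  for (i in seq_along(materials)) {
    mask <- as.vector(labels == i)
    if (!any(mask)) next
    mu_rho <- get_mass_attenuation(materials[[i]]$name, energies)  # length ne
    # outer product energies x pixels
    lac[, mask] <- outer(mu_rho, density_map[mask])
  }
  dim(lac) <- c(ne, h, w)
  structure(list(lac = lac, energies = as.numeric(energies), labels = labels,
                 materials = materials, shapes = shapes),
            class = "spectral_phantom")
}

#' @export
print.spectral_phantom <- function(x, ...) {
  d <- dim(x$lac)
  cat(sprintf("<spectral_phantom> %d channels (%.4g-%.4g keV), %d x %d pixels, %d objects\n",
              d[1], min(x$energies), max(x$energies), d[2], d[3],
              length(unique(x$labels[x$labels > 0]))))
  invisible(x)
}

#' Centre-crop a spectral stack or phantom
#'
#' Spatial dimensions are cropped symmetrically (extra pixel trimmed from the
#' trailing side when the parity differs); the energy axis keeps a contiguous
#' block starting at the lowest channel, i.e. the highest-energy (lowest-flux)
#' channels are dropped.
#'
#' @param stack A `spectral_phantom` or [spectral_image_stack()].
#' @param spatial Target `c(height, width)` in pixels.
#' @param channels Target number of energy channels.
#' @return An object of the same class, cropped, with metadata adjusted.
#' @export
center_crop <- function(stack, spatial, channels) {
  arr_name <- if (inherits(stack, "spectral_phantom")) "lac" else "pixels"
  arr <- stack[[arr_name]]
  d <- dim(arr)
  spatial <- rep(as.integer(spatial), length.out = 2)
  channels <- as.integer(channels)
  if (channels > d[1] || spatial[1] > d[2] || spatial[2] > d[3]) {
    stop("crop_too_large: target dimensions exceed the source", call. = FALSE)
  }
  e_idx <- seq_len(channels)
  r0 <- (d[2] - spatial[1]) %/% 2
  c0 <- (d[3] - spatial[2]) %/% 2
  r_idx <- r0 + seq_len(spatial[1])
  c_idx <- c0 + seq_len(spatial[2])
  stack[[arr_name]] <- arr[e_idx, r_idx, c_idx, drop = FALSE]
  stack$energies <- stack$energies[e_idx]
  if (!is.null(stack$labels)) stack$labels <- stack$labels[r_idx, c_idx]
  stack
}
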