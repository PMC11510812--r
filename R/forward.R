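# Beer-Lambert forward projection and Poisson measurement noise.

#' Construct a spectral sinogram object
#'
#' @param attenuation Array (E x A x D) of line integrals (unitless).
#' @param energies Channel centres (keV).
#' @param geometry A [scan_geometry()] with `A` angles and `D` detector cells.
#' @param noisy Logical flag: has counting noise been applied?
#' @param pixel_size_cm Reconstruction-grid pixel size the projection assumed.
#' @param seed Optional noise seed (recorded for provenance).
#' @return A `spectral_sinogram` object.
#' @export
spectral_sinogram <- function(attenuation, energies, geometry, noisy = FALSE,
                              pixel_size_cm = NULL, seed = NULL) {
  d <- dim(attenuation)
  stopifnot(length(d) == 3, d[1] == length(energies),
            d[2] == length(geometry$angles), d[3] == geometry$detector_pixels)
  if (!all(is.finite(attenuation))) {
    stop("invalid_sinogram: non-finite attenuation values", call. = FALSE)
  }
  structure(list(attenuation = attenuation, energies = as.numeric(energies),
                 geometry = geometry, noisy = isTRUE(noisy),
                 pixel_size_cm = pixel_size_cm, seed = seed),
            class = "spectral_sinogram")
}

#' @export
print.spectral_sinogram <- function(x, ...) {
  d <- dim(x$attenuation)
  cat(sprintf("<spectral_sinogram> %d channels x %d angles x %d detectors (%s)\n",
              d[1], d[2], d[3], if (x$noisy) "noisy" else "noiseless"))
  invisible(x)
}

#' Pixel size implied by a geometry and grid
#'
#' The object grid is laid out so that its width spans the field of view of
#' the detector at the isocentre.
#'
#' @param g A [scan_geometry()].
#' @param grid_width Image width in pixels.
#' @return Pixel size (cm).
#' @export
pixel_size_for <- function(g, grid_width) {
  field_of_view(g) / grid_width
}

#' Project a spectral phantom into a sinogram
#'
#' Computes, channel by channel, the discrete line integral of the linear
#' attenuation coefficient along each source-detector ray (the exponent of the
#' poly-energetic Beer-Lambert law).  Rays are sampled at half-pixel steps
#' with bilinear interpolation; the operator is linear in the phantom.
#'
#' @param phantom A `spectral_phantom` (or any E x H x W stack-like object
#'   with `lac`/`pixels` and `energies`).
#' @param g A [scan_geometry()].
#' @param pixel_size_cm Pixel size (cm); default spans the field of view.
#' @param step_frac Ray sampling step as a fraction of the pixel size.
#' @return A noiseless [spectral_sinogram()].
#' @export
project <- function(phantom, g, pixel_size_cm = NULL, step_frac = 0.5) {
  arr <- if (!is.null(phantom$lac)) phantom$lac else phantom$pixels
  d <- dim(arr)
  if (is.null(pixel_size_cm)) pixel_size_cm <- pixel_size_for(g, d[3])
  half_diag <- 0.5 * pixel_size_cm * sqrt(d[2]^2 + d[3]^2)
  if (g$beam == "fan" && half_diag >= g$source_to_object) {
    stop("phantom_outside_fov: object grid reaches the source orbit",
         call. = FALSE)
  }
  if (pixel_size_cm * max(d[2], d[3]) > field_of_view(g) * sqrt(2) + 1e-9) {
    stop("phantom_outside_fov: grid wider than the detector field of view",
         call. = FALSE)
  }
  sino <- .cpp_project(as.numeric(arr), as.integer(d),
                       g$angles * pi / 180,
                       g$source_to_object, g$object_to_detector,
                       g$detector_pitch / 10, g$detector_pixels,
                       pixel_size_cm, g$beam == "fan", step_frac, FALSE)
  dim(sino) <- c(d[1], length(g$angles), g$detector_pixels)
  spectral_sinogram(sino, phantom$energies, g, noisy = FALSE,
                    pixel_size_cm = pixel_size_cm)
}

#' Adjoint of [project()] (unfiltered backprojection)
#'
#' Exact transpose of the sampling-based projector; used by the iterative
#' reconstruction.
#'
#' @param sino A [spectral_sinogram()].
#' @param grid `c(height, width)` of the image.
#' @param pixel_size_cm Pixel size (cm).
#' @param step_frac Must match the value used by [project()].
#' @return Array (E x H x W).
#' @export
project_adjoint <- function(sino, grid, pixel_size_cm = NULL,
                            step_frac = 0.5) {
  g <- sino$geometry
  d <- dim(sino$attenuation)
  if (is.null(pixel_size_cm)) {
    pixel_size_cm <- sino$pixel_size_cm %||% pixel_size_for(g, grid[2])
  }
  img <- .cpp_project(as.numeric(sino$attenuation),
                      as.integer(c(d[1], grid[1], grid[2])),
                      g$angles * pi / 180,
                      g$source_to_object, g$object_to_detector,
                      g$detector_pitch / 10, g$detector_pixels,
                      pixel_size_cm, g$beam == "fan", step_frac, TRUE)
  dim(img) <- c(d[1], grid[1], grid[2])
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Corrupt a sinogram with Poisson counting noise
#'
#' Implements the photon-counting noise model: for channel `E` with incident
#' fluence `I0(E)` the detected counts are
#' `N ~ Poisson(I0(E) * exp(-y))`, and the noisy line integral is recovered as
#' `y~ = log(I0(E) / max(N, 1))` (counts are clipped at one photon before the
#' logarithm, since a zero count carries no finite attenuation estimate).
#'
#' @param sino A noiseless [spectral_sinogram()].
#' @param spectrum An [energy_spectrum()] whose channels match the sinogram's
#'   energy grid; its fluence is the per-detector-pixel photon budget.
#' @param seed Integer seed making the draw reproducible.
#' @return A noisy [spectral_sinogram()].
#' @export
add_poisson_noise <- function(sino, spectrum, seed) {
  stopifnot(inherits(sino, "spectral_sinogram"),
            inherits(spectrum, "energy_spectrum"))
  if (length(spectrum$bin_centers) != length(sino$energies) ||
      max(abs(spectrum$bin_centers - sino$energies)) >
        1e-6 * spectrum$bin_width) {
    stop("misaligned_energies: spectrum and sinogram energy grids differ",
         call. = FALSE)
  }
  d <- dim(sino$attenuation)
  i0 <- spectrum$fluence
  lambda <- i0 * exp(-sino$attenuation)   # recycles i0 along channel axis
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  counts <- stats::rpois(length(lambda), lambda)
  counts <- pmax(counts, 1)
  ytilde <- log(i0 / counts)   # recycling again: i0 varies fastest, matches
  dim(ytilde) <- d
  spectral_sinogram(ytilde, sino$energies, sino$geometry, noisy = TRUE,
                    pixel_size_cm = sino$pixel_size_cm, seed = as.integer(seed))
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
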