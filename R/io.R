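# Artifact serialisation: multi-page 32-bit TIFF for array data (one page per
# energy channel) with a JSON sidecar for the metadata.  TIFF pages are
# affinely rescaled to [0, 1] on write (the scale and offset live in the
# sidecar), so arbitrary-valued stacks survive the float encoding.

.sidecar <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

.write_pages <- function(arr3, path) {
  d <- dim(arr3)
  lo <- min(arr3); hi <- max(arr3)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[1]), function(e) {
    matrix((arr3[e, , ] - lo) / scale, d[2], d[3])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  list(offset = lo, scale = scale, dim = d)
}

.read_pages <- function(path, meta) {
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  arr <- array(0, d)
  for (e in seq_len(d[1])) {
    arr[e, , ] <- pages[[e]] * meta$scale + meta$offset
  }
  arr
}

#' Save / load a spectral image stack
#'
#' Writes `<path>.tif` (one 32-bit page per channel) and `<path>.json`
#' (energies, provenance, scaling).
#'
#' @param stack A [spectral_image_stack()].
#' @param path Output path (`.tif` extension added if missing).
#' @return The TIFF path, invisibly / the restored object.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "spectral_image_stack"))
  if (!grepl("\\.tif$", path)) path <- paste0(path, ".tif")
  meta <- .write_pages(stack$pixels, path)
  jsonlite::write_json(
    list(type = "spectral_image_stack", energies = stack$energies,
         provenance = stack$provenance, tiff = meta),
    .sidecar(path), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!grepl("\\.tif$", path)) path <- paste0(path, ".tif")
  js <- jsonlite::read_json(.sidecar(path), simplifyVector = TRUE)
  stopifnot(identical(js$type, "spectral_image_stack"))
  spectral_image_stack(.read_pages(path, js$tiff), js$energies, js$provenance)
}

#' Save / load a spectral sinogram
#'
#' @param sino A [spectral_sinogram()].
#' @param path Output path (`.tif` extension added if missing).
#' @return The TIFF path, invisibly / the restored object.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "spectral_sinogram"))
  if (!grepl("\\.tif$", path)) path <- paste0(path, ".tif")
  meta <- .write_pages(sino$attenuation, path)
  g <- sino$geometry
  jsonlite::write_json(
    list(type = "spectral_sinogram", energies = sino$energies,
         noisy = sino$noisy, seed = sino$seed,
         pixel_size_cm = sino$pixel_size_cm,
         geometry = list(source_to_object = g$source_to_object,
                         object_to_detector = g$object_to_detector,
                         detector_pixels = g$detector_pixels,
                         detector_pitch = g$detector_pitch,
                         angles = g$angles, beam = g$beam),
         tiff = meta),
    .sidecar(path), digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  if (!grepl("\\.tif$", path)) path <- paste0(path, ".tif")
  js <- jsonlite::read_json(.sidecar(path), simplifyVector = TRUE)
  stopifnot(identical(js$type, "spectral_sinogram"))
  g <- js$geometry
  geom <- scan_geometry(g$source_to_object, g$object_to_detector,
                        g$detector_pixels, g$detector_pitch, g$angles, g$beam)
  spectral_sinogram(.read_pages(path, js$tiff), js$energies, geom,
                    noisy = js$noisy, pixel_size_cm = js$pixel_size_cm,
                    seed = js$seed)
}

#' Save / load a spectral phantom
#'
#' The LAC array goes to TIFF; energies and the label map go to the sidecar.
#'
#' @param phantom A `spectral_phantom`.
#' @param path Output path (`.tif` extension added if missing).
#' @return The TIFF path, invisibly / the restored object.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "spectral_phantom"))
  if (!grepl("\\.tif$", path)) path <- paste0(path, ".tif")
  meta <- .write_pages(phantom$lac, path)
  jsonlite::write_json(
    list(type = "spectral_phantom", energies = phantom$energies,
         labels = phantom$labels,
         materials = lapply(phantom$materials, function(m) {
           list(name = m$name, density = m$density,
                modulation_amplitude = m$modulation_amplitude,
                modulation_period = m$modulation_period)
         }),
         shapes = phantom$shapes, tiff = meta),
    .sidecar(path), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  if (!grepl("\\.tif$", path)) path <- paste0(path, ".tif")
  js <- jsonlite::read_json(.sidecar(path), simplifyVector = TRUE)
  stopifnot(identical(js$type, "spectral_phantom"))
  mats <- lapply(seq_len(nrow(js$materials)), function(i) {
    material_spec(js$materials$name[i], js$materials$density[i],
                  js$materials$modulation_amplitude[i],
                  js$materials$modulation_period[i])
  })
  structure(list(lac = .read_pages(path, js$tiff), energies = js$energies,
                 labels = matrix(as.integer(js$labels), nrow(js$labels)),
                 materials = mats, shapes = NULL),
            class = "spectral_phantom")
}

#' Save / load a trained denoising model
#'
#' Plain-text JSON checkpoint: configuration, block spec, training log and
#' all parameter arrays.
#'
#' @param model A `denoising_model`.
#' @param path Output `.json` path.
#' @return The path, invisibly / the restored model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "denoising_model"))
  flat <- lapply(model$params, function(layer) {
    lapply(layer, function(p) {
      if (is.matrix(p)) list(data = as.numeric(p), dim = dim(p)) else p
    })
  })
  jsonlite::write_json(
    list(type = "denoising_model", config = unclass(model$config),
         spec = unclass(model$spec), norm = as.list(model$norm),
         training_log = model$training_log, params = flat),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(js$type, "denoising_model"))
  params <- lapply(js$params, function(layer) {
    lapply(layer, function(p) {
      if (is.list(p) && !is.null(p$dim)) {
        matrix(p$data, p$dim[1], p$dim[2])
      } else if (is.list(p)) {
        unlist(p)
      } else {
        p
      }
    })
  })
  cfg <- structure(js$config, class = "model_config")
  spec <- block_spec(js$spec$block_shape, js$spec$overlap)
  structure(list(params = params, config = cfg, spec = spec,
                 norm = unlist(js$norm),
                 training_log = js$training_log),
            class = "denoising_model")
}
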