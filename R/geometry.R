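# Fan-beam scan geometry.

#' Define a fan-beam scan geometry
#'
#' Point source, linear (flat) detector.  The reconstruction field of view is
#' the detector width demagnified to the isocentre plane, so an object grid
#' spanning the FOV is fully sampled by every projection.
#'
#' @param source_to_object Source-to-isocentre distance (cm).
#' @param object_to_detector Isocentre-to-detector distance (cm).
#' @param detector_pixels Number of detector cells.
#' @param detector_pitch Detector cell pitch (mm).
#' @param angles Projection angles (degrees) in `[0, 360)`, pairwise distinct.
#' @param beam `"fan"` (default) or `"parallel"`; the parallel mode ignores
#'   the distances and is provided for analytic cross-checks.
#' @return A `scan_geometry` object.
#' @export
scan_geometry <- function(source_to_object = 57.50,
                          object_to_detector = 58.05,
                          detector_pixels = 256L,
                          detector_pitch = 0.8,
                          angles = seq(0, 359, by = 1),
                          beam = c("fan", "parallel")) {
  beam <- match.arg(beam)
  stopifnot(source_to_object > 0, object_to_detector >= 0,
            detector_pixels >= 1, detector_pitch > 0)
  angles <- as.numeric(angles)
  if (any(angles < 0 | angles >= 360)) {
    stop("invalid_geometry: angles must lie in [0, 360)", call. = FALSE)
  }
  if (anyDuplicated(angles)) {
    stop("invalid_geometry: projection angles must be pairwise distinct",
         call. = FALSE)
  }
  structure(list(source_to_object = source_to_object,
                 object_to_detector = object_to_detector,
                 detector_pixels = as.integer(detector_pixels),
                 detector_pitch = detector_pitch,
                 angles = angles,
                 beam = beam),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %s beam, SOD %.2f cm, ODD %.2f cm, %d x %.2f mm detector, %d angles\n",
              x$beam, x$source_to_object, x$object_to_detector,
              x$detector_pixels, x$detector_pitch, length(x$angles)))
  invisible(x)
}

#' Geometric magnification of a scan geometry
#'
#' Ratio of the source-to-detector to the source-to-object distance; an object
#' at the isocentre is magnified by this factor on the detector.
#'
#' @param g A [scan_geometry()].
#' @return Unitless magnification `(SOD + ODD) / SOD`.
#' @examples
#' magnification(scan_geometry(33.20, 27.00))
#' @export
magnification <- function(g) {
  stopifnot(inherits(g, "scan_geometry"))
  (g$source_to_object + g$object_to_detector) / g$source_to_object
}

#' Field of view of a geometry at the isocentre (cm)
#'
#' @param g A [scan_geometry()].
#' @return Width (cm) of the detector demagnified to the isocentre plane; for
#'   parallel beams, the physical detector width.
#' @export
field_of_view <- function(g) {
  stopifnot(inherits(g, "scan_geometry"))
  w <- g$detector_pixels * g$detector_pitch / 10
  if (g$beam == "fan") w / magnification(g) else w
}
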