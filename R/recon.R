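# Angular subset splitting and channel-wise filtered backprojection.

#' Construct a spectral image stack
#'
#' @param pixels Array (E x H x W) of reconstructed values (1/cm).
#' @param energies Channel centres (keV), strictly increasing.
#' @param provenance Free-text provenance (filter, subset, method).
#' @return A `spectral_image_stack` object.
#' @export
spectral_image_stack <- function(pixels, energies, provenance = "") {
  d <- dim(pixels)
  stopifnot(length(d) == 3, d[1] == length(energies))
  if (!all(is.finite(pixels))) {
    stop("invalid_stack: non-finite pixel values", call. = FALSE)
  }
  if (is.unsorted(energies, strictly = TRUE)) {
    stop("invalid_stack: energies must be strictly increasing", call. = FALSE)
  }
  structure(list(pixels = pixels, energies = as.numeric(energies),
                 provenance = provenance),
            class = "spectral_image_stack")
}

#' @export
print.spectral_image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<spectral_image_stack> %d channels x %d x %d [%s]\n",
              d[1], d[2], d[3], x$provenance))
  invisible(x)
}

#' Split a sinogram into K equally spaced angular subsets
#'
#' Subset `j` receives angle indices `j, j+K, j+2K, ...` (1-based), so every
#' subset is itself an equally spaced angle schedule and the subsets partition
#' the full set.  Reconstructions from different subsets then carry
#' independent measurement noise, the premise of the leave-one-out training
#' strategy.
#'
#' @param sino A [spectral_sinogram()].
#' @param K Number of subsets (`1 <= K <=` number of angles).
#' @return List with `split` (list `K`, `subsets` of 1-based index vectors)
#'   and `sinos` (list of K [spectral_sinogram()]s carrying their own angles).
#' @export
split_angles <- function(sino, K) {
  stopifnot(inherits(sino, "spectral_sinogram"))
  n <- length(sino$geometry$angles)
  K <- as.integer(K)
  if (K < 1L || K > n) {
    stop("invalid_split: K must be between 1 and the number of angles",
         call. = FALSE)
  }
  subsets <- lapply(seq_len(K), function(j) seq(j, n, by = K))
  sinos <- lapply(subsets, function(idx) {
    g <- sino$geometry
    gj <- scan_geometry(g$source_to_object, g$object_to_detector,
                        g$detector_pixels, g$detector_pitch,
                        g$angles[idx], g$beam)
    spectral_sinogram(sino$attenuation[, idx, , drop = FALSE],
                      sino$energies, gj, noisy = sino$noisy,
                      pixel_size_cm = sino$pixel_size_cm, seed = sino$seed)
  })
  list(split = list(K = K, subsets = subsets), sinos = sinos)
}

# frequency response of the reconstruction filter on a padded grid of length L
# sampled at pitch dv; returns a length-L real vector.
.fbp_filter_response <- function(L, dv, filter, cutoff) {
  # band-limited ramp from its exact space-domain kernel (avoids the DC bias
  # of sampling |f| directly)
  n <- seq_len(L) - 1L
  m <- pmin(n, L - n)
  h <- numeric(L)
  h[m == 0] <- 1 / (4 * dv^2)
  odd <- m %% 2 == 1
  h[odd] <- -1 / (pi^2 * m[odd]^2 * dv^2)
  H <- Re(stats::fft(h))
  f <- pmin(n, L - n) / (L * dv)      # cycles/cm, symmetric
  fn <- 1 / (2 * dv)
  w <- switch(filter,
    "ram-lak" = as.numeric(f <= cutoff * fn + 1e-12),
    "hann" = ifelse(f <= cutoff * fn,
                    0.5 * (1 + cos(pi * f / (cutoff * fn))), 0),
    stop("unknown_filter: '", filter, "'", call. = FALSE))
  H * w
}

#' Channel-wise filtered backprojection
#'
#' Reconstructs every energy channel independently.  Fan-beam data use the
#' standard flat-detector weighting (detector rebinned to the isocentre plane,
#' cosine pre-weight, ramp filtering, distance-weighted backprojection); the
#' per-angle weight is `2 * pi / n`, so a reconstruction from any equally
#' spaced angular subset is unbiased and subset reconstructions average to the
#' full-angle reconstruction.
#'
#' @param sino A [spectral_sinogram()].
#' @param filter `"ram-lak"` or `"hann"`.
#' @param cutoff Fraction `s` of the Nyquist frequency where the Ram-Lak
#'   response truncates / the Hann window reaches zero (`0 < s <= 1`).
#' @param grid `c(height, width)`; defaults to the square grid spanning the
#'   field of view at the sinogram's pixel size.
#' @param pixel_size_cm Pixel size (cm); defaults to the sinogram's value.
#' @return A [spectral_image_stack()].
#' @export
fbp_channelwise <- function(sino, filter = c("ram-lak", "hann"), cutoff = 1,
                            grid = NULL, pixel_size_cm = NULL) {
  stopifnot(inherits(sino, "spectral_sinogram"), cutoff > 0, cutoff <= 1)
  filter <- match.arg(filter)
  g <- sino$geometry
  if (length(g$angles) < 2L) {
    stop("invalid_geometry: need at least 2 angles for FBP", call. = FALSE)
  }
  if (is.null(pixel_size_cm)) {
    pixel_size_cm <- sino$pixel_size_cm %||%
      (field_of_view(g) / g$detector_pixels)
  }
  if (is.null(grid)) {
    n <- round(field_of_view(g) / pixel_size_cm)
    grid <- c(n, n)
  }
  d <- dim(sino$attenuation)
  ne <- d[1]; nang <- d[2]; ndet <- d[3]
  fan <- g$beam == "fan"
  M <- if (fan) magnification(g) else 1
  dv <- g$detector_pitch / 10 / M        # virtual detector pitch (cm)
  sdet <- (seq_len(ndet) - (ndet + 1) / 2) * dv
  pre_w <- if (fan) {
    g$source_to_object / sqrt(g$source_to_object^2 + sdet^2)
  } else {
    rep(1, ndet)
  }
  L <- 2^ceiling(log2(2 * ndet))
  H <- .fbp_filter_response(L, dv, filter, cutoff)

  q <- array(0, dim = c(ne, nang, ndet))
  for (e in seq_len(ne)) {
    p <- sino$attenuation[e, , , drop = TRUE]     # A x D
    if (is.null(dim(p))) p <- matrix(p, nang, ndet)
    p <- sweep(p, 2L, pre_w, `*`)
    pp <- matrix(0, L, nang)                      # detector axis first
    pp[seq_len(ndet), ] <- t(p)
    qq <- Re(stats::mvfft(stats::mvfft(pp) * H, inverse = TRUE)) / L
    q[e, , ] <- t(qq[seq_len(ndet), , drop = FALSE]) * dv
  }

  img <- .cpp_fbp_backproject(as.numeric(q), as.integer(c(ne, nang, ndet)),
                              g$angles * pi / 180, g$source_to_object,
                              dv, as.integer(grid[1]), as.integer(grid[2]),
                              pixel_size_cm, fan)
  img <- img * (2 * pi / nang) / 2
  dim(img) <- c(ne, grid[1], grid[2])
  spectral_image_stack(img, sino$energies,
                       sprintf("fbp[%s,s=%.2g,n=%d]", filter, cutoff, nang))
}

#' Mean of several spectral image stacks
#'
#' @param stacks List of [spectral_image_stack()]s with identical shapes.
#' @return A [spectral_image_stack()] holding the voxel-wise mean.
#' @export
average_stacks <- function(stacks) {
  stopifnot(length(stacks) >= 1)
  px <- stacks[[1]]$pixels
  if (length(stacks) > 1) {
    for (s in stacks[-1]) {
      if (!identical(dim(s$pixels), dim(px))) {
        stop("shape_mismatch: stacks differ in shape", call. = FALSE)
      }
      px <- px + s$pixels
    }
  }
  spectral_image_stack(px / length(stacks), stacks[[1]]$energies,
                       sprintf("mean-of-%d", length(stacks)))
}
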