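# Comparison methods: Low2High filter-pair self-supervision and
# total-variation regularised iterative reconstruction (FISTA).

#' Build the Low2High training pair from a full-angle sinogram
#'
#' Input is the low-pass reconstruction (Hann window, cutoff 0.2 of Nyquist),
#' target the standard Ram-Lak reconstruction of the *same* projections.
#' Noise lives predominantly above the Hann cutoff, so the pair approximates
#' a (low-noise input, noisy target) pair without splitting angles.
#'
#' @param sino A full-angle [spectral_sinogram()].
#' @param grid,pixel_size_cm Passed to [fbp_channelwise()].
#' @return A `training_pair` (input, target, `heldout_index = NA`).
#' @export
low2high_pairs <- function(sino, grid = NULL, pixel_size_cm = NULL) {
  input <- fbp_channelwise(sino, "hann", 0.2, grid, pixel_size_cm)
  target <- fbp_channelwise(sino, "ram-lak", 1.0, grid, pixel_size_cm)
  structure(list(input = input, target = target, heldout_index = NA_integer_),
            class = "training_pair")
}

#' Low2High denoising
#'
#' Trains the block-based network to predict the Ram-Lak reconstruction from
#' the Hann-filtered one, then applies it to the Hann-filtered reconstruction.
#'
#' @param sino A full-angle [spectral_sinogram()].
#' @param spec A [block_spec()].
#' @param config A [model_config()].
#' @param grid,pixel_size_cm Passed to [fbp_channelwise()].
#' @return List with `denoised` ([spectral_image_stack()]), `model`, and the
#'   training `pair`.
#' @export
low2high_denoise <- function(sino, spec, config = model_config(),
                             grid = NULL, pixel_size_cm = NULL) {
  pair <- low2high_pairs(sino, grid, pixel_size_cm)
  model <- train(list(pair), spec, config)
  den <- predict_stack(model, pair$input)
  den$provenance <- "low2high"
  list(denoised = den, model = model, pair = pair)
}

#' TV reconstruction configuration
#'
#' @param alpha Regularisation strength (>= 0).  The reference choices are 1
#'   for phantom preset 1, 0.5 for preset 2 and 0.035 for low-dose real data.
#' @param iterations FISTA iterations (default 100).
#' @param prox_iterations Inner iterations of the TV proximal solve.
#' @param seed Seed (recorded; the solver itself is deterministic apart from
#'   the power-iteration start vector).
#' @return A `tv_config` list.
#' @export
tv_config <- function(alpha, iterations = 100L, prox_iterations = 20L,
                      seed = 1L) {
  stopifnot(alpha >= 0, iterations >= 1, prox_iterations >= 1)
  structure(list(alpha = alpha, iterations = as.integer(iterations),
                 prox_iterations = as.integer(prox_iterations),
                 seed = as.integer(seed)),
            class = "tv_config")
}

# isotropic total variation of an (E, H, W) stack, per channel
.tv_value <- function(x) {
  d <- dim(x)
  gx <- x[, , c(2:d[3], d[3]), drop = FALSE] - x
  gy <- x[, c(2:d[2], d[2]), , drop = FALSE] - x
  mag <- sqrt(gx^2 + gy^2)
  apply(mag, 1, sum)
}

#' Isotropic total variation per channel
#'
#' Forward differences with replicated (Neumann) boundaries; no coupling
#' between energy channels.
#'
#' @param stack A [spectral_image_stack()] or (E, H, W) array.
#' @return Numeric vector of per-channel TV values.
#' @export
total_variation <- function(stack) {
  arr <- if (is.array(stack)) stack else stack$pixels
  .tv_value(arr)
}

# Chambolle dual iteration for prox_{lambda TV}, vectorised over channels.
# g: (E, H, W); returns the proximal point.
.tv_prox <- function(g, lambda, iters) {
  if (lambda <= 0) return(g)
  d <- dim(g)
  px <- array(0, d); py <- array(0, d)
  tau <- 0.25
  for (it in seq_len(iters)) {
    # divergence of (px, py) with the adjoint boundary convention
    div <- px - px[, , c(1, seq_len(d[3] - 1)), drop = FALSE]
    div[, , 1] <- px[, , 1]
    div[, , d[3]] <- -px[, , d[3] - 1, drop = FALSE]
    divy <- py - py[, c(1, seq_len(d[2] - 1)), , drop = FALSE]
    divy[, 1, ] <- py[, 1, ]
    divy[, d[2], ] <- -py[, d[2] - 1, , drop = FALSE]
    div <- div + divy
    u <- div - g / lambda
    gx <- u[, , c(2:d[3], d[3]), drop = FALSE] - u
    gx[, , d[3]] <- 0
    gy <- u[, c(2:d[2], d[2]), , drop = FALSE] - u
    gy[, d[2], ] <- 0
    denom <- 1 + tau * sqrt(gx^2 + gy^2)
    px <- (px + tau * gx) / denom
    py <- (py + tau * gy) / denom
  }
  div <- px - px[, , c(1, seq_len(d[3] - 1)), drop = FALSE]
  div[, , 1] <- px[, , 1]
  div[, , d[3]] <- -px[, , d[3] - 1, drop = FALSE]
  divy <- py - py[, c(1, seq_len(d[2] - 1)), , drop = FALSE]
  divy[, 1, ] <- py[, 1, ]
  divy[, d[2], ] <- -py[, d[2] - 1, , drop = FALSE]
  g - lambda * (div + divy)
}

# largest singular value of the single-channel projector by power iteration
.projector_norm <- function(g, grid, pixel_size_cm, iters = 30L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  x <- array(stats::rnorm(grid[1] * grid[2]), c(1L, grid[1], grid[2]))
  e0 <- 1
  for (i in seq_len(iters)) {
    x <- x / sqrt(sum(x^2))
    ph <- list(lac = x, energies = e0)
    s <- project(ph, g, pixel_size_cm)
    x <- project_adjoint(s, grid, pixel_size_cm)
  }
  # after normalising, one A^T A application scales x by sigma_max^2,
  # so ||x|| = sigma_max^2 and sigma_max = ||x||^(1/2) = (sum x^2)^(1/4)
  sum(x^2)^0.25
}

#' Total-variation regularised iterative reconstruction
#'
#' Minimises `0.5 * ||A x - y||^2 + alpha * TV(x)` channel-by-channel with
#' FISTA; the TV proximal step uses a dual (Chambolle) inner iteration.  All
#' channels are advanced together (the objective is separable across
#' channels), with one multi-channel projection per iteration.  TV is purely
#' spatial: there is deliberately no regularisation along the energy axis.
#'
#' @param sino A [spectral_sinogram()].
#' @param config A [tv_config()].
#' @param grid `c(height, width)`; defaults to the FOV-spanning square grid.
#' @param pixel_size_cm Pixel size (cm); defaults to the sinogram's value.
#' @param verbose Print the objective every 10 iterations.
#' @return A [spectral_image_stack()]; attribute `objective` holds the
#'   per-iteration objective values.
#' @export
tv_reconstruct <- function(sino, config, grid = NULL, pixel_size_cm = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(sino, "spectral_sinogram"), inherits(config, "tv_config"))
  g <- sino$geometry
  if (is.null(pixel_size_cm)) {
    pixel_size_cm <- sino$pixel_size_cm %||%
      (field_of_view(g) / g$detector_pixels)
  }
  if (is.null(grid)) {
    n <- round(field_of_view(g) / pixel_size_cm)
    grid <- c(n, n)
  }
  d <- dim(sino$attenuation)
  ne <- d[1]
  y <- sino$attenuation
  sigma <- .projector_norm(g, grid, pixel_size_cm, seed = config$seed)
  L <- sigma^2
  step <- 1 / L
  x <- array(0, c(ne, grid[1], grid[2]))
  z <- x
  tk <- 1
  obj <- numeric(config$iterations)
  for (it in seq_len(config$iterations)) {
    ph <- list(lac = z, energies = sino$energies)
    res <- project(ph, g, pixel_size_cm)$attenuation - y
    grad <- project_adjoint(
      spectral_sinogram(res, sino$energies, g, noisy = FALSE,
                        pixel_size_cm = pixel_size_cm),
      grid, pixel_size_cm)
    x_new <- .tv_prox(z - step * grad, config$alpha * step,
                      config$prox_iterations)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- x_new + ((tk - 1) / t_new) * (x_new - x)
    x <- x_new
    tk <- t_new
    ph <- list(lac = x, energies = sino$energies)
    fid <- 0.5 * sum((project(ph, g, pixel_size_cm)$attenuation - y)^2)
    obj[it] <- fid + config$alpha * sum(.tv_value(x))
    if (!is.finite(obj[it])) {
      stop("divergence: objective became non-finite at iteration ", it,
           call. = FALSE)
    }
    # adaptive restart: drop momentum whenever the objective increases
    if (it > 1 && obj[it] > obj[it - 1]) {
      z <- x
      tk <- 1
    }
    if (verbose && it %% 10 == 0) {
      message(sprintf("iter %3d  objective %.6g", it, obj[it]))
    }
  }
  out <- spectral_image_stack(x, sino$energies,
                              sprintf("ir-tv[alpha=%g,%d it]",
                                      config$alpha, config$iterations))
  attr(out, "objective") <- obj
  out
}
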