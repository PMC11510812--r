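# Leave-one-out self-supervised training on angular-subset reconstructions.
#
# The denoiser never sees clean data: each of the K subset reconstructions
# takes a turn as the target while the mean of the other K-1 serves as the
# input.  Because subsets hold mutually exclusive projections, input and
# target carry independent noise realisations of the same object, so the
# minimiser of the expected squared error is the clean image.  At inference
# the network is applied to the mean of all K reconstructions.

#' Model and training configuration
#'
#' @param base_channels U-Net feature channels at the first level.
#' @param lr Adam learning rate.
#' @param epochs Training epochs (full passes over all blocks).
#' @param batch_size Blocks per gradient step.
#' @param seed Integer seed driving weight initialisation and block
#'   shuffling.
#' @return A `model_config` list.
#' @export
model_config <- function(base_channels = 32, lr = 1e-4, epochs = 100,
                         batch_size = 32, seed = 1L) {
  stopifnot(base_channels >= 1, lr > 0, epochs >= 1, batch_size >= 1)
  structure(list(depth = 3L, base_channels = as.integer(base_channels),
                 activation = "relu", norm = "batch", pooling = "max",
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build the K leave-one-out training pairs
#'
#' Pair `j` has target = reconstruction `j` and input = mean of the other
#' `K - 1` reconstructions.  The mean over `j` of all inputs equals the mean
#' of all K reconstructions (an exact algebraic identity), which is what the
#' trained network later receives at inference.
#'
#' @param recons List of K (>= 2) [spectral_image_stack()]s of equal shape.
#' @return List of K `training_pair`s: lists with `input`, `target`
#'   ([spectral_image_stack()]s) and `heldout_index`.
#' @export
make_loo_pairs <- function(recons) {
  K <- length(recons)
  if (K < 2) {
    stop("need_two_subsets: leave-one-out pairing requires K >= 2",
         call. = FALSE)
  }
  d <- dim(recons[[1]]$pixels)
  for (r in recons) {
    if (!identical(dim(r$pixels), d)) {
      stop("shape_mismatch: reconstructions differ in shape", call. = FALSE)
    }
  }
  total <- Reduce(`+`, lapply(recons, `[[`, "pixels"))
  lapply(seq_len(K), function(j) {
    input <- (total - recons[[j]]$pixels) / (K - 1)
    structure(list(
      input = spectral_image_stack(input, recons[[j]]$energies,
                                   sprintf("loo-mean-excl-%d", j)),
      target = recons[[j]],
      heldout_index = j
    ), class = "training_pair")
  })
}

# stack training blocks from all pairs: returns (H, W, n, E) arrays
.pair_blocks <- function(pairs, spec) {
  xs <- list(); ys <- list()
  for (p in pairs) {
    bx <- extract_blocks(p$input, spec)
    by <- extract_blocks(p$target, spec)
    xs[[length(xs) + 1L]] <- bx$blocks
    ys[[length(ys) + 1L]] <- by$blocks
  }
  bs <- dim(xs[[1]])[1:3]
  n_each <- vapply(xs, function(a) dim(a)[4], 1)
  x <- array(unlist(xs), dim = c(bs, sum(n_each)))
  y <- array(unlist(ys), dim = c(bs, sum(n_each)))
  # (E, H, W, n) -> (H, W, n, E): energy depth becomes the channel axis
  list(x = aperm(x, c(2, 3, 4, 1)), y = aperm(y, c(2, 3, 4, 1)))
}

#' Train the denoising network on leave-one-out pairs
#'
#' Minimises the mean squared error between the network's prediction on input
#' blocks and the corresponding target blocks (Adam, fixed epoch schedule, no
#' validation split).  The energy depth of each block maps to the network's
#' channel axis.
#'
#' @param pairs List of `training_pair`s from [make_loo_pairs()] (or a single
#'   pair in a list, as in the filter-pair baseline).
#' @param spec A [block_spec()].
#' @param config A [model_config()].
#' @param verbose Print per-epoch losses.
#' @return A `denoising_model`: list with `params`, `config`, `spec`,
#'   `training_log` (mean loss per epoch).
#' @export
train <- function(pairs, spec, config = model_config(), verbose = FALSE) {
  stopifnot(inherits(spec, "block_spec"), inherits(config, "model_config"))
  c_e <- spec$block_shape[1]
  dat <- .pair_blocks(pairs, spec)
  n <- dim(dat$x)[3]
  # normalise the data scale once (scalar affine map, inverted at inference)
  norm_mean <- mean(dat$x)
  norm_sd <- stats::sd(as.vector(dat$x))
  if (!is.finite(norm_sd) || norm_sd == 0) norm_sd <- 1
  dat$x <- (dat$x - norm_mean) / norm_sd
  dat$y <- (dat$y - norm_mean) / norm_sd
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  params <- unet_init(c_e, c_e, config$base_channels)
  opt <- .adam_init(params)
  log <- numeric(config$epochs)
  bsz <- config$batch_size
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / bsz)
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1) * bsz + 1):min(bi * bsz, n)]
      xb <- dat$x[, , idx, , drop = FALSE]
      yb <- dat$y[, , idx, , drop = FALSE]
      fw <- unet_forward(params, xb, training = TRUE)
      resid <- fw$y - yb
      loss <- mean(resid^2)
      ep_loss <- ep_loss + loss * length(idx)
      dy <- resid * (2 / length(resid))
      grads <- unet_backward(params, fw$cache, dy)
      params <- .bn_update_running(params, fw$cache)
      st <- .adam_step(params, grads, opt, config$lr)
      params <- st$params
      opt <- st$opt
    }
    log[ep] <- ep_loss / n
    if (verbose) message(sprintf("epoch %3d  mse %.6g", ep, log[ep]))
  }
  structure(list(params = params, config = config, spec = spec,
                 norm = c(mean = norm_mean, sd = norm_sd),
                 training_log = log),
            class = "denoising_model")
}

#' @export
print.denoising_model <- function(x, ...) {
  cat(sprintf("<denoising_model> base %d, %d epochs, final mse %.4g\n",
              x$config$base_channels, length(x$training_log),
              x$training_log[length(x$training_log)]))
  invisible(x)
}

#' Apply a trained model blockwise to a stack
#'
#' @param model A `denoising_model`.
#' @param stack A [spectral_image_stack()].
#' @param batch_size Blocks per forward pass.
#' @return A denoised [spectral_image_stack()].
#' @export
predict_stack <- function(model, stack, batch_size = 64L) {
  spec <- model$spec
  eb <- extract_blocks(stack, spec)
  n <- dim(eb$blocks)[4]
  nm <- if (is.null(model$norm)) c(mean = 0, sd = 1) else model$norm
  out <- array(0, dim = dim(eb$blocks))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- aperm(eb$blocks[, , , idx, drop = FALSE], c(2, 3, 4, 1))
    xb <- (xb - nm[["mean"]]) / nm[["sd"]]
    fw <- unet_forward(model$params, xb, training = FALSE)
    out[, , , idx] <- aperm(fw$y, c(4, 1, 2, 3)) * nm[["sd"]] + nm[["mean"]]
  }
  px <- assemble_blocks(out, eb$origins, dim(stack$pixels))
  spectral_image_stack(px, stack$energies,
                       paste0(stack$provenance, "+denoised"))
}

#' Denoise the averaged reconstruction with a trained model
#'
#' Inference input is the mean of the K subset reconstructions, which equals
#' the mean of the K leave-one-out training inputs.
#'
#' @param model A `denoising_model` trained with a matching [block_spec()].
#' @param recons List of K [spectral_image_stack()]s.
#' @return A denoised [spectral_image_stack()].
#' @export
denoise <- function(model, recons) {
  avg <- average_stacks(recons)
  if (dim(avg$pixels)[1] < model$spec$block_shape[1]) {
    stop("shape_mismatch: stack has fewer channels than the block depth",
         call. = FALSE)
  }
  predict_stack(model, avg)
}
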