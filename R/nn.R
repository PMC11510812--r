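# A small convolutional U-Net with hand-written forward and backward passes.
#
# Layout convention for activations: 4-way arrays (H, W, N, C) so that
# channel-wise statistics reduce to column operations on a (H*W*N) x C matrix
# view, and channel concatenation is plain vector concatenation.  Convolutions
# are 3x3 / padding 1 (im2col + BLAS matrix product); the final projection is
# 1x1.  Each 3x3 convolution is followed by batch normalisation and ReLU;
# downsampling is 2x2 max pooling and upsampling nearest-neighbour.

.he_init <- function(n_out, n_in_eff) {
  matrix(stats::rnorm(n_out * n_in_eff, sd = sqrt(2 / n_in_eff)),
         n_out, n_in_eff)
}

.new_conv <- function(c_in, c_out, k = 3) {
  list(W = .he_init(c_out, c_in * k * k), b = numeric(c_out), k = k,
       c_in = c_in, c_out = c_out)
}

.new_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c), momentum = 0.1, eps = 1e-5)
}

#' Create an untrained U-Net of depth 3
#'
#' @param c_in,c_out Input/output channel counts (the energy depth of a
#'   training block).
#' @param base_channels Feature channels at the first level; doubled per
#'   level.
#' @return List of layer parameter lists (opaque; consumed by
#'   [unet_forward()]).
#' @keywords internal
unet_init <- function(c_in, c_out, base_channels = 8) {
  b <- base_channels
  list(
    enc1a = .new_conv(c_in, b),      bn1a = .new_bn(b),
    enc1b = .new_conv(b, b),         bn1b = .new_bn(b),
    enc2a = .new_conv(b, 2 * b),     bn2a = .new_bn(2 * b),
    enc2b = .new_conv(2 * b, 2 * b), bn2b = .new_bn(2 * b),
    bot_a = .new_conv(2 * b, 4 * b), bn3a = .new_bn(4 * b),
    bot_b = .new_conv(4 * b, 4 * b), bn3b = .new_bn(4 * b),
    dec2a = .new_conv(6 * b, 2 * b), bn4a = .new_bn(2 * b),
    dec2b = .new_conv(2 * b, 2 * b), bn4b = .new_bn(2 * b),
    dec1a = .new_conv(3 * b, b),     bn5a = .new_bn(b),
    dec1b = .new_conv(b, b),         bn5b = .new_bn(b),
    head = .new_conv(b, c_out, k = 1)
  )
}

# ---- primitive layers -------------------------------------------------------

.conv3_fwd <- function(x, layer) {
  d <- dim(x)
  m <- prod(d[1:3])
  cols <- .cpp_im2col3(x, d[1], d[2], d[3], d[4])   # m x (c_in*9)
  y <- cols %*% t(layer$W) + rep(layer$b, each = m)
  dim(y) <- c(d[1], d[2], d[3], layer$c_out)
  list(y = y, cols = cols, dims = d)
}

.conv3_bwd <- function(cache, layer, dy) {
  d <- dim(dy)
  dim(dy) <- c(prod(d[1:3]), d[4])
  dW <- t(crossprod(cache$cols, dy))    # (c_out) x (c_in*9)
  db <- colSums(dy)
  dcols <- dy %*% layer$W               # m x (c_in*9)
  dx <- .cpp_col2im3(dcols, cache$dims[1], cache$dims[2], cache$dims[3],
                     cache$dims[4])
  dim(dx) <- cache$dims
  list(dx = dx, dW = dW, db = db)
}

.conv1_fwd <- function(x, layer) {
  d <- dim(x)
  m <- prod(d[1:3])
  xm <- x
  dim(xm) <- c(m, d[4])
  y <- xm %*% t(layer$W) + rep(layer$b, each = m)
  dim(y) <- c(d[1:3], layer$c_out)
  list(y = y, xm = xm, dims = d)
}

.conv1_bwd <- function(cache, layer, dy) {
  d <- dim(dy)
  dim(dy) <- c(prod(d[1:3]), d[4])
  dW <- t(crossprod(cache$xm, dy))
  db <- colSums(dy)
  dx <- dy %*% layer$W
  dim(dx) <- cache$dims
  list(dx = dx, dW = dW, db = db)
}

.bn_fwd <- function(x, layer, training) {
  d <- dim(x)
  m <- prod(d[1:3])
  c <- d[4]
  xm <- x
  dim(xm) <- c(m, c)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
  } else {
    mu <- layer$run_mean
    va <- layer$run_var
  }
  inv_sd <- 1 / sqrt(va + layer$eps)
  xhat <- .cpp_bn_apply(xm, m, mu, inv_sd, numeric(c))
  y <- .cpp_bn_apply(xhat, m, numeric(c), layer$gamma, layer$beta)
  dim(y) <- d
  dim(xhat) <- c(m, c)
  list(y = y, xhat = xhat, inv_sd = inv_sd, dims = d,
       batch_mean = mu, batch_var = va)
}

.bn_bwd <- function(cache, layer, dy) {
  d <- cache$dims
  m <- prod(d[1:3])
  c <- d[4]
  dim(dy) <- c(m, c)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  # standard batch-norm gradient
  dxhat <- .cpp_bn_apply(dy, m, numeric(c), layer$gamma, numeric(c))
  dim(dxhat) <- c(m, c)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  # dx = (dxhat - m1 - xhat * m2) * inv_sd
  t2 <- .cpp_bn_apply(cache$xhat, m, numeric(c), m2, m1)
  dx <- .cpp_bn_apply(dxhat - t2, m, numeric(c), cache$inv_sd, numeric(c))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

.upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

.upsample2_bwd <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1, d[1], by = 2); i2 <- seq(2, d[1], by = 2)
  j1 <- seq(1, d[2], by = 2); j2 <- seq(2, d[2], by = 2)
  dy[i1, j1, , , drop = FALSE] + dy[i1, j2, , , drop = FALSE] +
    dy[i2, j1, , , drop = FALSE] + dy[i2, j2, , , drop = FALSE]
}

.cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- c(a, b)
  dim(out) <- c(da[1:3], da[4] + db[4])
  out
}

# conv3 + BN + ReLU composite
.cbr_fwd <- function(x, params, conv_name, bn_name, training) {
  cv <- .conv3_fwd(x, params[[conv_name]])
  bn <- .bn_fwd(cv$y, params[[bn_name]], training)
  rl <- .relu_fwd(bn$y)
  list(y = rl$y, conv = cv, bn = bn, mask = rl$mask)
}

.cbr_bwd <- function(cache, params, conv_name, bn_name, dy, grads) {
  dy <- dy * cache$mask
  bnb <- .bn_bwd(cache$bn, params[[bn_name]], dy)
  grads[[bn_name]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
  cvb <- .conv3_bwd(cache$conv, params[[conv_name]], bnb$dx)
  grads[[conv_name]] <- list(W = cvb$dW, b = cvb$db)
  list(dx = cvb$dx, grads = grads)
}

# ---- full network -----------------------------------------------------------

#' U-Net forward pass
#'
#' @param params Parameter list from [unet_init()].
#' @param x Input activations, array (H, W, N, C).
#' @param training Use batch statistics (`TRUE`) or running statistics.
#' @return List with `y` (output array) and `cache` (for the backward pass).
#' @keywords internal
unet_forward <- function(params, x, training = TRUE) {
  e1a <- .cbr_fwd(x, params, "enc1a", "bn1a", training)
  e1b <- .cbr_fwd(e1a$y, params, "enc1b", "bn1b", training)
  d1 <- dim(e1b$y)
  p1 <- .cpp_maxpool2(e1b$y, d1[1], d1[2], d1[3], d1[4])
  x2 <- p1$y; dim(x2) <- c(d1[1] / 2, d1[2] / 2, d1[3], d1[4])

  e2a <- .cbr_fwd(x2, params, "enc2a", "bn2a", training)
  e2b <- .cbr_fwd(e2a$y, params, "enc2b", "bn2b", training)
  d2 <- dim(e2b$y)
  p2 <- .cpp_maxpool2(e2b$y, d2[1], d2[2], d2[3], d2[4])
  x3 <- p2$y; dim(x3) <- c(d2[1] / 2, d2[2] / 2, d2[3], d2[4])

  b_a <- .cbr_fwd(x3, params, "bot_a", "bn3a", training)
  b_b <- .cbr_fwd(b_a$y, params, "bot_b", "bn3b", training)

  u2 <- .upsample2(b_b$y)
  c2 <- .cat_ch(e2b$y, u2)
  d2a <- .cbr_fwd(c2, params, "dec2a", "bn4a", training)
  d2b <- .cbr_fwd(d2a$y, params, "dec2b", "bn4b", training)

  u1 <- .upsample2(d2b$y)
  c1 <- .cat_ch(e1b$y, u1)
  d1a <- .cbr_fwd(c1, params, "dec1a", "bn5a", training)
  d1b <- .cbr_fwd(d1a$y, params, "dec1b", "bn5b", training)

  hd <- .conv1_fwd(d1b$y, params$head)
  cache <- list(e1a = e1a, e1b = e1b, p1 = p1, d1 = d1,
                e2a = e2a, e2b = e2b, p2 = p2, d2 = d2,
                b_a = b_a, b_b = b_b,
                d2a = d2a, d2b = d2b, d1a = d1a, d1b = d1b,
                hd = hd, skip2_ch = d2[4], skip1_ch = d1[4])
  list(y = hd$y, cache = cache)
}

#' U-Net backward pass
#'
#' @param params Parameter list.
#' @param cache Cache from [unet_forward()].
#' @param dy Gradient of the loss w.r.t. the network output.
#' @return Named list of parameter gradients.
#' @keywords internal
unet_backward <- function(params, cache, dy) {
  grads <- list()
  hb <- .conv1_bwd(cache$hd, params$head, dy)
  grads$head <- list(W = hb$dW, b = hb$db)

  r <- .cbr_bwd(cache$d1b, params, "dec1b", "bn5b", hb$dx, grads)
  grads <- r$grads
  r <- .cbr_bwd(cache$d1a, params, "dec1a", "bn5a", r$dx, grads)
  grads <- r$grads
  dc1 <- r$dx
  n1 <- cache$skip1_ch
  dskip1 <- dc1[, , , seq_len(n1), drop = FALSE]
  du1 <- dc1[, , , -seq_len(n1), drop = FALSE]
  dd2b <- .upsample2_bwd(du1)

  r <- .cbr_bwd(cache$d2b, params, "dec2b", "bn4b", dd2b, grads)
  grads <- r$grads
  r <- .cbr_bwd(cache$d2a, params, "dec2a", "bn4a", r$dx, grads)
  grads <- r$grads
  dc2 <- r$dx
  n2 <- cache$skip2_ch
  dskip2 <- dc2[, , , seq_len(n2), drop = FALSE]
  du2 <- dc2[, , , -seq_len(n2), drop = FALSE]
  db_b <- .upsample2_bwd(du2)

  r <- .cbr_bwd(cache$b_b, params, "bot_b", "bn3b", db_b, grads)
  grads <- r$grads
  r <- .cbr_bwd(cache$b_a, params, "bot_a", "bn3a", r$dx, grads)
  grads <- r$grads
  dx3 <- r$dx
  dp2 <- .cpp_maxpool2_bwd(dx3, cache$p2$argmax, prod(cache$d2))
  dim(dp2) <- cache$d2
  de2b <- dp2 + dskip2

  r <- .cbr_bwd(cache$e2b, params, "enc2b", "bn2b", de2b, grads)
  grads <- r$grads
  r <- .cbr_bwd(cache$e2a, params, "enc2a", "bn2a", r$dx, grads)
  grads <- r$grads
  dx2 <- r$dx
  dp1 <- .cpp_maxpool2_bwd(dx2, cache$p1$argmax, prod(cache$d1))
  dim(dp1) <- cache$d1
  de1b <- dp1 + dskip1

  r <- .cbr_bwd(cache$e1b, params, "enc1b", "bn1b", de1b, grads)
  grads <- r$grads
  r <- .cbr_bwd(cache$e1a, params, "enc1a", "bn1a", r$dx, grads)
  r$grads
}

# update batch-norm running statistics after a training-mode forward pass
.bn_update_running <- function(params, cache) {
  pairs <- list(c("bn1a", "e1a"), c("bn1b", "e1b"), c("bn2a", "e2a"),
                c("bn2b", "e2b"), c("bn3a", "b_a"), c("bn3b", "b_b"),
                c("bn4a", "d2a"), c("bn4b", "d2b"), c("bn5a", "d1a"),
                c("bn5b", "d1b"))
  for (p in pairs) {
    bn <- params[[p[1]]]
    cb <- cache[[p[2]]]$bn
    mom <- bn$momentum
    params[[p[1]]]$run_mean <- (1 - mom) * bn$run_mean + mom * cb$batch_mean
    params[[p[1]]]$run_var <- (1 - mom) * bn$run_var + mom * cb$batch_var
  }
  params
}

# ---- Adam -------------------------------------------------------------------

.adam_init <- function(params) {
  flat <- list()
  for (ln in names(params)) {
    for (pn in intersect(names(params[[ln]]), c("W", "b", "gamma", "beta"))) {
      key <- paste(ln, pn, sep = ".")
      flat[[key]] <- list(m = params[[ln]][[pn]] * 0,
                          v = params[[ln]][[pn]] * 0)
    }
  }
  list(state = flat, t = 0, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

.adam_step <- function(params, grads, opt, lr) {
  opt$t <- opt$t + 1
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (ln in names(grads)) {
    for (pn in names(grads[[ln]])) {
      key <- paste(ln, pn, sep = ".")
      g <- grads[[ln]][[pn]]
      st <- opt$state[[key]]
      st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
      st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g^2
      opt$state[[key]] <- st
      params[[ln]][[pn]] <- params[[ln]][[pn]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + opt$eps)
    }
  }
  list(params = params, opt = opt)
}
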