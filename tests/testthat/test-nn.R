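test_that("analytic gradients match finite differences", {
  set.seed(42)
  p <- unet_init(2, 2, base_channels = 2)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  tg <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  fw <- unet_forward(p, x, training = TRUE)
  loss0 <- mean((fw$y - tg)^2)
  g <- unet_backward(p, fw$cache, (fw$y - tg) * (2 / length(fw$y)))
  eps <- 1e-6
  checks <- list(c("enc1a", "W"), c("bn2a", "gamma"), c("bot_b", "b"),
                 c("dec1a", "W"), c("bn5b", "beta"), c("head", "W"))
  for (ch in checks) {
    ln <- ch[1]; pn <- ch[2]
    i <- sample(length(p[[ln]][[pn]]), 1)
    p2 <- p
    p2[[ln]][[pn]][i] <- p2[[ln]][[pn]][i] + eps
    l2 <- mean((unet_forward(p2, x, TRUE)$y - tg)^2)
    num <- (l2 - loss0) / eps
    ana <- g[[ln]][[pn]][i]
    expect_lt(abs(num - ana) / max(abs(num), 1e-8), 1e-3)
  }
})

test_that("training is bitwise reproducible for a fixed seed", {
  set.seed(77)
  stack <- spectral_image_stack(array(rnorm(8 * 24 * 24), c(8, 24, 24)), 1:8)
  pair <- structure(list(input = stack, target = stack, heldout_index = 1L),
                    class = "training_pair")
  spec <- block_spec(c(4L, 16L, 16L), 0)
  cfg <- model_config(base_channels = 4, lr = 1e-3, epochs = 2, seed = 5)
  m1 <- train(list(pair), spec, cfg)
  m2 <- train(list(pair), spec, cfg)
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$params$head$W, m2$params$head$W)
  m3 <- train(list(pair), spec, model_config(4, 1e-3, 2, seed = 6))
  expect_false(identical(m1$training_log, m3$training_log))
})

test_that("the network overfits an identity task", {
  # smooth multi-channel field (image-like content, unlike white noise)
  n <- 32
  sm <- outer(sin(seq(0, 3 * pi, length.out = n)),
              cos(seq(0, 2 * pi, length.out = n)))
  arr <- array(0, c(8, n, n))
  for (e in 1:8) arr[e, , ] <- sm * (0.5 + 0.1 * e) + 0.05 * e
  stack <- spectral_image_stack(arr, 1:8)
  pair <- structure(list(input = stack, target = stack, heldout_index = 1L),
                    class = "training_pair")
  spec <- block_spec(c(4L, 16L, 16L), c(0.75, 0.5, 0.5))
  m <- train(list(pair), spec,
             model_config(base_channels = 8, lr = 5e-3, epochs = 20,
                          seed = 3))
  expect_lt(m$training_log[20], 0.1 * m$training_log[1])
  # training loss trends downwards overall
  expect_lt(mean(utils::tail(m$training_log, 3)),
            mean(utils::head(m$training_log, 3)))
})

test_that("block depth must match the network channel count", {
  stack <- spectral_image_stack(array(rnorm(8 * 16 * 16), c(8, 16, 16)), 1:8)
  pair <- structure(list(input = stack, target = stack, heldout_index = 1L),
                    class = "training_pair")
  m <- train(list(pair), block_spec(c(4L, 16L, 16L), 0),
             model_config(2, 1e-3, 1, seed = 1))
  bad <- spectral_image_stack(array(0, c(2, 16, 16)), 1:2)
  expect_error(denoise(m, list(bad, bad)), "shape_mismatch")
})
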