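test_that("MSE matches its definition on hand and brute-force fixtures", {
  f <- matrix(0, 2, 2)
  g <- f; g[1, 1] <- 1
  expect_equal(mse(f, f), 0)
  expect_equal(mse(f, g), 0.25)
  set.seed(2)
  a <- matrix(rnorm(30), 5); b <- matrix(rnorm(30), 5)
  acc <- 0
  for (i in 1:5) for (j in 1:6) acc <- acc + (a[i, j] - b[i, j])^2
  expect_equal(mse(a, b), acc / 30)
  expect_error(mse(a, matrix(0, 2, 2)), "shape_mismatch")
})

test_that("PSNR uses the joint peak and is scale invariant", {
  f <- matrix(c(1, 0, 0, 0), 2)
  g <- matrix(0, 2, 2)
  expect_equal(psnr(f, g), 20 * log10(1) - 10 * log10(0.25),
               tolerance = 1e-12)
  expect_equal(psnr(f, g), 6.0206, tolerance = 1e-4)
  expect_equal(psnr(f, f), Inf)
  expect_equal(psnr(3 * f, 3 * g), psnr(f, g), tolerance = 1e-12)
  # joint peak: the test image may set the peak
  f2 <- matrix(c(0.5, 0, 0, 0), 2)
  g2 <- matrix(c(1, 0, 0, 0), 2)
  expect_equal(psnr(f2, g2), 20 * log10(1) - 10 * log10(mse(f2, g2)))
  expect_equal(psnr(f2, g2, peak = "reference"),
               20 * log10(0.5) - 10 * log10(mse(f2, g2)))
})

test_that("SSIM is 1 for identical images, negative for anti-correlated ones", {
  set.seed(4)
  f <- matrix(rnorm(100), 10)
  expect_equal(ssim(f, f), 1)
  fz <- f - mean(f)   # exactly zero-mean: the covariance term sets the sign
  expect_lt(ssim(fz, -fz, window = 10L), 0)
  expect_equal(ssim(f, -f), ssim(-f, f))
})

test_that("SSIM with a full-image window equals the direct global formula", {
  set.seed(9)
  f <- matrix(runif(64), 8)
  g <- matrix(runif(64), 8)
  L <- diff(range(f))
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  n <- 64
  muf <- mean(f); mug <- mean(g)
  vf <- mean(f^2) - muf^2; vg <- mean(g^2) - mug^2
  cfg <- mean(f * g) - muf * mug
  direct <- ((2 * muf * mug + c1) * (2 * cfg + c2)) /
    ((muf^2 + mug^2 + c1) * (vf + vg + c2))
  expect_equal(ssim(f, g, window = 8L), direct, tolerance = 1e-12)
})

test_that("CNR matches its closed form and degenerates sensibly", {
  img <- matrix(0, 4, 4)
  img[1, 1:3] <- c(4, 5, 6)      # target: mean 5, sd 1
  img[3, 1:3] <- c(0, 1, 2)      # background: mean 1, sd 1
  tmask <- matrix(FALSE, 4, 4); tmask[1, 1:3] <- TRUE
  bmask <- matrix(FALSE, 4, 4); bmask[3, 1:3] <- TRUE
  expect_equal(cnr(img, roi_mask(tmask), roi_mask(bmask)), 2.0)
  # identical statistics give zero
  img2 <- img; img2[3, 1:3] <- c(4, 5, 6)
  expect_equal(cnr(img2, roi_mask(tmask), roi_mask(bmask)), 0)
  # constant disjoint regions with different means give the infinity sentinel
  img3 <- matrix(1, 4, 4); img3[1, ] <- 3
  expect_equal(cnr(img3, roi_mask(tmask), roi_mask(bmask)), Inf)
  expect_error(cnr(img, roi_mask(tmask), roi_mask(tmask)), "overlapping_rois")
})

test_that("channel-wise CNR of an iodine object rises across the K edge", {
  # two channels straddling the iodine K edge, equal noise in both
  set.seed(6)
  mats <- list(material_spec("iodine", density = 0.02,
                             modulation_amplitude = 0))
  ph <- build_phantom(mats, list(circle_shape(16, 16, 6)), c(32L, 32L),
                      energies = c(31, 35))
  noise <- array(rnorm(2 * 32 * 32, sd = 0.01), c(2, 32, 32))
  stack <- spectral_image_stack(ph$lac + noise, c(31, 35))
  target <- roi_circle(c(32, 32), 16, 16, 4)
  background <- roi_circle(c(32, 32), 4, 28, 3)
  ev <- evaluate_stack(stack, ph, cnr_rois = list(target = target,
                                                  background = background))
  expect_gt(ev$cnr_per_channel[2], 2 * ev$cnr_per_channel[1])
})

test_that("ROI profiles recover the attenuation curve used to build the phantom", {
  m <- material_spec("nitromethane", modulation_amplitude = 0)
  e <- seq(20, 150, by = 10)
  ph <- build_phantom(list(m), list(circle_shape(10, 10, 4)), c(20L, 20L), e)
  roi <- roi_circle(c(20, 20), 10, 10, 3)
  pr <- roi_profile(ph, roi)
  expect_equal(pr$mean, get_mass_attenuation("nitromethane", e) * m$density)
  expect_equal(pr$sd, rep(0, length(e)))
  expect_equal(pr$channel_averaged_sd, 0)

  # hand-computed single-channel statistics
  st <- spectral_image_stack(array(c(1, 2, 3, 4), c(1, 2, 2)), 50)
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  pr2 <- roi_profile(st, roi_mask(mask))
  expect_equal(pr2$mean, mean(c(1, 2, 4)))
  expect_equal(pr2$sd, sd(c(1, 2, 4)))
})

test_that("profile MSE reduces to its closed forms and the loop oracle", {
  p <- c(1, 2, 3, 4)
  expect_equal(profile_mse(p, p), list(mean = 0, sd = 0))
  off <- profile_mse(p + 0.5, p)
  expect_equal(off$mean, 0.25)
  expect_equal(off$sd, 0)
  set.seed(14)
  a <- rnorm(9); b <- rnorm(9)
  se <- vapply(1:9, function(i) (a[i] - b[i])^2, 1)
  expect_equal(profile_mse(a, b), list(mean = mean(se), sd = sd(se)))
  expect_error(profile_mse(1:3, 1:4), "length_mismatch")
})

test_that("evaluate_stack is consistent and reports round-trip losslessly", {
  ph <- build_phantom(phantom_materials(1, 2),
                      grid = c(32L, 32L), energies = c(45, 70, 100))
  ident <- spectral_image_stack(ph$lac, ph$energies)
  ev <- evaluate_stack(ident, ph)
  expect_true(all(ev$per_channel$ssim == 1))
  expect_true(all(is.infinite(ev$per_channel$psnr)))

  set.seed(15)
  noisy <- spectral_image_stack(ph$lac + array(rnorm(3 * 32 * 32, sd = 0.02),
                                               c(3, 32, 32)), ph$energies)
  roi <- roi_circle(c(32, 32), 8, 8, 3)
  ev2 <- evaluate_stack(noisy, ph, rois = list(obj = roi))
  # summary is recomputable from the per-channel rows
  expect_equal(ev2$summary$mean[1], mean(ev2$per_channel$psnr))
  expect_equal(ev2$summary$sd[2], sd(ev2$per_channel$ssim))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_metric_report(ev2, csv, js)
  back <- read_metric_report(csv, js)
  expect_equal(back$per_channel$psnr, ev2$per_channel$psnr)
  expect_equal(back$summary$mean, ev2$summary$mean)
  expect_equal(back$roi_stats$obj$profile_mse_mean,
               ev2$roi_stats$obj$profile_mse_mean)
})
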