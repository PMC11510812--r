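test_that("the filter pair splits the band: low-pass input, full-band target", {
  g <- test_geometry(n_angles = 120, ndet = 64, pitch_mm = 2.4)
  d <- disc_phantom(n = 48, r_cm = 1.5, mu = 0.3, ne = 1,
                    px_cm = field_of_view(g) / 48)
  zero <- spectral_sinogram(array(0, c(1, 120, 64)), d$energies[1], g,
                            pixel_size_cm = d$px)
  zp <- low2high_pairs(zero, grid = c(48, 48))
  expect_true(all(zp$input$pixels == 0))
  expect_true(all(zp$target$pixels == 0))

  sino <- project(d, g, d$px)
  pair <- low2high_pairs(sino, grid = c(48, 48))
  pow_above <- function(img, frac) {
    sp <- abs(stats::fft(img))^2
    n <- nrow(img)
    f <- pmin(0:(n - 1), n - 0:(n - 1)) / n
    rad <- sqrt(outer(f^2, f^2, `+`))
    sum(sp[rad > frac * 0.5])
  }
  expect_lt(pow_above(pair$input$pixels[1, , ], 0.2),
            pow_above(pair$target$pixels[1, , ], 0.2))
})

test_that("total variation vanishes for constants and zero data maps to zero", {
  const <- array(3.2, c(2, 10, 10))
  expect_equal(total_variation(const), c(0, 0))

  g <- test_geometry(n_angles = 40, ndet = 24, pitch_mm = 4)
  zero <- spectral_sinogram(array(0, c(1, 40, 24)), 50, g,
                            pixel_size_cm = 0.2)
  out <- tv_reconstruct(zero, tv_config(alpha = 0.5, iterations = 5),
                        grid = c(12, 12))
  expect_true(all(out$pixels == 0))
})

test_that("FISTA with alpha = 0 solves the least-squares problem", {
  # tiny 8x8 system with a dense linear-algebra oracle
  g <- scan_geometry(30, 30, 12L, 8, angles = seq(0, 342, by = 18))
  px <- field_of_view(g) / 8
  set.seed(19)
  xtrue <- array(0, c(1, 8, 8))
  xtrue[1, 3:6, 3:6] <- matrix(runif(16, 0.1, 0.4), 4)
  sino <- project(list(lac = xtrue, energies = 50), g, px)
  # dense operator by projecting unit basis images
  A <- matrix(0, length(sino$attenuation), 64)
  for (k in 1:64) {
    ek <- array(0, c(1, 8, 8)); ek[k] <- 1
    A[, k] <- as.vector(project(list(lac = ek, energies = 50), g, px)$attenuation)
  }
  xls <- qr.solve(qr(A, LAPACK = TRUE), as.vector(sino$attenuation))
  fit <- tv_reconstruct(sino, tv_config(alpha = 0, iterations = 500),
                        grid = c(8, 8), pixel_size_cm = px)
  rel <- sqrt(sum((as.vector(fit$pixels) - xls)^2) / sum(xls^2))
  expect_lt(rel, 1e-4)
  obj <- attr(fit, "objective")
  expect_lte(obj[length(obj)], obj[1])
})

test_that("stronger regularisation never increases the output TV", {
  fx <- make_fixture(c(8, 32, 32), seed = 23)
  sino <- fx$sinogram
  sub <- spectral_sinogram(sino$attenuation[1:2, , , drop = FALSE],
                           sino$energies[1:2], sino$geometry, noisy = TRUE,
                           pixel_size_cm = sino$pixel_size_cm)
  tvs <- vapply(c(0, 0.5, 2), function(a) {
    out <- tv_reconstruct(sub, tv_config(alpha = a, iterations = 30),
                          grid = c(32, 32))
    sum(total_variation(out))
  }, 1)
  expect_true(all(diff(tvs) < 0))
})
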