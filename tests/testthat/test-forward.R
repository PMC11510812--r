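test_that("magnification is (SOD + ODD) / SOD", {
  expect_equal(round(magnification(scan_geometry(33.20, 27.00)), 2), 1.81)
  expect_equal(magnification(scan_geometry(57.50, 58.05)), 115.55 / 57.50)
  expect_equal(magnification(scan_geometry(50, 0)), 1.0)
})

test_that("geometry invariants are enforced", {
  expect_error(scan_geometry(angles = c(0, 10, 10)), "invalid_geometry")
  expect_error(scan_geometry(angles = c(0, 361)), "invalid_geometry")
})

test_that("projection of an empty phantom is zero and the operator is linear", {
  g <- test_geometry()
  d <- disc_phantom(n = 32, r_cm = 1.2, mu = 0.3, ne = 2)
  zero <- list(lac = d$lac * 0, energies = d$energies)
  expect_true(all(project(zero, g, d$px)$attenuation == 0))
  s1 <- project(d, g, d$px)$attenuation
  s3 <- project(list(lac = 3 * d$lac, energies = d$energies), g, d$px)$attenuation
  expect_equal(s3, 3 * s1)
})

test_that("a central ray through a uniform disc integrates to the chord length", {
  g <- test_geometry(n_angles = 8, ndet = 49, pitch_mm = 2.4)
  d <- disc_phantom(n = 64, r_cm = 2, mu = 0.2, ne = 1, px_cm = 0.08)
  sino <- project(d, g, d$px)
  central <- sino$attenuation[1, , 25]   # detector centre cell, all angles
  expect_lt(max(abs(central - 2 * 2 * 0.2)) / (2 * 2 * 0.2), 0.02)
  # rotation consistency for a centred disc: profiles angle-independent
  prof <- sino$attenuation[1, , ]
  expect_lt(max(apply(prof, 2, function(v) diff(range(v)))), 0.02)
})

test_that("default scan geometry matches the synthetic protocol", {
  g <- scan_geometry()
  expect_equal(length(g$angles), 360L)
  expect_equal(g$detector_pixels, 256L)
  expect_equal(diff(g$angles)[1], 1)
})

test_that("the adjoint projector satisfies the inner-product identity", {
  g <- test_geometry(n_angles = 24, ndet = 20, pitch_mm = 4)
  set.seed(11)
  x <- array(rnorm(1 * 16 * 16), c(1, 16, 16))
  px <- field_of_view(g) / 16
  ax <- project(list(lac = x, energies = 50), g, px)
  y <- array(rnorm(length(ax$attenuation)), dim(ax$attenuation))
  aty <- project_adjoint(
    spectral_sinogram(y, 50, g, pixel_size_cm = px), c(16, 16), px)
  expect_equal(sum(ax$attenuation * y), sum(x * aty), tolerance = 1e-10)
})

test_that("Poisson corruption is unbiased, seeded, and mild at high flux", {
  g <- scan_geometry(detector_pixels = 64L, detector_pitch = 3.2,
                     angles = seq(0, 350, by = 10))
  ne <- 4
  sino0 <- spectral_sinogram(array(0, c(ne, 36, 64)), 1:4 * 10, g,
                             pixel_size_cm = 0.1)
  spec <- energy_spectrum(1:4 * 10, rep(1e6, 4), 10)
  noisy <- add_poisson_noise(sino0, spec, seed = 42)
  counts <- 1e6 * exp(-noisy$attenuation)
  # sample mean of counts within 3 sigma of the Poisson mean
  se <- sqrt(1e6 / length(counts))
  expect_lt(abs(mean(counts) - 1e6), 3 * se)

  # y~ -> y in the high-flux limit
  y <- array(0.5, c(ne, 36, 64))
  sino1 <- spectral_sinogram(y, 1:4 * 10, g, pixel_size_cm = 0.1)
  spec8 <- energy_spectrum(1:4 * 10, rep(1e8, 4), 10)
  ny <- add_poisson_noise(sino1, spec8, seed = 1)
  expect_lt(max(abs(ny$attenuation - y)) / 0.5, 0.01)

  # reproducibility and seed independence
  n1 <- add_poisson_noise(sino1, spec, seed = 7)
  n2 <- add_poisson_noise(sino1, spec, seed = 7)
  n3 <- add_poisson_noise(sino1, spec, seed = 8)
  expect_identical(n1$attenuation, n2$attenuation)
  r1 <- n1$attenuation - y
  r3 <- n3$attenuation - y
  expect_lt(abs(cor(as.vector(r1), as.vector(r3))), 0.05)

  expect_error(add_poisson_noise(sino1, energy_spectrum(1:3 * 10, rep(1, 3), 10),
                                 seed = 1),
               "misaligned_energies")
})

test_that("noise corruption leaves E[I0 exp(-y~)] = I0 exp(-y)", {
  g <- scan_geometry(detector_pixels = 128L, detector_pitch = 1.6,
                     angles = seq(0, 355, by = 5))
  y <- array(1.2, c(2, 72, 128))
  sino <- spectral_sinogram(y, c(30, 60), g, pixel_size_cm = 0.1)
  spec <- energy_spectrum(c(30, 60), c(2e4, 2e4), 30)
  noisy <- add_poisson_noise(sino, spec, seed = 3)
  lam <- 2e4 * exp(-1.2)
  counts <- 2e4 * exp(-noisy$attenuation)
  se <- sqrt(lam / length(counts))
  expect_lt(abs(mean(counts) - lam), 3 * se)
})
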