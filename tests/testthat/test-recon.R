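test_that("angular splitting follows the stride rule and partitions the angles", {
  g <- scan_geometry()   # 360 angles at 1 degree
  sino <- spectral_sinogram(array(0, c(1, 360, 256)), 50, g,
                            pixel_size_cm = 0.1)
  sp <- split_angles(sino, 4)
  expect_equal(length(sp$sinos), 4L)
  for (j in 1:4) {
    idx <- sp$split$subsets[[j]]
    expect_equal(idx, seq(j, 360, by = 4))
    a <- sp$sinos[[j]]$geometry$angles
    expect_equal(length(a), 90L)
    expect_equal(unique(diff(a)), 4)
    expect_equal(a[1], j - 1)
  }
  all_idx <- sort(unlist(sp$split$subsets))
  expect_equal(all_idx, 1:360)

  # K = 1 is the identity split
  sp1 <- split_angles(sino, 1)
  expect_equal(sp1$sinos[[1]]$attenuation, sino$attenuation)
  expect_equal(sp1$sinos[[1]]$geometry$angles, g$angles)

  # 180 projections at 2 degrees split into K = 2 sets of 90
  g2 <- scan_geometry(33.20, 27.00, 80L, 0.25 * 1.81 * 10 / 80 * 80,
                      angles = seq(0, 358, by = 2))
  s2 <- spectral_sinogram(array(0, c(1, 180, 80)), 30, g2,
                          pixel_size_cm = 0.02)
  sp2 <- split_angles(s2, 2)
  expect_equal(vapply(sp2$split$subsets, length, 1L), c(90L, 90L))

  expect_error(split_angles(s2, 200), "invalid_split")
})

test_that("FBP is linear and quantitatively recovers a uniform disc", {
  g <- test_geometry(n_angles = 180, ndet = 96, pitch_mm = 1.6)
  d <- disc_phantom(n = 64, r_cm = 2, mu = 0.25, ne = 1,
                    px_cm = field_of_view(g) / 64)
  sino <- project(d, g, d$px)
  expect_true(all(fbp_channelwise(
    spectral_sinogram(sino$attenuation * 0, d$energies, g,
                      pixel_size_cm = d$px))$pixels == 0))
  rec <- fbp_channelwise(sino, "ram-lak", 1, c(64, 64))
  interior <- disc_phantom(n = 64, r_cm = 1.4, ne = 1, px_cm = d$px)$inside
  expect_lt(abs(mean(rec$pixels[1, , ][interior]) - 0.25) / 0.25, 0.03)
  # exact linearity
  rec2 <- fbp_channelwise(
    spectral_sinogram(2 * sino$attenuation, d$energies, g,
                      pixel_size_cm = d$px), "ram-lak", 1, c(64, 64))
  expect_equal(rec2$pixels, 2 * rec$pixels)
  expect_error(fbp_channelwise(sino, "butterworth"), "'arg'")
})

test_that("subset reconstructions average exactly to the full reconstruction", {
  g <- test_geometry(n_angles = 120, ndet = 64, pitch_mm = 2.4)
  d <- disc_phantom(n = 48, r_cm = 1.5, mu = 0.3, ne = 2,
                    px_cm = field_of_view(g) / 48)
  sino <- project(d, g, d$px)
  full <- fbp_channelwise(sino, grid = c(48, 48))
  sp <- split_angles(sino, 4)
  subs <- lapply(sp$sinos, fbp_channelwise, grid = c(48, 48))
  expect_lt(max(abs(average_stacks(subs)$pixels - full$pixels)), 1e-6)
})

test_that("the Hann window suppresses high spatial frequencies", {
  g <- test_geometry(n_angles = 180, ndet = 96, pitch_mm = 1.6)
  d <- disc_phantom(n = 64, r_cm = 2, mu = 0.25, ne = 1,
                    px_cm = field_of_view(g) / 64)
  sino <- project(d, g, d$px)
  set.seed(21)
  noisy <- spectral_sinogram(
    sino$attenuation + array(rnorm(length(sino$attenuation), sd = 0.05),
                             dim(sino$attenuation)),
    d$energies, g, noisy = TRUE, pixel_size_cm = d$px)
  hi <- fbp_channelwise(noisy, "ram-lak", 1, c(64, 64))
  lo <- fbp_channelwise(noisy, "hann", 0.2, c(64, 64))
  pow_above <- function(img, frac) {
    sp <- abs(stats::fft(img))^2
    f <- pmin(0:63, 64 - 0:63) / 64   # cycles per pixel, Nyquist 0.5
    rad <- sqrt(outer(f^2, f^2, `+`))
    sum(sp[rad > frac * 0.5])
  }
  p_hi <- pow_above(hi$pixels[1, , ], 0.2)
  p_lo <- pow_above(lo$pixels[1, , ], 0.2)
  expect_gt(p_hi / p_lo, 10)
})

test_that("disjoint-angle subsets of a noisy sinogram carry uncorrelated noise", {
  fx <- make_fixture(c(8, 32, 32), seed = 13)
  sp <- split_angles(fx$sinogram, 2)
  spc <- split_angles(fx$clean_sinogram, 2)
  r1 <- fbp_channelwise(sp$sinos[[1]], grid = c(32, 32))
  r2 <- fbp_channelwise(sp$sinos[[2]], grid = c(32, 32))
  c1 <- fbp_channelwise(spc$sinos[[1]], grid = c(32, 32))
  c2 <- fbp_channelwise(spc$sinos[[2]], grid = c(32, 32))
  n1 <- r1$pixels - c1$pixels
  n2 <- r2$pixels - c2$pixels
  bg <- as.vector(fx$phantom$labels == 0)
  m1 <- matrix(n1, 8, 32 * 32)[, bg]
  m2 <- matrix(n2, 8, 32 * 32)[, bg]
  expect_lt(abs(cor(as.vector(m1), as.vector(m2))), 0.05)
})
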