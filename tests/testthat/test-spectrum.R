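test_that("no photon exceeds the tube potential, at any kvp", {
  for (kvp in c(80, 100, 150)) {
    s <- build_source_spectrum(kvp)
    expect_true(all(s$fluence[s$bin_centers >= kvp] == 0))
    expect_gt(max(s$fluence), 0)
  }
})

test_that("the 150 kVp reference spectrum peaks at the K-fluorescence line", {
  s <- build_source_spectrum(150)
  peak_e <- s$bin_centers[which.max(s$fluence)]
  expect_lt(abs(peak_e - 59.3), 0.5)
})

test_that("rebinning averages blocks and conserves the mean flux", {
  # brute-force oracle on an arbitrary 20-bin fixture, groups of 4
  set.seed(3)
  f <- runif(20)
  s <- energy_spectrum(seq(0.5, by = 1, length.out = 20), f, 1)
  r <- rebin_average(s, 4L)
  manual <- vapply(seq_len(5), function(i) mean(f[(4 * i - 3):(4 * i)]), 1)
  expect_equal(r$fluence, manual)
  expect_equal(r$bin_width, 4)
  expect_equal(mean(r$fluence), mean(f))

  # constant spectrum is invariant
  cs <- energy_spectrum(seq(0.5, by = 1, length.out = 12), rep(7, 12), 1)
  expect_equal(rebin_average(cs, 3L)$fluence, rep(7, 4))

  expect_error(rebin_average(s, 3L), "indivisible_length")
})

test_that("the staging grid and ten-fold averaging give 131 one-keV channels", {
  s <- interpolate_spectrum(build_source_spectrum(150))
  expect_equal(length(s$bin_centers), 1310L)
  r <- rebin_average(s, 10L)
  expect_equal(length(r$bin_centers), 131L)
  expect_equal(r$bin_centers, seq(20, 150, by = 1))
})

test_that("count normalisation is exact, shape-preserving, idempotent", {
  s <- energy_spectrum(c(0.5, 1.5, 2.5), c(1, 2, 3), 1)
  n <- normalize_total_counts(s, 12)
  expect_equal(n$fluence, c(2, 4, 6))
  expect_equal(sum(normalize_total_counts(reference_channel_spectrum(),
                                          60000)$fluence), 60000)
  # already-normalised spectrum is unchanged
  expect_equal(normalize_total_counts(n, 12)$fluence, n$fluence)
  # ratios between bins survive
  expect_equal(n$fluence[2] / n$fluence[1], 2)
  zero <- energy_spectrum(c(0.5, 1.5), c(0, 0), 1)
  expect_error(normalize_total_counts(zero, 10), "zero_spectrum")
})

test_that("spectrum construction rejects bad filtration and degenerate grids", {
  expect_error(build_source_spectrum(150, filtration = list(c("kryptonite", 1))),
               "unknown_filtration")
  expect_error(build_source_spectrum(0.2), "kvp_below_grid")
})

test_that("spectra survive a CSV round trip", {
  s <- rebin_average(interpolate_spectrum(build_source_spectrum(150)), 10L)
  p <- tempfile(fileext = ".csv")
  write_spectrum_csv(s, p)
  r <- read_spectrum_csv(p)
  expect_equal(r$bin_centers, s$bin_centers)
  expect_equal(r$fluence, s$fluence)
})
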