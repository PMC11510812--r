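test_that("compound attenuation follows the mixture rule over the element tables", {
  # water: mass fractions from H2O, against an explicit hand computation
  aw <- c(H = 1.008, O = 15.999)
  wH <- 2 * aw["H"] / (2 * aw["H"] + aw["O"])
  wO <- 1 - wH
  for (e in c(20, 50, 70, 120)) {
    expected <- wH * get_mass_attenuation("H", e) +
      wO * get_mass_attenuation("O", e)
    expect_equal(get_mass_attenuation("water", e), unname(expected),
                 tolerance = 1e-12)
  }
  # tabulated anchor points are returned exactly (log-log interpolation is
  # exact at the knots)
  expect_equal(get_mass_attenuation("Al", 50), 0.3681, tolerance = 1e-9)
  expect_equal(get_mass_attenuation("O", 100), 0.1551, tolerance = 1e-9)
})

test_that("zero density gives zero linear attenuation", {
  expect_equal(get_linear_attenuation("water", 70, density = 0), 0)
})

test_that("iodine attenuation jumps across its K shell, water does not", {
  below <- get_mass_attenuation("iodine", 33.1)
  above <- get_mass_attenuation("iodine", 33.3)
  expect_gt(above, below)
  e <- seq(20, 50, by = 0.05)
  w <- get_mass_attenuation("water", e)
  expect_true(all(diff(w) < 0))
})

test_that("the K-edge finder locates edges and ignores smooth profiles", {
  e <- seq(25, 45, by = 0.05)
  edge <- find_k_edge(e, get_mass_attenuation("iodine", e))
  expect_lt(abs(edge - 33.17), 0.1)

  ew <- seq(20, 50, by = 0.05)
  expect_true(is.na(find_k_edge(ew, get_mass_attenuation("water", ew))))

  # synthetic step doubling at sample k is reported at sample k
  prof <- rep(1, 30)
  prof[17:30] <- 2
  expect_equal(find_k_edge(seq_len(30), prof), 17)
})

test_that("attenuation lookups fail loudly on bad input", {
  expect_error(get_mass_attenuation("unobtainium", 50), "unknown_material")
  expect_error(get_mass_attenuation("water", 5000), "energy_out_of_range")
  expect_error(find_k_edge(c(1, 3, 2), c(1, 2, 3)), "nonmonotone")
  expect_error(find_k_edge(c(1, 2), c(1, 2)), "at least 3")
})

test_that("formula parsing handles counts and multi-letter symbols", {
  expect_equal(parse_formula("H2O"), c(H = 2, O = 1))
  expect_equal(parse_formula("C6H5NO2"), c(C = 6, H = 5, N = 1, O = 2))
  expect_error(parse_formula("h2o"), "unknown_material")
})
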