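test_that("phantom LAC is the mass attenuation times the modulated density", {
  # single 1-pixel aluminium object without modulation: exact product
  m <- material_spec("aluminium", modulation_amplitude = 0)
  sh <- list(circle_shape(8, 8, 0.6))
  e <- c(40, 80, 120)
  ph <- build_phantom(list(m), sh, grid = c(16L, 16L), energies = e)
  expect_equal(sum(ph$labels), 1L)
  got <- matrix(ph$lac, 3, 16 * 16)[, as.vector(ph$labels == 1)]
  expect_equal(as.vector(got), get_mass_attenuation("aluminium", e) * m$density)
})

test_that("background is exactly zero wherever labels are zero, and only there", {
  ph <- build_phantom(phantom_materials(1), grid = c(50L, 50L),
                      energies = c(45, 70))
  bg <- as.vector(ph$labels == 0)
  lac_flat <- matrix(ph$lac, 2, 50 * 50)
  expect_true(all(lac_flat[, bg] == 0))
  expect_true(all(lac_flat[, !bg] > 0))
  expect_equal(length(unique(ph$labels[ph$labels > 0])), 4L)
})

test_that("edge-free material LAC decreases with energy channel by channel", {
  ph <- build_phantom(phantom_materials(1), grid = c(50L, 50L),
                      energies = seq(20, 150, by = 10))
  lac_flat <- matrix(ph$lac, dim(ph$lac)[1], 50 * 50)
  obj <- as.vector(ph$labels > 0)
  expect_true(all(apply(lac_flat[, obj], 2, diff) < 0))
})

test_that("phantom construction is linear in density", {
  sh <- list(circle_shape(10, 10, 4))
  m1 <- material_spec("water", density = 1)
  m2 <- material_spec("water", density = 2)
  p1 <- build_phantom(list(m1), sh, c(20L, 20L), c(50, 100))
  p2 <- build_phantom(list(m2), sh, c(20L, 20L), c(50, 100))
  expect_equal(p2$lac, 2 * p1$lac)
})

test_that("zero modulation amplitude gives spatially constant objects", {
  sh <- list(circle_shape(10, 10, 5))
  m <- material_spec("acetone", modulation_amplitude = 0)
  ph <- build_phantom(list(m), sh, c(20L, 20L), c(45, 70))
  vals <- matrix(ph$lac, 2, 400)[1, as.vector(ph$labels == 1)]
  expect_equal(max(vals) - min(vals), 0)
  # with modulation the object varies along x
  mm <- material_spec("acetone", modulation_amplitude = 0.05)
  ph2 <- build_phantom(list(mm), sh, c(20L, 20L), c(45, 70))
  vals2 <- matrix(ph2$lac, 2, 400)[1, as.vector(ph2$labels == 1)]
  expect_gt(diff(range(vals2)), 0)
})

test_that("invalid phantom requests fail with named errors", {
  expect_error(build_phantom(phantom_materials(1, 2),
                             list(circle_shape(10, 10, 4),
                                  circle_shape(12, 10, 4)),
                             c(20L, 20L), c(45, 70)),
               "overlapping_shapes")
  expect_error(build_phantom(list(material_spec("water")),
                             list(circle_shape(2, 2, 5)),
                             c(20L, 20L), c(45, 70)),
               "invalid_shapes")
  expect_error(phantom_materials(3), "unknown_preset")
})

test_that("center_crop keeps the centred window and matching metadata", {
  ph <- build_phantom(phantom_materials(1), grid = c(100L, 100L),
                      energies = seq(20, 150, by = 1))
  cr <- center_crop(ph, c(96L, 96L), 128L)
  expect_equal(dim(cr$lac), c(128L, 96L, 96L))
  expect_equal(length(cr$energies), 128L)
  expect_equal(cr$energies, seq(20, 147, by = 1))
  # retained voxels equal the corresponding source voxels
  expect_equal(cr$lac[5, , ], ph$lac[5, 3:98, 3:98])
  expect_equal(cr$labels, ph$labels[3:98, 3:98])
  # cropping to identical dims is the identity
  id <- center_crop(ph, c(100L, 100L), 131L)
  expect_equal(id$lac, ph$lac)
  expect_error(center_crop(ph, c(120L, 120L), 131L), "crop_too_large")
})
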