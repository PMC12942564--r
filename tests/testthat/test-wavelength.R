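test_that("wavelength axis is evenly spaced with forced endpoints", {
  ax <- make_wavelength_axis(204, 400, 1000)
  expect_length(ax$centers, 204)
  expect_equal(ax$centers[1], 400)
  expect_equal(ax$centers[204], 1000)
  expect_equal(ax$centers[21], 400 + 20 * 600 / 203, tolerance = 1e-12)
  expect_true(all(diff(ax$centers) > 0))
  expect_equal(stats::sd(diff(ax$centers)), 0, tolerance = 1e-9)
  expect_equal(make_wavelength_axis(2, 0, 1)$centers, c(0, 1))
})

test_that("invalid axis parameters are rejected", {
  expect_error(make_wavelength_axis(1), "n_bands")
  expect_error(make_wavelength_axis(-5), "n_bands")
  expect_error(make_wavelength_axis(10, 900, 400), "range_min")
})

test_that("nearest_band maps wavelengths to grid indices with low tie-break", {
  ax <- make_wavelength_axis(204, 400, 1000)
  expect_equal(nearest_band(ax, 400), 1L)
  expect_equal(nearest_band(ax, 1000), 204L)
  # 460 nm sits between centers 21 (~459.11) and 22 (~462.07)
  expect_equal(nearest_band(ax, 460), 21L)
  ax3 <- structure(list(centers = c(400, 500, 600), range_min = 400,
                        range_max = 600), class = "wavelength_axis")
  expect_equal(nearest_band(ax3, 450), 1L)  # tie broken toward lower index
  expect_error(nearest_band(ax, 2000), "outside")
})

test_that("subset_axis keeps selected centers and rejects bad indices", {
  ax <- make_wavelength_axis(10, 400, 1000)
  sub <- subset_axis(ax, c(2, 5, 9))
  expect_equal(sub$centers, ax$centers[c(2, 5, 9)])
  expect_error(subset_axis(ax, c(0, 2)), "out of range")
})
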