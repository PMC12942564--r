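small_params <- function(seed = 7, ...) {
  phantom_params(
    n_subjects = 2, acquisition_days = c(0, 6, 17),
    image_size = c(24, 24), n_bands = 20,
    lesion_radius_min = 3, lesion_radius_max = 7, seed = seed, ...
  )
}

test_that("cohort generation is a pure function of its parameters", {
  c1 <- generate_cohort(small_params())
  c2 <- generate_cohort(small_params())
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$samples[[3]]$radiance, c2$samples[[3]]$radiance)
  expect_equal(nrow(c1$metadata), 2 * 3)
  # every subject appears with every configured age
  tab <- table(c1$metadata$subject_id, c1$metadata$age_days)
  expect_true(all(tab == 1))
})

test_that("per-subject random streams: adding a subject leaves others unchanged", {
  c2 <- generate_cohort(small_params())
  c3 <- generate_cohort(phantom_params(
    n_subjects = 3, acquisition_days = c(0, 6, 17),
    image_size = c(24, 24), n_bands = 20,
    lesion_radius_min = 3, lesion_radius_max = 7, seed = 7
  ))
  expect_identical(c2$samples[[1]]$radiance, c3$samples[[1]]$radiance)
  expect_identical(c2$samples[[6]]$radiance, c3$samples[[6]]$radiance)
})

test_that("lesion morphology grows to mid-course and the age signal is spectral", {
  coh <- generate_cohort(small_params())
  s0 <- coh$samples[[1]]   # age 0
  s6 <- coh$samples[[2]]   # age 6
  expect_gt(sum(s6$mask), sum(s0$mask))
  # reflectance at the Soret band separates ages more than at ~900 nm
  ax <- coh$axis
  refl <- function(s) radiometric_normalize(s$radiance, s$white, s$dark)
  r0 <- refl(s0); r6 <- refl(s6)
  core <- s0$mask == 1 & s6$mask == 1
  band_diff <- function(nm) {
    b <- nearest_band(ax, nm)
    abs(mean(r0[b, , ][core]) - mean(r6[b, , ][core]))
  }
  expect_gt(band_diff(430), band_diff(900))
})

test_that("implied reflectance stays within physical bounds at default noise", {
  coh <- tiny_cohort()
  for (s in coh$samples[c(1, 5, 9)]) {
    refl <- radiometric_normalize(s$radiance, s$white, s$dark)
    expect_gt(min(refl), -0.05)
    expect_lt(max(refl), 1.05)
  }
})

test_that("age signal dominates pixel noise in spectral angle", {
  coh <- generate_cohort(small_params())
  refl <- function(s) radiometric_normalize(s$radiance, s$white, s$dark)
  s1 <- coh$samples[[1]]; s17 <- coh$samples[[3]]
  ctr <- mask_center(s1$mask)
  px <- function(r, at) r[, at[1], at[2]]
  r1 <- refl(s1); r17 <- refl(s17)
  across_age <- spectral_angle(px(r1, ctr), px(r17, ctr))
  same_age <- spectral_angle(px(r1, ctr), px(r1, ctr + c(1, 0)))
  expect_gt(across_age, same_age)
})

test_that("visibility threshold drops low-contrast samples with a logged reason", {
  coh <- generate_cohort(small_params(visibility_threshold = 0.03))
  expect_gt(nrow(coh$excluded), 0)
  expect_match(coh$excluded$reason[1], "no visible hematoma")
  expect_equal(nrow(coh$metadata) + nrow(coh$excluded), 6)
  # only faded late-stage acquisitions fall below the threshold
  expect_true(all(coh$excluded$age_days >= 10))
})

test_that("oversized lesions and invalid parameters are rejected", {
  expect_error(
    generate_cohort(phantom_params(
      n_subjects = 1, acquisition_days = 6, image_size = c(16, 16),
      n_bands = 8, lesion_radius_min = 4, lesion_radius_max = 14, seed = 1
    )),
    "exceeds image bounds"
  )
  expect_error(phantom_params(n_subjects = 0), "positive")
  expect_error(phantom_params(lesion_radius_min = -1), "radii")
})
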