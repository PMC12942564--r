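test_that("radiometric normalization satisfies its defining identities", {
  d <- c(4, 5, 5)
  white <- array(runif(prod(d), 0.8, 1), dim = d)
  dark <- array(runif(prod(d), 0, 0.1), dim = d)
  expect_equal(radiometric_normalize(white, white, dark),
               array(1, dim = d))
  expect_equal(radiometric_normalize(dark, white, dark),
               array(0, dim = d))
  raw <- array(0.55, dim = c(1, 1, 1))
  expect_equal(
    as.numeric(radiometric_normalize(raw, array(1, dim(raw)), array(0.1, dim(raw)))),
    0.5
  )
})

test_that("normalization inverts the synthesis model to floating tolerance", {
  set.seed(3)
  for (rep in 1:5) {
    d <- c(sample(2:8, 1), sample(4:10, 1), sample(4:10, 1))
    r <- array(runif(prod(d)), dim = d)
    white <- array(runif(prod(d), 0.7, 1.1), dim = d)
    dark <- array(runif(prod(d), 0, 0.2), dim = d)
    raw <- dark + r * (white - dark)
    out <- radiometric_normalize(raw, white, dark)
    expect_lt(max(abs(out - r) / pmax(abs(r), 1e-12)), 1e-6)
  }
  # per-band reference spectra broadcast like full cubes
  d <- c(3, 4, 4)
  raw <- array(runif(prod(d)), dim = d)
  ws <- c(0.9, 1.0, 1.1); ds_ <- c(0.05, 0.02, 0.08)
  full <- radiometric_normalize(raw, array(ws, d), array(ds_, d))
  spec <- radiometric_normalize(raw, ws, ds_)
  expect_equal(spec, full)
})

test_that("degenerate references are reported with band and pixel", {
  d <- c(2, 3, 3)
  white <- array(1, dim = d); dark <- array(0, dim = d)
  white[2, 3, 1] <- 0; dark[2, 3, 1] <- 0
  expect_error(radiometric_normalize(array(0.5, d), white, dark),
               "band 2, pixel \\(3, 1\\)")
})

test_that("builtin segmenter recovers the phantom lesion", {
  coh <- tiny_cohort()
  s <- coh$samples[[2]]  # age 3: solid contrast
  refl <- radiometric_normalize(s$radiance, s$white, s$dark)
  m <- segment_lesion(refl)
  expect_false(is.null(m))
  expect_equal(attr(m, "provenance"), "builtin-segmenter")
  iou <- sum(m & s$mask) / sum(m | s$mask)
  expect_gt(iou, 0.5)
})

test_that("segmenter signals lesion-not-found on a uniform cube", {
  d <- c(10, 16, 16)
  flat <- array(rep(runif(10, 0.4, 0.6), prod(d[2:3])), dim = d)
  expect_null(segment_lesion(flat))
})

test_that("segmenter restricted to a prompt box stays inside it", {
  coh <- tiny_cohort()
  s <- coh$samples[[2]]
  refl <- radiometric_normalize(s$radiance, s$white, s$dark)
  ctr <- mask_center(s$mask)
  box <- c(max(1, ctr[1] - 9), min(24, ctr[1] + 9),
           max(1, ctr[2] - 9), min(24, ctr[2] + 9))
  m <- segment_lesion(refl, prompt_box = box)
  expect_false(is.null(m))
  outside <- m
  outside[box[1]:box[2], box[3]:box[4]] <- 0
  expect_equal(sum(outside), 0)
})

test_that("mask centroids round half up", {
  m <- matrix(0L, 30, 30)
  m[10, 20] <- 1L
  expect_equal(unname(mask_center(m)), c(10, 20))
  m2 <- matrix(0L, 5, 5); m2[1, 1] <- 1L; m2[1, 3] <- 1L
  expect_equal(unname(mask_center(m2)), c(1, 2))
  m3 <- matrix(0L, 12, 12); m3[4:8, 4:8] <- 1L  # 5x5 block, centroid (6,6)
  expect_equal(unname(mask_center(m3)), c(6, 6))
  expect_error(mask_center(matrix(0L, 3, 3)), "empty mask")
})

test_that("patch extraction is exact-size, clamped, never padded", {
  cube <- array(seq_len(3 * 100 * 100), dim = c(3, 100, 100))
  p <- extract_patch(cube, c(50, 50), 16)
  expect_equal(dim(p), c(3, 16, 16))
  expect_equal(attr(p, "origin"), c(42, 42))
  expect_equal(p[, 1, 1], cube[, 42, 42])
  # corner centers clamp inside the image
  p0 <- extract_patch(cube, c(1, 1), 16)
  expect_equal(attr(p0, "origin"), c(1, 1))
  pE <- extract_patch(cube, c(100, 100), 16)
  expect_equal(attr(pE, "origin"), c(85, 85))
  # band count is always preserved
  expect_equal(dim(extract_patch(cube, c(7, 93), 10))[1], 3)
  expect_error(extract_patch(cube, c(50, 50), 101), "exceeds image extent")
})

test_that("build_dataset excludes invisible lesions and logs the reason", {
  coh <- generate_cohort(phantom_params(
    n_subjects = 2, acquisition_days = c(0, 3, 6),
    image_size = c(24, 24), n_bands = 16,
    lesion_radius_min = 3, lesion_radius_max = 7,
    heterogeneity = 0, seed = 5
  ))
  # zero out one sample's lesion so the builtin segmenter finds nothing
  flat <- coh$samples[[1]]
  skin <- flat$radiance[, 1, 1]
  flat$radiance <- array(rep(skin, 24 * 24), dim = dim(flat$radiance))
  coh$samples[[1]] <- flat
  ds <- build_dataset(coh, masks = "builtin")
  expect_equal(n_samples(ds), 5)
  expect_equal(nrow(ds$exclusions), 1)
  expect_match(ds$exclusions$reason, "lesion not found")
  expect_true(all(ds$metadata$mask_provenance == "builtin-segmenter"))
})

test_that("patch datasets round-trip through the on-disk container", {
  ds <- tiny_dataset()
  path <- tempfile(fileext = ".rds")
  write_patch_dataset(ds, path)
  back <- read_patch_dataset(path)
  expect_equal(back$patches, ds$patches)
  expect_equal(back$metadata$subject_id, ds$metadata$subject_id)
  expect_equal(back$informative_bands, ds$informative_bands)
})
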