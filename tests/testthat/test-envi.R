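test_that("ENVI cubes round-trip through all interleaves", {
  set.seed(1)
  cube <- array(runif(5 * 4 * 6), dim = c(5, 4, 6))
  wl <- seq(400, 800, length.out = 5)
  for (il in c("bsq", "bil", "bip")) {
    path <- tempfile(fileext = ".raw")
    write_envi(cube, path, wavelengths = wl, interleave = il)
    back <- read_envi(path)
    expect_equal(back$values, cube, tolerance = 1e-6, info = il)
    expect_equal(back$wavelengths, wl, tolerance = 1e-3)
  }
})

test_that("float64 and uint8 ENVI data types round-trip", {
  cube <- array(seq(0, 1, length.out = 3 * 2 * 2), dim = c(3, 2, 2))
  p64 <- tempfile()
  write_envi(cube, p64, data_type = 5L)
  expect_equal(read_envi(p64)$values, cube, tolerance = 1e-12)
  mask <- array(c(0, 1, 1, 0), dim = c(1, 2, 2))
  p8 <- tempfile()
  write_envi(mask, p8, data_type = 1L, interleave = "bsq")
  expect_equal(read_envi(p8)$values, mask)
})

test_that("missing or malformed ENVI files produce clear errors", {
  expect_error(read_envi(tempfile()), "missing ENVI header")
  hdr <- tempfile(fileext = ".hdr")
  writeLines(c("ENVI", "samples = 4", "lines = 4"), hdr)
  file.create(sub("\\.hdr$", "", hdr))
  expect_error(read_envi(hdr), "missing field")
})

test_that("a cohort written to ENVI + CSV rebuilds to identical patches", {
  coh <- tiny_cohort()
  dir <- tempfile("cohort_")
  csv <- write_phantom_cohort(coh, dir)
  md <- utils::read.csv(csv)
  expect_named(md, c("sample_id", "subject_id", "age_days", "stage",
                     "path_cube", "path_white", "path_dark", "path_mask"))
  ds_mem <- build_dataset(coh, masks = "truth")
  ds_file <- build_dataset(csv, patch_size = 24, masks = "truth")
  expect_equal(ds_file$patches, ds_mem$patches, tolerance = 1e-5)
  expect_equal(ds_file$metadata$age_days, ds_mem$metadata$age_days)
  expect_equal(ds_file$axis$centers, ds_mem$axis$centers, tolerance = 1e-3)
  unlink(dir, recursive = TRUE)
})

test_that("build_dataset names the offending row for missing files", {
  coh <- tiny_cohort()
  dir <- tempfile("cohort_")
  csv <- write_phantom_cohort(coh, dir)
  md <- utils::read.csv(csv, stringsAsFactors = FALSE)
  file.remove(md$path_cube[2])
  expect_error(build_dataset(csv, patch_size = 24, masks = "truth"),
               "row 2")
  unlink(dir, recursive = TRUE)
})
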