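ax <- make_wavelength_axis()

test_that("chromophore curves are normalized with documented absorption maxima", {
  for (nm in chromophore_names()) {
    mu <- chromophore_absorption(nm, ax)
    expect_true(all(mu >= 0), info = nm)
    expect_lte(max(mu), 1 + 1e-9)
  }
  # oxyhemoglobin global maximum sits in the Soret region (405-445 nm)
  oxy <- chromophore_absorption("oxyhemoglobin", ax)
  peak <- ax$centers[which.max(oxy)]
  expect_gte(peak, 405); expect_lte(peak, 445)
  # Q-band local maxima near 540 and 578 nm (within +-10 nm)
  for (target in c(540, 578)) {
    win <- which(abs(ax$centers - target) <= 10)
    i <- win[which.max(oxy[win])]
    expect_gt(oxy[i], oxy[i - 1]); expect_gt(oxy[i], oxy[i + 1])
  }
  # bilirubin local maximum within 450-470 nm
  bili <- chromophore_absorption("bilirubin", ax)
  win <- which(ax$centers >= 450 & ax$centers <= 470)
  expect_equal(which.max(bili), win[which.max(bili[win])])
  # melanin is monotone decreasing
  mel <- chromophore_absorption("melanin", ax)
  expect_true(all(diff(mel) < 0))
})

test_that("restricted axes stay within [0, 1] and unknown names error", {
  one <- make_wavelength_axis(2, 700, 701)
  v <- chromophore_absorption("oxyhemoglobin", one)
  expect_true(all(v >= 0 & v <= 1))
  expect_error(chromophore_absorption("chlorophyll", ax), "unknown chromophore")
})

test_that("time-course weights follow hematoma kinetics", {
  w0 <- time_course_weights(0)
  expect_equal(unname(w0["bilirubin"]), 0)
  # hemoglobin decays monotonically across representative ages
  hb <- sapply(c(0, 6, 18), function(a) {
    w <- time_course_weights(a); w["oxyhemoglobin"] + w["deoxyhemoglobin"]
  })
  expect_true(all(diff(hb) < 0))
  # bilirubin is unimodal: rises then falls over a dense age grid
  bili <- sapply(seq(0, 30, by = 0.5), function(a) time_course_weights(a)["bilirubin"])
  pk <- which.max(bili)
  expect_true(all(diff(bili[1:pk]) >= 0))
  expect_true(all(diff(bili[pk:length(bili)]) <= 0))
  # contrast fades: total weight at 20 d below the mid-course maximum,
  # and everything goes to ~0 far beyond the resolution horizon
  tot <- function(a) sum(time_course_weights(a))
  expect_lt(tot(20), max(sapply(4:9, tot)))
  expect_lt(tot(60), 1e-3)
  expect_error(time_course_weights(-1), "non-negative")
})
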