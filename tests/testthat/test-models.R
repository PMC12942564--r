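test_that("spatial averaging equals the brute-force per-band mean", {
  set.seed(11)
  patch <- array(runif(6 * 5 * 5), dim = c(6, 5, 5))
  sig <- spatial_average(patch)
  brute <- sapply(1:6, function(b) {
    acc <- 0
    for (r in 1:5) for (cc in 1:5) acc <- acc + patch[b, r, cc]
    acc / 25
  })
  expect_equal(sig, brute, tolerance = 1e-12)
  # constant band
  patch[2, , ] <- 0.3
  expect_equal(spatial_average(patch)[2], 0.3)
  # dataset form agrees with per-patch form
  ds <- tiny_dataset()
  sigs <- spatial_average(ds)
  expect_equal(dim(sigs), c(n_samples(ds), 20))
  expect_equal(unname(sigs[3, ]), spatial_average(ds$patches[, , , 3]))
})

test_that("lasso handles degenerate targets and selects informative bands", {
  set.seed(21)
  # constant targets -> constant prediction
  x <- matrix(runif(40 * 8), 40, 8)
  m_const <- fit_lasso(x, rep(7, 40))
  expect_equal(predict_ages(m_const, x), rep(7, 40))
  # one perfectly age-linear band among pure-noise bands
  n <- 60
  age <- runif(n, 0, 20)
  x2 <- matrix(rnorm(n * 10), n, 10)
  x2[, 4] <- age / 20 + rnorm(n, sd = 0.01)
  m <- fit_lasso(x2, age)
  expect_true(4 %in% m$nonzero_bands)
  expect_lt(length(m$nonzero_bands), 6)
  # in the strong-penalty limit glmnet keeps only the intercept
  path_fit <- glmnet::glmnet(x2, age, alpha = 1)
  cf <- stats::coef(path_fit, s = max(path_fit$lambda) * 10)
  expect_equal(sum(as.numeric(cf)[-1] != 0), 0)
  expect_equal(as.numeric(cf)[1], mean(age), tolerance = 1e-6)
})

test_that("mean model predicts the training mean everywhere", {
  ds <- tiny_dataset()
  fold <- loso_split(ds)[[1]]
  m <- hematochron:::.fit_fold(ds, fold, model_spec("mean"), train_config(), 1, 1)
  p <- predict_ages(m, ds[fold$test_idx])
  expect_equal(p, rep(mean(ds$metadata$age_days[fold$train_idx]),
                      length(fold$test_idx)))
})

test_that("linear band model predicts and differentiates analytically", {
  set.seed(4)
  x <- array(runif(3 * 4 * 4 * 5), dim = c(3, 4, 4, 5))
  m <- linear_band_model(c(2, -1, 0.5), intercept = 1)
  p <- predict_ages(m, x)
  sig <- t(apply(x, 4, function(a) rowMeans(matrix(a, nrow = 3))))
  expect_equal(p, as.numeric(1 + sig %*% c(2, -1, 0.5)))
})
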