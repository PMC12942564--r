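test_that("standard subsets hit their nominal wavelengths", {
  ax <- make_wavelength_axis(204, 400, 1000)
  rgb <- make_subset("rgb", ax)
  expect_length(rgb$indices, 3)
  expect_true(all(abs(rgb$wavelengths - c(460, 540, 650)) < 1.5))
  physio <- make_subset("physio", ax)
  expect_length(physio$indices, 6)
  expect_true(all(rgb$indices %in% physio$indices))
  full <- make_subset("full", ax)
  expect_equal(full$indices, 1:204)
  expect_error(make_subset("topk", ax), "consensus")
})

test_that("smoothgrad on a linear model recovers coefficient ratios", {
  set.seed(31)
  x <- array(runif(4 * 6 * 6 * 10), dim = c(4, 6, 6, 10))
  m <- linear_band_model(c(3, 1, 0, 0))
  sc <- smoothgrad_importance(m, x, noise_sd = 0.1, n_draws = 5, seed = 2)
  expect_equal(sc$scores[1] / sc$scores[2], 3, tolerance = 1e-6)
  expect_equal(sc$scores[3], 0)
  expect_error(smoothgrad_importance(m, x, n_draws = 0), "n_draws")
})

test_that("smoothgrad is deterministic under seed and zero for unused bands", {
  set.seed(32)
  cfg <- toy_cnn_config(6)
  m <- build_cnn(cfg, seed = 5)
  # zero the first-layer weights that read band 3: with kernel width 3 the
  # only paths from band 3 run through kernel taps at bands 2-4
  x <- array(runif(6 * 8 * 8 * 4), dim = c(6, 8, 8, 4))
  s1 <- smoothgrad_importance(m, x, noise_sd = 0.1, n_draws = 3, seed = 7)
  s2 <- smoothgrad_importance(m, x, noise_sd = 0.1, n_draws = 3, seed = 7)
  expect_equal(s1$scores, s2$scores)
  # plain-saliency limit: noise_sd 0, one draw equals the raw gradient
  s0 <- smoothgrad_importance(m, x, noise_sd = 0, n_draws = 1)
  g <- cnn_input_gradient(m, x)
  expect_equal(s0$scores, rowMeans(abs(matrix(g, nrow = 6))), tolerance = 1e-7)
})

test_that("occlusion equals the brute-force re-evaluation oracle", {
  set.seed(33)
  nb <- 6
  x <- array(runif(nb * 5 * 5 * 20), dim = c(nb, 5, 5, 20))
  truth <- runif(20, 0, 20)
  model <- linear_band_model(rnorm(nb), intercept = 5)
  means <- rowMeans(matrix(x, nrow = nb))
  oc <- occlusion_importance(model, x, truth, "train_mean", band_means = means)
  # independent brute-force loop
  base <- mean(abs(predict_ages(model, x) - truth))
  for (b in seq_len(nb)) {
    xb <- x
    xb[b, , , ] <- means[b]
    brute <- mean(abs(predict_ages(model, xb) - truth)) - base
    expect_equal(oc$scores[b], brute, tolerance = 1e-9)
  }
  # identity replacement is a no-op: all scores exactly zero
  id <- occlusion_importance(model, x, truth, "identity")
  expect_equal(id$scores, rep(0, nb))
  expect_error(occlusion_importance(model, x, truth, "train_mean"),
               "band_means")
})

test_that("rank consensus matches brute force, is symmetric, conserves rank mass", {
  set.seed(34)
  n <- 204
  a <- hematochron:::new_band_score(runif(n), "smoothgrad")
  b <- hematochron:::new_band_score(runif(n), "occlusion")
  cons <- rank_consensus(a, b)
  # brute-force rank computation by sorting
  brute_rank <- function(s) {
    o <- order(-s)
    r <- numeric(n)
    i <- 1
    while (i <= n) {
      j <- i
      while (j < n && s[o[j + 1]] == s[o[i]]) j <- j + 1
      r[o[i:j]] <- mean(i:j)
      i <- j + 1
    }
    r
  }
  expect_equal(cons$scores, (brute_rank(a$scores) + brute_rank(b$scores)) / 2,
               tolerance = 1e-12)
  sym <- rank_consensus(b, a)
  expect_equal(cons$scores, sym$scores)
  expect_true(all(cons$scores >= 1 & cons$scores <= n))
  expect_equal(mean(cons$scores), (n + 1) / 2, tolerance = 1e-12)
  # idempotence: consensus of a method with itself is its own ranking
  expect_equal(rank_consensus(a, a)$scores, brute_rank(a$scores))
  expect_error(rank_consensus(a, hematochron:::new_band_score(1:3, "occlusion")),
               "lengths differ")
})

test_that("top_k selects by consensus with index tie-breaking", {
  cons <- hematochron:::new_band_score(c(1.5, 1.5, 3, 4), "consensus-rank")
  expect_equal(top_k(cons, 2)$indices, c(1L, 2L))
  expect_equal(top_k(cons, 4)$indices, 1:4)
  expect_equal(top_k(cons, 1)$indices, 1L)   # tie at the cut -> lower index
  expect_error(top_k(cons, 5), "exceeds band count")
})

test_that("apply_subset restricts patches and the wavelength axis", {
  ds <- tiny_dataset()
  rgb <- make_subset("rgb", ds$axis)
  ds_rgb <- apply_subset(ds, rgb)
  expect_equal(dim(ds_rgb$patches)[1], 3)
  expect_equal(ds_rgb$axis$centers, ds$axis$centers[rgb$indices])
  full <- make_subset("full", ds$axis)
  expect_equal(apply_subset(ds, full)$patches, ds$patches)
  bad <- hematochron:::new_band_subset("topk", c(1L, 99L))
  expect_error(apply_subset(ds, bad), "out of range")
})
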