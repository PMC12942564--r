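test_that("configurations are validated", {
  expect_error(cnn_config(n_bands = 2), "smallest spectral kernel")
  expect_error(cnn_config(dropout = 1), "dropout")
  cfg <- cnn_config()
  expect_equal(cfg$spec_channels, c(128L, 64L, 32L))
  expect_equal(cfg$spat_channels, c(64L, 128L))
})

test_that("flatten width is independent of band count and patch size", {
  for (nb in c(20L, 60L)) {
    m <- build_cnn(phantom_cnn_config(nb), seed = 1)
    tr <- cnn_shape_trace(m, patch_size = 48L)
    expect_equal(tr$flatten, 16L * 4L * 4L, info = nb)
    expect_equal(tr$linear2, 1L)
    expect_equal(tr$spec_conv3[2], nb)
  }
})

test_that("prediction is deterministic, order-preserving, and shape-checked", {
  set.seed(2)
  cfg <- toy_cnn_config()
  m <- build_cnn(cfg, seed = 3)
  x <- array(runif(6 * 8 * 8 * 4), dim = c(6, 8, 8, 4))
  p1 <- predict_ages(m, x)
  expect_length(p1, 4)
  expect_true(all(is.finite(p1)))
  expect_equal(predict_ages(m, x), p1)
  # duplicated sample -> identical prediction; order preserved
  x2 <- x[, , , c(2, 2, 1, 3, 4)]
  p2 <- predict_ages(m, x2)
  expect_equal(p2[1], p2[2])
  expect_equal(p2[3], p1[1])
  expect_error(predict_ages(m, x[1:5, , , , drop = FALSE]), "5 bands")
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(3)
  cfg <- toy_cnn_config()
  m <- build_cnn(cfg, seed = 2)
  x <- array(rnorm(6 * 8 * 8 * 3), dim = c(6, 8, 8, 3))
  y <- c(1, 5, 9)
  lg <- hematochron:::cpp_cnn_loss_grad(cfg, m$weights, as.numeric(x), y,
                                        dim(x), TRUE)
  h <- 1e-3
  # parameter gradients: a sample of weights from every layer family
  for (wname in c("s1_W", "s2_W", "s3_W", "t1_W", "t2_W", "h1_W", "h2_W",
                  "bn2_g", "bn4_b")) {
    W <- m$weights[[wname]]
    G <- lg$grad[[wname]]
    set.seed(9)
    idx <- sample(length(W), min(4, length(W)))
    for (i in idx) {
      wp <- m$weights; wp[[wname]][i] <- wp[[wname]][i] + h
      wm <- m$weights; wm[[wname]][i] <- wm[[wname]][i] - h
      lp <- hematochron:::cpp_cnn_loss_grad(cfg, wp, as.numeric(x), y, dim(x), FALSE)$loss
      lm <- hematochron:::cpp_cnn_loss_grad(cfg, wm, as.numeric(x), y, dim(x), FALSE)$loss
      fd <- (lp - lm) / (2 * h)
      # float forward + ReLU kinks limit attainable agreement
      expect_lt(abs(fd - G[i]), 0.05 * max(abs(G[i]), 1),
                label = sprintf("%s[%d] fd=%.4f ana=%.4f", wname, i, fd, G[i]))
    }
  }
  # input gradients
  set.seed(10)
  for (j in sample(length(x), 5)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    lp <- hematochron:::cpp_cnn_loss_grad(cfg, m$weights, as.numeric(xp), y, dim(x), FALSE)$loss
    lm <- hematochron:::cpp_cnn_loss_grad(cfg, m$weights, as.numeric(xm), y, dim(x), FALSE)$loss
    fd <- (lp - lm) / (2 * h)
    expect_lt(abs(fd - lg$input_grad[j]), 0.05 * max(abs(fd), 0.2))
  }
})

test_that("training is deterministic given a seed and restores the best epoch", {
  set.seed(6)
  cfg <- cnn_config(n_bands = 10, spec_channels = c(3, 3, 2),
                    spec_kernels = c(3, 3, 3), spec_pool_len = 4,
                    spat_channels = c(2, 3), spat_pool = 2,
                    head_hidden = 5, dropout = 0.2)
  x <- array(runif(10 * 8 * 8 * 12), dim = c(10, 8, 8, 12))
  y <- runif(12, 0, 20)
  tc <- train_config(batch_size = 4, max_epochs = 6, patience = 3, seed = 77)
  m1 <- train_cnn(cfg, x[, , , 1:8], y[1:8], x[, , , 9:12], y[9:12], tc)
  m2 <- train_cnn(cfg, x[, , , 1:8], y[1:8], x[, , , 9:12], y[9:12], tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
  expect_gte(m1$best_epoch, 1)
  expect_equal(m1$best_val_mae, min(m1$history$val_mae), tolerance = 1e-6)
  expect_error(
    train_cnn(cfg, x[, , , 1:8], y[1:8], x[, , , integer(0)], numeric(0), tc),
    "validation set"
  )
})

test_that("the network can overfit a small batch (sanity check)", {
  ds <- tiny_dataset()
  idx <- seq(1, n_samples(ds), length.out = 8)
  x <- ds$patches[, , , idx]
  y <- ds$metadata$age_days[idx]
  cfg <- phantom_cnn_config(dim(x)[1])
  cfg$dropout <- 0   # memorization check: no regularization
  tc <- train_config(lr = 3e-3, batch_size = 8, max_epochs = 150,
                     patience = 149, min_delta = 0, augment = FALSE, seed = 12)
  m <- train_cnn(cfg, x, y, x, y, tc)   # train == val: pure memorization
  p <- predict_ages(m, x)
  expect_lt(mean(abs(p - y)), 0.5)
})
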