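test_that("empty configuration yields full defaults", {
  cfg <- validate_config(NULL)
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$phantom$n_subjects, 8L)
  expect_equal(cfg$k, 20L)
  # an empty YAML file behaves the same
  f <- tempfile(fileext = ".yaml")
  file.create(f)
  expect_equal(unclass(validate_config(f)), unclass(cfg))
})

test_that("configuration errors are exhaustive and name the keys", {
  err <- tryCatch(
    validate_config(list(
      train = list(batch_size = -1, bogus_key = 2),
      k = 999,
      nonsense = TRUE
    )),
    error = function(e) conditionMessage(e)
  )
  expect_match(err, "train.batch_size")
  expect_match(err, "train.bogus_key")
  expect_match(err, "k \\(999\\) exceeds")
  expect_match(err, "unknown config key 'nonsense'")
})

test_that("a minimal experiment runs end to end and is reproducible", {
  cfg <- validate_config(list(
    phantom = list(n_subjects = 2L, acquisition_days = c(0, 6, 13),
                   image_size = c(16L, 16L), n_bands = 12L,
                   lesion_radius_min = 2, lesion_radius_max = 5),
    cnn = list(spec_channels = c(2L, 2L, 3L), spec_pool_len = 4L,
               spat_channels = c(3L, 4L), spat_pool = 2L, head_hidden = 6L),
    train = list(max_epochs = 2L, patience = 1L, batch_size = 4L),
    subsets = c("full", "topk"),
    k = 4L, seeds = 1L
  ))
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- run_experiment(cfg, d1, quiet = TRUE)
  r2 <- run_experiment(cfg, d2, quiet = TRUE)
  # comparison table has one row per model, with stage-wise MAE columns
  expect_setequal(r1$comparison$model,
                  c("lasso", "mean", "cnn_full", "cnn_topk"))
  expect_true(all(c("mae_early", "mae_middle", "mae_late") %in%
                  names(r1$comparison)))
  expect_equal(r1$comparison, r2$comparison)
  # manifest names the seed and config hash; Top-k subset flows through
  expect_true(file.exists(file.path(d1, "manifest.json")))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$config_hash, r1$manifest$config_hash)
  imp <- utils::read.csv(file.path(d1, "importance_seed1.csv"))
  expect_equal(sum(imp$selected_topk), 4)
  expect_equal(r1$results[["1"]]$topk$indices,
               imp$band_index[imp$selected_topk])
  unlink(c(d1, d2), recursive = TRUE)
})
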