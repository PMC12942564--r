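test_that("stage assignment partitions the age range", {
  expect_equal(assign_stage(c(0, 3, 4, 9, 10, 20)),
               c("early", "early", "middle", "middle", "late", "late"))
  expect_error(assign_stage(-1), "negative")
})

test_that("metrics match hand-computed values and flag undefined R2", {
  m <- compute_metrics(c(1, 5, 9), c(1, 5, 9))
  expect_equal(m$mae, 0); expect_equal(m$rmse, 0); expect_equal(m$r2, 1)
  expect_equal(c(m$acc1, m$acc2, m$acc3), c(100, 100, 100))
  m2 <- compute_metrics(c(0, 4), c(1, 2))
  expect_equal(m2$mae, 1.5)
  expect_equal(m2$rmse, sqrt(2.5), tolerance = 1e-9)
  expect_equal(m2$acc1, 50); expect_equal(m2$acc2, 100)
  m3 <- compute_metrics(c(1, 2, 3), c(5, 5, 5))
  expect_true(is.na(m3$r2))
  expect_true(isTRUE(attr(m3$r2, "undefined")))
  expect_false(is.na(m3$mae))
})

test_that("metric invariants hold on random prediction vectors", {
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    truth <- runif(n, 0, 20)
    pred <- truth + rnorm(n, sd = runif(1, 0.1, 5))
    m <- compute_metrics(pred, truth)
    expect_gte(m$rmse, m$mae)
    expect_gte(m$mae, 0)
    expect_lte(m$acc1, m$acc2); expect_lte(m$acc2, m$acc3)
    expect_lte(m$r2, 1)
  }
})

test_that("LOSO folds cover each subject exactly once without leakage", {
  ds <- tiny_dataset()
  folds <- loso_split(ds)
  expect_length(folds, 3)
  held <- vapply(folds, `[[`, character(1), "test_subject")
  expect_equal(sort(held), sort(unique(ds$metadata$subject_id)))
  for (f in folds) {
    expect_length(intersect(f$test_idx, f$train_idx), 0)
    expect_false(f$test_subject %in% f$train_subjects)
    expect_setequal(c(f$test_idx, f$train_idx), seq_len(n_samples(ds)))
  }
  one <- ds[ds$metadata$subject_id == held[1]]
  expect_error(loso_split(one), "at least 2 subjects")
})

test_that("run_loso produces a coherent, deterministic report", {
  ds <- tiny_dataset()
  tc <- train_config(max_epochs = 2, patience = 1, seed = 9)
  r1 <- run_loso(ds, model_spec("lasso"), tc)
  r2 <- run_loso(ds, model_spec("lasso"), tc)
  expect_equal(r1$predictions, r2$predictions)
  expect_equal(nrow(r1$folds), 3)
  expect_equal(sum(r1$stage$n), nrow(r1$predictions))
  # pooled MAE lies between the per-fold extremes
  expect_gte(r1$pooled$mae, min(r1$folds$mae) - 1e-12)
  expect_lte(r1$pooled$mae, max(r1$folds$mae) + 1e-12)
  # per-day table covers every acquisition age
  expect_setequal(r1$per_day$true_age, unique(ds$metadata$age_days))
})

test_that("the mean predictor cannot beat the out-of-sample variance baseline", {
  ds <- tiny_dataset()
  r <- run_loso(ds, model_spec("mean"), train_config(max_epochs = 2, patience = 1))
  expect_lte(as.numeric(r$pooled$r2), 0)
})

test_that("evaluation reports serialize to JSON and CSV", {
  ds <- tiny_dataset()
  r <- run_loso(ds, model_spec("mean"), train_config(max_epochs = 2, patience = 1))
  dir <- tempfile("report_")
  write_eval_report(r, dir)
  expect_true(file.exists(file.path(dir, "mean_report.json")))
  j <- jsonlite::read_json(file.path(dir, "mean_report.json"))
  expect_equal(j$pooled$mae, r$pooled$mae, tolerance = 1e-9)
  folds <- utils::read.csv(file.path(dir, "mean_folds.csv"))
  expect_equal(nrow(folds), 3)
  unlink(dir, recursive = TRUE)
})
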