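# Leave-one-subject-out evaluation: metric computation, stage labels,
# fold construction and the full LOSO driver.

#' Healing-stage label for a hematoma age
#'
#' Stages follow the dominant visual/biochemical phases of hematoma
#' evolution: early (0--3 days, fresh hemoglobin, reddish), middle (4--9
#' days, highest spectral contrast), late (>= 10 days, bilirubin
#' accumulation and fading).
#'
#' @param age_days Age in days (vectorized, each >= 0).
#' @return Character vector: `"early"`, `"middle"` or `"late"`.
#' @export
assign_stage <- function(age_days) {
  if (any(age_days < 0)) stop("negative hematoma age", call. = FALSE)
  ifelse(age_days <= 3, "early", ifelse(age_days <= 9, "middle", "late"))
}

#' Regression metrics for age predictions
#'
#' @param pred,truth Equal-length numeric vectors of predicted and true
#'   ages (days).
#' @return A list of class `metric_set`: `mae`, `rmse` (days), `r2`
#'   (`NA` with attribute `undefined = TRUE` when the truth is constant,
#'   i.e. `SS_tot = 0`), and threshold accuracies `acc1`, `acc2`, `acc3`
#'   (percent of predictions within +-1/2/3 days).
#' @examples
#' compute_metrics(c(0, 4), c(1, 2))  # MAE 1.5, Acc@1d 50%
#' @export
compute_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) > 0)
  e <- pred - truth
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (ss_tot == 0) {
    structure(NA_real_, undefined = TRUE)
  } else 1 - sum(e^2) / ss_tot
  structure(
    list(
      mae = mean(abs(e)),
      rmse = sqrt(mean(e^2)),
      r2 = r2,
      acc1 = 100 * mean(abs(e) <= 1),
      acc2 = 100 * mean(abs(e) <= 2),
      acc3 = 100 * mean(abs(e) <= 3),
      n = length(e)
    ),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "MAE %.3f d | RMSE %.3f d | R2 %s | Acc@1d %.1f%% | Acc@2d %.1f%% | Acc@3d %.1f%% (n=%d)\n",
    x$mae, x$rmse, ifelse(is.na(x$r2), "undef", sprintf("%.3f", x$r2)),
    x$acc1, x$acc2, x$acc3, x$n
  ))
  invisible(x)
}

#' Leave-one-subject-out fold structure
#'
#' One fold per subject (sorted ids, so the fold order is deterministic);
#' each fold holds out all of that subject's samples for testing and trains
#' on every other subject.
#'
#' @param dataset A `cohort_dataset` with at least two subjects.
#' @return List of folds, each a list with `test_subject`,
#'   `train_subjects`, `test_idx`, `train_idx` (sample indices).
#' @export
loso_split <- function(dataset) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  subjects <- sort(unique(dataset$metadata$subject_id))
  if (length(subjects) < 2) {
    stop("LOSO requires at least 2 subjects", call. = FALSE)
  }
  lapply(subjects, function(s) {
    test_idx <- which(dataset$metadata$subject_id == s)
    list(
      test_subject = s,
      train_subjects = setdiff(subjects, s),
      test_idx = test_idx,
      train_idx = which(dataset$metadata$subject_id != s)
    )
  })
}

#' Run leave-one-subject-out cross-validation
#'
#' Trains one model per fold and aggregates predictions.  For model types
#' with early stopping (the CNN), a validation subset of `n_val_subjects`
#' training subjects is carved out per fold (seeded, subject-level, so no
#' within-fold leakage); the Lasso and mean baselines train on all
#' training-fold samples.
#'
#' @param dataset A `cohort_dataset`.
#' @param spec A [model_spec()].
#' @param train_cfg A [train_config()] (used by the CNN; its `seed` drives
#'   all per-fold randomness for every model type).
#' @param n_val_subjects Training subjects reserved per fold for early
#'   stopping (CNN only).
#' @return An `eval_report`: `folds` (per-fold metrics data.frame),
#'   `pooled` and `mean_folds` [compute_metrics()] sets, `stage`
#'   (per-stage MAE with counts), `per_day` (per-ground-truth-day
#'   quartiles/mean of predictions), and `predictions` (per-sample table).
#' @export
run_loso <- function(dataset, spec, train_cfg = train_config(),
                     n_val_subjects = 2L) {
  stopifnot(inherits(dataset, "cohort_dataset"), inherits(spec, "model_spec"))
  folds <- loso_split(dataset)
  preds <- list()
  fold_rows <- list()
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    if (!length(fold$test_idx)) {
      warning(sprintf("fold %s has no test samples; skipped", fold$test_subject))
      next
    }
    # leakage audit: hard invariant, not just a test
    stopifnot(!any(fold$test_idx %in% fold$train_idx))
    fit <- .fit_fold(dataset, fold, spec, train_cfg, n_val_subjects,
                     fold_seed = train_cfg$seed + 7L * fi)
    test_ds <- dataset[fold$test_idx]
    p <- predict_ages(fit, test_ds)
    preds[[fi]] <- data.frame(
      sample_id = test_ds$metadata$sample_id,
      subject_id = test_ds$metadata$subject_id,
      true_age = test_ds$metadata$age_days,
      predicted_age = p,
      stage = test_ds$metadata$stage,
      fold = fold$test_subject,
      stringsAsFactors = FALSE
    )
    m <- compute_metrics(p, test_ds$metadata$age_days)
    fold_rows[[fi]] <- data.frame(
      test_subject = fold$test_subject, n = m$n, mae = m$mae, rmse = m$rmse,
      r2 = as.numeric(m$r2), acc1 = m$acc1, acc2 = m$acc2, acc3 = m$acc3,
      stringsAsFactors = FALSE
    )
  }
  predictions <- do.call(rbind, preds)
  fold_df <- do.call(rbind, fold_rows)
  rownames(predictions) <- rownames(fold_df) <- NULL
  pooled <- compute_metrics(predictions$predicted_age, predictions$true_age)
  mean_folds <- structure(
    list(
      mae = mean(fold_df$mae), rmse = mean(fold_df$rmse),
      r2 = mean(fold_df$r2, na.rm = TRUE),
      acc1 = mean(fold_df$acc1), acc2 = mean(fold_df$acc2),
      acc3 = mean(fold_df$acc3), n = sum(fold_df$n)
    ),
    class = "metric_set"
  )
  abs_err <- abs(predictions$predicted_age - predictions$true_age)
  stage_df <- do.call(rbind, lapply(c("early", "middle", "late"), function(st) {
    sel <- predictions$stage == st
    data.frame(
      stage = st, n = sum(sel),
      mae = if (any(sel)) mean(abs_err[sel]) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  per_day <- do.call(rbind, lapply(sort(unique(predictions$true_age)), function(d) {
    p <- predictions$predicted_age[predictions$true_age == d]
    data.frame(
      true_age = d, n = length(p), mean = mean(p),
      q25 = unname(stats::quantile(p, 0.25)),
      median = stats::median(p),
      q75 = unname(stats::quantile(p, 0.75)),
      stringsAsFactors = FALSE
    )
  }))
  structure(
    list(
      model = spec$type, folds = fold_df, pooled = pooled,
      mean_folds = mean_folds, stage = stage_df, per_day = per_day,
      predictions = predictions
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> model=%s, %d LOSO folds, %d predictions\n",
              x$model, nrow(x$folds), nrow(x$predictions)))
  cat("  pooled:     "); print(x$pooled)
  cat("  mean/folds: "); print(x$mean_folds)
  cat(sprintf("  stage MAE:  early %.2f (n=%d) | middle %.2f (n=%d) | late %.2f (n=%d)\n",
              x$stage$mae[1], x$stage$n[1], x$stage$mae[2], x$stage$n[2],
              x$stage$mae[3], x$stage$n[3]))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the report as machine-readable JSON plus CSV tables (per-fold
#' metrics, per-stage MAE, per-day prediction distribution, per-sample
#' predictions).
#'
#' @param report An `eval_report`.
#' @param dir Output directory (created if needed).
#' @param name Basename prefix for the files.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir, name = report$model) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(
      model = report$model,
      pooled = unclass(report$pooled),
      mean_folds = unclass(report$mean_folds),
      stage = report$stage
    ),
    file.path(dir, paste0(name, "_report.json")),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  utils::write.csv(report$folds, file.path(dir, paste0(name, "_folds.csv")), row.names = FALSE)
  utils::write.csv(report$stage, file.path(dir, paste0(name, "_stage.csv")), row.names = FALSE)
  utils::write.csv(report$per_day, file.path(dir, paste0(name, "_per_day.csv")), row.names = FALSE)
  utils::write.csv(report$predictions, file.path(dir, paste0(name, "_predictions.csv")), row.names = FALSE)
  invisible(dir)
}
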