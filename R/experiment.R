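# End-to-end experiment orchestration: phantom simulation -> preprocessing
# -> LOSO evaluation of the Lasso baseline and the CNN -> band-importance
# consensus -> reduced-band LOSO runs -> comparison tables.  One master
# seed expands deterministically into per-stage seeds; every output names
# the seed and a config hash.

#' Default experiment configuration
#'
#' @return A nested list of class `experiment_config` with sections
#'   `phantom` (simulator), `preprocess`, `cnn` (architecture), `train`
#'   (protocol), `subsets`, `k`, `seeds`.
#' @export
default_experiment_config <- function() {
  structure(
    list(
      phantom = list(
        n_subjects = 8L,
        acquisition_days = c(0, 1, 2, 3, 5, 6, 7, 9, 11, 13, 16, 19),
        image_size = c(48L, 48L),
        n_bands = 60L,
        lesion_radius_min = 4,
        lesion_radius_max = 14,
        heterogeneity = 0.6,
        visibility_threshold = 0
      ),
      preprocess = list(patch_size = NULL, masks = "truth", min_contrast = 0.025),
      cnn = list(
        spec_channels = c(4L, 4L, 8L), spec_kernels = c(7L, 5L, 3L),
        spec_pool_len = 8L, spat_channels = c(8L, 16L), spat_pool = 4L,
        head_hidden = 32L, dropout = 0.3
      ),
      train = list(
        lr = 2.5e-3, batch_size = 4L, weight_decay = 1e-5,
        max_epochs = 18L, patience = 8L, min_delta = 0.01, augment = TRUE,
        lr_schedule = "cosine", lr_end = 1.25e-4
      ),
      subsets = c("full", "topk"),
      k = 20L,
      seeds = 1L
    ),
    class = "experiment_config"
  )
}

.config_schema <- list(
  phantom = c("n_subjects", "acquisition_days", "image_size", "n_bands",
              "lesion_radius_min", "lesion_radius_max",
              "heterogeneity", "visibility_threshold"),
  preprocess = c("patch_size", "masks", "min_contrast"),
  cnn = c("spec_channels", "spec_kernels", "spec_pool_len", "spat_channels",
          "spat_pool", "head_hidden", "dropout"),
  train = c("lr", "batch_size", "weight_decay", "max_epochs", "patience",
            "min_delta", "augment", "lr_schedule", "lr_end"),
  subsets = NULL, k = NULL, seeds = NULL
)

#' Validate an experiment configuration
#'
#' Fills defaults for missing keys and collects every validation error
#' (unknown keys, wrong types, inconsistent values) rather than stopping
#' at the first.
#'
#' @param x A YAML file path, a list, or `NULL` (pure defaults).
#' @return An `experiment_config`, or an error listing all problems.
#' @export
validate_config <- function(x = NULL) {
  cfg <- default_experiment_config()
  user <- if (is.null(x)) list()
          else if (is.character(x)) {
            if (!file.exists(x)) stop(sprintf("config file '%s' not found", x), call. = FALSE)
            y <- yaml::read_yaml(x)
            if (is.null(y)) list() else y
          }
          else if (is.list(x)) x
          else stop("config must be a file path or a list", call. = FALSE)
  errs <- character()
  for (key in names(user)) {
    if (!key %in% names(.config_schema)) {
      errs <- c(errs, sprintf("unknown config key '%s'", key))
      next
    }
    sub <- .config_schema[[key]]
    if (is.null(sub)) {
      cfg[[key]] <- user[[key]]
    } else {
      for (k2 in names(user[[key]])) {
        if (!k2 %in% sub) {
          errs <- c(errs, sprintf("unknown config key '%s.%s'", key, k2))
        } else {
          cfg[[key]][[k2]] <- user[[key]][[k2]]
        }
      }
    }
  }
  # value checks (exhaustive)
  if (cfg$phantom$n_subjects < 2) errs <- c(errs, "phantom.n_subjects must be >= 2")
  if (cfg$phantom$n_bands < 3) errs <- c(errs, "phantom.n_bands must be >= 3")
  if (cfg$train$batch_size < 1) errs <- c(errs, "train.batch_size must be positive")
  if (cfg$train$lr <= 0) errs <- c(errs, "train.lr must be positive")
  if (cfg$train$max_epochs < 1) errs <- c(errs, "train.max_epochs must be positive")
  if (cfg$train$patience >= cfg$train$max_epochs) {
    errs <- c(errs, "train.patience must be < train.max_epochs")
  }
  if (cfg$k > cfg$phantom$n_bands) {
    errs <- c(errs, sprintf("k (%d) exceeds phantom.n_bands (%d)",
                            cfg$k, cfg$phantom$n_bands))
  }
  bad_subsets <- setdiff(cfg$subsets, c("full", "topk", "rgb", "physio"))
  if (length(bad_subsets)) {
    errs <- c(errs, sprintf("unknown subset name(s): %s",
                            paste(bad_subsets, collapse = ", ")))
  }
  if (!length(cfg$seeds)) errs <- c(errs, "seeds must be non-empty")
  if (length(errs)) {
    stop(paste0("invalid experiment config:\n  - ",
                paste(errs, collapse = "\n  - ")), call. = FALSE)
  }
  class(cfg) <- "experiment_config"
  cfg
}

.config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

# deterministic per-stage seed expansion from a master seed
.stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 2654435 + 97 * stage_index) %% 2147483629)
}

#' Run the full phantom experiment
#'
#' For each configured seed: simulate a phantom cohort, build the patch
#' dataset, run LOSO for the Lasso baseline and the full-band CNN, train a
#' tuning-split attribution model, compute SmoothGrad + occlusion
#' consensus band importance and the Top-k subset, run LOSO for each
#' configured reduced-band CNN, and write comparison tables (overall and
#' stage-wise MAE per configuration), the band-importance table, and a run
#' manifest naming the seed and config hash.
#'
#' @param config An `experiment_config` (see [validate_config()]).
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with per-seed results: `reports` (named list
#'   of `eval_report`), `importance` (band table), `comparison`
#'   (data.frame), plus `manifest`.
#' @export
run_experiment <- function(config = default_experiment_config(),
                           out_dir = tempfile("hematochron_run_"),
                           quiet = FALSE) {
  config <- validate_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  all_results <- list()
  comparison <- list()
  for (seed in config$seeds) {
    say("[seed %d] simulating phantom cohort", seed)
    pp <- phantom_params(
      n_subjects = config$phantom$n_subjects,
      acquisition_days = config$phantom$acquisition_days,
      image_size = config$phantom$image_size,
      n_bands = config$phantom$n_bands,
      lesion_radius_min = config$phantom$lesion_radius_min,
      lesion_radius_max = config$phantom$lesion_radius_max,
      heterogeneity = config$phantom$heterogeneity,
      visibility_threshold = config$phantom$visibility_threshold,
      seed = .stage_seed(seed, 1L)
    )
    cohort <- generate_cohort(pp)
    dataset <- build_dataset(
      cohort,
      patch_size = config$preprocess$patch_size,
      masks = config$preprocess$masks,
      min_contrast = config$preprocess$min_contrast
    )
    tc <- train_config(
      lr = config$train$lr, batch_size = config$train$batch_size,
      weight_decay = config$train$weight_decay,
      max_epochs = config$train$max_epochs, patience = config$train$patience,
      min_delta = config$train$min_delta, augment = config$train$augment,
      lr_schedule = config$train$lr_schedule, lr_end = config$train$lr_end,
      seed = .stage_seed(seed, 2L)
    )
    cnn_cfg <- function(nb) {
      cnn_config(
        n_bands = nb,
        spec_channels = config$cnn$spec_channels,
        spec_kernels = config$cnn$spec_kernels,
        spec_pool_len = config$cnn$spec_pool_len,
        spat_channels = config$cnn$spat_channels,
        spat_pool = config$cnn$spat_pool,
        head_hidden = config$cnn$head_hidden,
        dropout = config$cnn$dropout
      )
    }
    nb <- dim(dataset$patches)[1]
    reports <- list()
    say("[seed %d] LOSO: lasso baseline", seed)
    reports$lasso <- run_loso(dataset, model_spec("lasso"), tc)
    say("[seed %d] LOSO: mean predictor", seed)
    reports$mean <- run_loso(dataset, model_spec("mean"), tc)
    say("[seed %d] LOSO: full-band CNN", seed)
    reports$cnn_full <- run_loso(dataset, model_spec("cnn", cnn_cfg(nb)), tc)

    # attribution model on a tuning split (last two subjects validate)
    subs <- sort(unique(dataset$metadata$subject_id))
    val_subj <- utils::tail(subs, min(2L, length(subs) - 1L))
    val_idx <- which(dataset$metadata$subject_id %in% val_subj)
    tr_idx <- setdiff(seq_len(n_samples(dataset)), val_idx)
    say("[seed %d] band importance (tuning-split model)", seed)
    att_model <- train_cnn(
      cnn_cfg(nb),
      dataset$patches[, , , tr_idx, drop = FALSE],
      dataset$metadata$age_days[tr_idx],
      dataset$patches[, , , val_idx, drop = FALSE],
      dataset$metadata$age_days[val_idx],
      tc
    )
    # attribution on the tuning-split validation samples; replacement means
    # come from the training split
    att_x <- dataset$patches[, , , val_idx, drop = FALSE]
    sg <- smoothgrad_importance(att_model, att_x, seed = .stage_seed(seed, 3L))
    band_means <- rowMeans(matrix(dataset$patches[, , , tr_idx, drop = FALSE], nrow = nb))
    oc <- occlusion_importance(att_model, att_x,
                               truth = dataset$metadata$age_days[val_idx],
                               replacement = "train_mean",
                               band_means = band_means)
    consensus <- rank_consensus(sg, oc)
    topk <- top_k(consensus, config$k, dataset$axis)
    imp_table <- band_importance_table(sg, oc, consensus, dataset$axis, topk)
    utils::write.csv(imp_table,
                     file.path(out_dir, sprintf("importance_seed%d.csv", seed)),
                     row.names = FALSE)

    for (sub_name in setdiff(config$subsets, "full")) {
      sub <- if (sub_name == "topk") topk
             else make_subset(sub_name, dataset$axis)
      ds_sub <- apply_subset(dataset, sub)
      say("[seed %d] LOSO: CNN on %s subset (%d bands)", seed, sub_name,
          length(sub$indices))
      reports[[paste0("cnn_", sub_name)]] <-
        run_loso(ds_sub, model_spec("cnn", cnn_cfg(length(sub$indices))), tc)
    }

    for (nm in names(reports)) {
      r <- reports[[nm]]
      comparison[[length(comparison) + 1L]] <- data.frame(
        seed = seed, model = nm,
        mae = r$pooled$mae, rmse = r$pooled$rmse, r2 = as.numeric(r$pooled$r2),
        acc1 = r$pooled$acc1, acc2 = r$pooled$acc2, acc3 = r$pooled$acc3,
        mae_early = r$stage$mae[r$stage$stage == "early"],
        mae_middle = r$stage$mae[r$stage$stage == "middle"],
        mae_late = r$stage$mae[r$stage$stage == "late"],
        stringsAsFactors = FALSE
      )
      write_eval_report(r, out_dir, sprintf("%s_seed%d", nm, seed))
    }
    all_results[[as.character(seed)]] <- list(
      reports = reports, importance = imp_table, topk = topk,
      informative_bands = dataset$informative_bands
    )
  }
  comparison <- do.call(rbind, comparison)
  utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("hematochron")),
    config = unclass(config),
    config_hash = hash,
    seeds = config$seeds,
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = all_results, comparison = comparison,
                 manifest = manifest, out_dir = out_dir))
}
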