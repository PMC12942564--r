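# Model-spec abstraction shared by LOSO evaluation and band importance:
# the spectral-spatial CNN, the Lasso-on-mean-spectrum baseline, and a
# mean-predictor dummy used as a floor reference.

#' Training protocol configuration
#'
#' Defaults follow the protocol the package's CNN is trained under at full
#' scale: Adam (learning rate 1e-3, batch size 32, weight decay 1e-5), up
#' to 100 epochs, random horizontal/vertical flip augmentation, and early
#' stopping when validation MAE fails to improve by at least `min_delta`
#' for `patience` consecutive epochs, with best-epoch weight restoration.
#'
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param weight_decay L2 penalty added to gradients.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs); must be < `max_epochs`.
#' @param min_delta Minimum validation-MAE improvement (days) that resets
#'   the patience counter.
#' @param augment Apply random horizontal + vertical flips (independent
#'   probability 0.5 per axis per draw) during training.
#' @param lr_schedule `"constant"` (the full-scale default) or `"cosine"`
#'   (cosine annealing from `lr` down to `lr_end`; useful when the epoch
#'   budget is tight).
#' @param lr_end Final learning rate of the cosine schedule.
#' @param seed Integer seed controlling initialization, shuffling, dropout
#'   and augmentation.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, batch_size = 32L, weight_decay = 1e-5,
                         max_epochs = 100L, patience = 25L, min_delta = 0.01,
                         augment = TRUE, lr_schedule = c("constant", "cosine"),
                         lr_end = lr / 20, seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(lr > 0, batch_size >= 1, weight_decay >= 0, max_epochs >= 1,
            patience >= 1, patience < max_epochs, min_delta >= 0, lr_end > 0)
  structure(
    list(lr = lr, batch_size = as.integer(batch_size),
         weight_decay = weight_decay, max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), min_delta = min_delta,
         augment = isTRUE(augment), lr_schedule = lr_schedule,
         lr_end = lr_end, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Model specification for LOSO evaluation
#'
#' @param type `"cnn"` (spectral-spatial network), `"lasso"` (L1-penalized
#'   regression on spatially averaged spectra) or `"mean"` (predicts the
#'   training-set mean age; a floor baseline).
#' @param config For `"cnn"`, a [cnn_config()]; ignored otherwise.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(type = c("cnn", "lasso", "mean"), config = NULL) {
  type <- match.arg(type)
  if (type == "cnn" && !is.null(config)) stopifnot(inherits(config, "cnn_config"))
  structure(list(type = type, config = config), class = "model_spec")
}

# fit one LOSO fold for any model type
.fit_fold <- function(dataset, fold, spec, train_cfg, n_val_subjects, fold_seed) {
  train_ds <- dataset[fold$train_idx]
  if (spec$type == "mean") {
    return(structure(list(mean_age = mean(train_ds$metadata$age_days)),
                     class = "mean_model"))
  }
  if (spec$type == "lasso") {
    sig <- spatial_average(train_ds)
    return(fit_lasso(sig, train_ds$metadata$age_days,
                     subject_ids = train_ds$metadata$subject_id))
  }
  # CNN: carve a subject-level validation split out of the training
  # subjects; with a single training subject (minimal cohorts) fall back
  # to holding out a quarter of its samples
  tr_subj <- sort(unique(train_ds$metadata$subject_id))
  nv <- min(n_val_subjects, length(tr_subj) - 1L)
  val_idx <- if (nv >= 1L) {
    val_subj <- .with_seed(fold_seed %% 2147483629L, sample(tr_subj, nv))
    which(train_ds$metadata$subject_id %in% val_subj)
  } else {
    .with_seed(fold_seed %% 2147483629L,
               sample(n_samples(train_ds), max(1L, n_samples(train_ds) %/% 4L)))
  }
  fit_idx <- setdiff(seq_len(n_samples(train_ds)), val_idx)
  cfg <- if (is.null(spec$config)) cnn_config(n_bands = dim(dataset$patches)[1]) else spec$config
  tc <- train_cfg
  tc$seed <- as.integer(fold_seed %% 2147483629L)
  train_cnn(cfg,
            x_train = train_ds$patches[, , , fit_idx, drop = FALSE],
            y_train = train_ds$metadata$age_days[fit_idx],
            x_val = train_ds$patches[, , , val_idx, drop = FALSE],
            y_val = train_ds$metadata$age_days[val_idx],
            train_cfg = tc)
}

#' Predict hematoma ages with a fitted model
#'
#' Deterministic inference (no augmentation, no dropout); one finite
#' prediction per sample, order-preserving.
#'
#' @param model A fitted model (`cnn_model`, `lasso_model`, `mean_model`
#'   or `linear_band_model`).
#' @param newdata A `cohort_dataset` or a patch array `(bands, P, P, n)`.
#' @return Numeric vector of predicted ages (days).
#' @export
predict_ages <- function(model, newdata) UseMethod("predict_ages")

.as_patches <- function(newdata) {
  if (inherits(newdata, "cohort_dataset")) newdata$patches
  else {
    stopifnot(is.array(newdata), length(dim(newdata)) %in% c(3, 4))
    if (length(dim(newdata)) == 3) array(newdata, dim = c(dim(newdata), 1))
    else newdata
  }
}

#' @export
predict_ages.mean_model <- function(model, newdata) {
  rep(model$mean_age, dim(.as_patches(newdata))[4])
}

#' Fit the Lasso baseline on spatially averaged spectra
#'
#' L1-penalized linear regression of hematoma age on the per-sample mean
#' spectrum, with the penalty chosen by internal cross-validation over a
#' logarithmic grid, grouped by subject when subject ids are supplied (so
#' the internal CV never leaks a subject across its folds).  The L1 penalty
#' drives uninformative band coefficients to exactly zero, giving an
#' implicit wavelength selection.
#'
#' @param signatures Numeric matrix `n_samples x n_bands` of mean spectra.
#' @param ages Numeric vector of hematoma ages (days).
#' @param subject_ids Optional subject id per sample for grouped internal CV.
#' @param nlambda Number of penalties on the logarithmic grid.
#' @param nfolds Internal CV folds.
#' @return A `lasso_model`: the fitted glmnet object, the selected
#'   `lambda`, and `nonzero_bands` (indices with nonzero coefficients).
#' @export
fit_lasso <- function(signatures, ages, subject_ids = NULL,
                      nlambda = 50L, nfolds = 5L) {
  stopifnot(is.matrix(signatures), nrow(signatures) == length(ages),
            nrow(signatures) >= 2)
  if (stats::var(ages) == 0) {
    return(structure(list(constant = ages[1], lambda = Inf,
                          nonzero_bands = integer()),
                     class = "lasso_model"))
  }
  n <- length(ages)
  foldid <- if (!is.null(subject_ids) && length(unique(subject_ids)) >= 4) {
    subs <- sort(unique(subject_ids))
    grp <- rep(seq_len(min(nfolds, length(subs))), length.out = length(subs))
    grp[match(subject_ids, subs)]
  } else if (n >= 8) {
    rep(seq_len(min(nfolds, n %/% 2)), length.out = n)  # deterministic
  } else NULL
  if (is.null(foldid)) {
    # too few samples for cross-validation: take a mild fixed penalty from
    # the glmnet path
    fit <- glmnet::glmnet(signatures, ages, alpha = 1, nlambda = nlambda,
                          standardize = TRUE)
    lam <- fit$lambda[min(length(fit$lambda), max(1L, length(fit$lambda) %/% 2L))]
    cf <- stats::coef(fit, s = lam)
    return(structure(
      list(fit = fit, lambda = lam, s = lam,
           nonzero_bands = which(as.numeric(cf)[-1] != 0)),
      class = "lasso_model"
    ))
  }
  cv <- suppressWarnings(glmnet::cv.glmnet(
    signatures, ages, alpha = 1, nlambda = nlambda,
    foldid = foldid,
    type.measure = "mae", standardize = TRUE
  ))
  cf <- stats::coef(cv, s = "lambda.min")
  nz <- which(as.numeric(cf)[-1] != 0)
  structure(
    list(fit = cv, lambda = cv$lambda.min, s = "lambda.min", nonzero_bands = nz),
    class = "lasso_model"
  )
}

#' @export
predict_ages.lasso_model <- function(model, newdata) {
  x <- if (inherits(newdata, "cohort_dataset")) spatial_average(newdata)
       else if (is.matrix(newdata)) newdata
       else spatial_average(.as_patches(newdata))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (!is.null(model$constant)) return(rep(model$constant, nrow(x)))
  as.numeric(stats::predict(model$fit, newx = x, s = model$s))
}

#' A linear toy model on per-band mean reflectance
#'
#' Predicts `intercept + sum_b coef[b] * mean(band b)`.  Mainly useful as
#' an analytically tractable reference when validating attribution methods
#' (its input gradient is exactly `coef[b] / n_pixels` for every pixel of
#' band `b`).
#'
#' @param coef Numeric vector of per-band coefficients.
#' @param intercept Intercept (days).
#' @return A `linear_band_model`.
#' @export
linear_band_model <- function(coef, intercept = 0) {
  structure(list(coef = as.numeric(coef), intercept = intercept),
            class = "linear_band_model")
}

#' @export
predict_ages.linear_band_model <- function(model, newdata) {
  p <- .as_patches(newdata)
  stopifnot(dim(p)[1] == length(model$coef))
  sig <- t(apply(p, 4, function(a) rowMeans(matrix(a, nrow = dim(p)[1]))))
  if (dim(p)[4] == 1) sig <- matrix(sig, nrow = 1)
  as.numeric(model$intercept + sig %*% model$coef)
}
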