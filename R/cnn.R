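# R surface of the spectral-spatial CNN regressor.

#' Configuration of the spectral-spatial CNN
#'
#' The default configuration is the full-scale architecture: a per-pixel
#' spectral Conv1D encoder (channel widths 128/64/32 with kernels 7/5/3 and
#' same-padding), adaptive average pooling of the spectral axis to length
#' 16 followed by averaging to a 32-vector per pixel, two spatial 3x3
#' Conv2D blocks (64 then 128 channels, each with 2x2 max pooling),
#' adaptive 4x4 average pooling, and a 2048 -> 256 -> 1 regression head
#' with dropout 0.3.  Every convolution is followed by ReLU and then
#' BatchNorm.  The architecture is parametrized over the band count, so the
#' same configuration serves full-spectrum and reduced-band inputs.
#'
#' @param n_bands Number of input spectral bands.
#' @param spec_channels Channel widths of the three spectral Conv1D layers.
#' @param spec_kernels Kernel sizes of the spectral convs (same-padded).
#' @param spec_pool_len Adaptive spectral pooling length L.
#' @param spat_channels Channel widths of the two spatial Conv2D layers.
#' @param spat_pool Side length of the adaptive spatial average pool.
#' @param head_hidden Width of the hidden linear layer.
#' @param dropout Dropout rate in the regression head.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(n_bands = 204L,
                       spec_channels = c(128L, 64L, 32L),
                       spec_kernels = c(7L, 5L, 3L),
                       spec_pool_len = 16L,
                       spat_channels = c(64L, 128L),
                       spat_pool = 4L,
                       head_hidden = 256L,
                       dropout = 0.3) {
  stopifnot(length(spec_channels) == 3, length(spec_kernels) == 3,
            length(spat_channels) == 2, all(spec_channels >= 1),
            all(spat_channels >= 1), spec_pool_len >= 1, spat_pool >= 1,
            head_hidden >= 1, dropout >= 0, dropout < 1)
  if (n_bands < min(spec_kernels)) {
    stop("n_bands must be at least the smallest spectral kernel", call. = FALSE)
  }
  structure(
    list(
      n_bands = as.integer(n_bands),
      spec_channels = as.integer(spec_channels),
      spec_kernels = as.integer(spec_kernels),
      spec_pool_len = as.integer(spec_pool_len),
      spat_channels = as.integer(spat_channels),
      spat_pool = as.integer(spat_pool),
      head_hidden = as.integer(head_hidden),
      dropout = dropout
    ),
    class = "cnn_config"
  )
}

#' Reduced-capacity CNN configuration for phantom-scale experiments
#'
#' Same architecture family as [cnn_config()] with slimmer channel widths
#' (4/4/8 spectral, 8/16 spatial, 32-unit head, spectral pool length 8),
#' sized for the small synthetic cohorts used in tests and examples, where
#' the full-scale capacity would be both unnecessary and slow on a single
#' CPU core.
#'
#' @param n_bands Number of input spectral bands.
#' @return A `cnn_config`.
#' @export
phantom_cnn_config <- function(n_bands) {
  cnn_config(
    n_bands = n_bands,
    spec_channels = c(4L, 4L, 8L),
    spec_kernels = c(7L, 5L, 3L),
    spec_pool_len = 8L,
    spat_channels = c(8L, 16L),
    spat_pool = 4L,
    head_hidden = 32L,
    dropout = 0.3
  )
}

#' Build (initialize) a CNN model
#'
#' He-initialized weights; the model is untrained but fully functional for
#' forward passes, shape tracing and gradient computation.
#'
#' @param config A [cnn_config()].
#' @param seed Integer seed for weight initialization.
#' @return A list of class `cnn_model` with `config`, `weights`, and empty
#'   training `history`.
#' @export
build_cnn <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cnn_config"))
  structure(
    list(config = config, weights = cpp_cnn_init(config, as.integer(seed)),
         in_mean = 0, in_sd = 1, history = NULL),
    class = "cnn_model"
  )
}

#' Train the CNN with Adam, augmentation and early stopping
#'
#' Minimizes mean squared error on the training patches while monitoring
#' mean absolute error on a held-out validation set; training stops early
#' when validation MAE fails to improve by at least `min_delta` for
#' `patience` consecutive epochs, and the best-validation-epoch weights are
#' restored.  Deterministic given `train_cfg$seed`.
#'
#' @param config A [cnn_config()].
#' @param x_train,x_val Patch arrays `(bands, P, P, n)`.
#' @param y_train,y_val Ages (days).
#' @param train_cfg A [train_config()].
#' @return A trained `cnn_model`; `history` holds per-epoch training loss
#'   and validation MAE, `best_epoch` the restored epoch.
#' @export
train_cnn <- function(config, x_train, y_train, x_val, y_val,
                      train_cfg = train_config()) {
  stopifnot(inherits(config, "cnn_config"), inherits(train_cfg, "train_config"))
  stopifnot(length(dim(x_train)) == 4, length(dim(x_val)) == 4)
  if (length(y_train) != dim(x_train)[4]) stop("y_train length mismatch", call. = FALSE)
  if (dim(x_val)[4] == 0 || length(y_val) == 0) {
    stop("validation set must be nonempty (early stopping monitors it)", call. = FALSE)
  }
  init <- cpp_cnn_init(config, train_cfg$seed)
  res <- cpp_cnn_train(
    config, init,
    as.numeric(x_train), as.numeric(y_train), as.integer(dim(x_train)),
    as.numeric(x_val), as.numeric(y_val), as.integer(dim(x_val)),
    unclass(train_cfg)
  )
  structure(
    list(
      config = config, weights = res$weights,
      in_mean = res$in_mean, in_sd = res$in_sd,
      history = data.frame(
        epoch = seq_along(res$train_loss),
        train_loss = unlist(res$train_loss),
        val_mae = unlist(res$val_mae)
      ),
      best_epoch = res$best_epoch,
      best_val_mae = res$best_val_mae,
      seed = train_cfg$seed
    ),
    class = "cnn_model"
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_model> %d bands, spectral %s, spatial %s, head %d; %s\n",
    x$config$n_bands,
    paste(x$config$spec_channels, collapse = "/"),
    paste(x$config$spat_channels, collapse = "/"),
    x$config$head_hidden,
    if (is.null(x$history)) "untrained"
    else sprintf("trained %d epochs (best %d, val MAE %.3f d)",
                 nrow(x$history), x$best_epoch, x$best_val_mae)
  ))
  invisible(x)
}

#' @export
predict_ages.cnn_model <- function(model, newdata) {
  p <- .as_patches(newdata)
  if (dim(p)[1] != model$config$n_bands) {
    stop(sprintf("input has %d bands but model expects %d",
                 dim(p)[1], model$config$n_bands), call. = FALSE)
  }
  x <- (as.numeric(p) - model$in_mean) / model$in_sd
  as.numeric(cpp_cnn_predict(model$config, model$weights,
                             x, as.integer(dim(p))))
}

#' Layer-by-layer shape trace of a forward pass
#'
#' Runs one sample through the network and records the realized shape at
#' every architectural stage (per-pixel shapes for the spectral encoder,
#' per-sample shapes for the spatial stage and head).
#'
#' @param model A `cnn_model`.
#' @param patch_size Spatial side length of the probe input.
#' @return Named list of integer shape vectors, in forward order.
#' @export
cnn_shape_trace <- function(model, patch_size = 64L) {
  stopifnot(inherits(model, "cnn_model"))
  nb <- model$config$n_bands
  x <- array(0, dim = c(nb, patch_size, patch_size, 1L))
  cpp_cnn_trace(model$config, model$weights, as.numeric(x), as.integer(dim(x)))
}

#' Gradient of the CNN output with respect to its input
#'
#' Inference-mode (running BatchNorm statistics, no dropout) gradient of
#' the scalar age prediction with respect to every input element, per
#' sample.  This is the primitive behind SmoothGrad band attribution.
#'
#' @param model A `cnn_model`.
#' @param x Patch array `(bands, P, P, n)`.
#' @return Array of the same shape as `x`.
#' @export
cnn_input_gradient <- function(model, x) {
  stopifnot(inherits(model, "cnn_model"))
  p <- .as_patches(x)
  xs <- (as.numeric(p) - model$in_mean) / model$in_sd
  g <- cpp_cnn_input_grad(model$config, model$weights,
                          xs, as.integer(dim(p)))
  # chain rule through the input standardization
  g / model$in_sd
}
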