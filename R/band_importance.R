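# Spectral configurations and consensus band importance.
#
# Two attribution methods are combined: SmoothGrad (noise-averaged absolute
# input gradients, aggregated per band) and occlusion sensitivity (MAE
# degradation when one band is replaced by an uninformative value).  Their
# per-band ranks are averaged into a consensus rank (1 = most important),
# from which the Top-k acquisition subset is taken.

new_band_score <- function(scores, method, axis = NULL) {
  structure(
    list(scores = as.numeric(scores), method = method, axis = axis),
    class = "band_score"
  )
}

#' @export
print.band_score <- function(x, ...) {
  cat(sprintf("<band_score> %s, %d bands, top band index %d\n",
              x$method, length(x$scores),
              if (x$method == "consensus-rank") which.min(x$scores)
              else which.max(x$scores)))
  invisible(x)
}

#' SmoothGrad band importance
#'
#' Adds Gaussian noise to the input patches, computes the gradient of the
#' predicted age with respect to every input element, and aggregates the
#' absolute gradients per spectral band (mean over noise draws, samples and
#' pixels).  With `noise_sd = 0` and `n_draws = 1` this reduces to plain
#' gradient saliency.
#'
#' @param model A trained `cnn_model`, or a [linear_band_model()] (whose
#'   gradient is analytic).
#' @param x Patch array `(bands, P, P, n)` or a `cohort_dataset`.
#' @param noise_sd Noise standard deviation as a fraction of the standard
#'   deviation of `x` (default 0.1).
#' @param n_draws Number of noise draws (default 25).
#' @param seed Integer seed for the noise.
#' @return A `band_score` with method `"smoothgrad"`.
#' @export
smoothgrad_importance <- function(model, x, noise_sd = 0.1, n_draws = 25L,
                                  seed = 1L) {
  if (n_draws < 1) stop("`n_draws` must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  p <- .as_patches(x)
  nb <- dim(p)[1]
  sd_x <- stats::sd(as.vector(p))
  acc <- numeric(nb)
  .with_seed(seed, {
    for (d in seq_len(n_draws)) {
      xd <- if (noise_sd > 0) {
        p + array(stats::rnorm(length(p), sd = noise_sd * sd_x), dim = dim(p))
      } else p
      g <- if (inherits(model, "linear_band_model")) {
        # gradient of intercept + sum_b coef[b] * mean(band b) is
        # coef[b]/n_pixels at every pixel of band b
        array(model$coef / prod(dim(p)[2:3]), dim = dim(p))
      } else {
        cnn_input_gradient(model, xd)
      }
      acc <- acc + rowMeans(abs(matrix(g, nrow = nb)))
    }
  })
  new_band_score(acc / n_draws, "smoothgrad")
}

#' Occlusion-sensitivity band importance
#'
#' Sequentially replaces each spectral band of every sample with an
#' uninformative value and measures the resulting degradation of MAE:
#' `score[b] = MAE(band b occluded) - MAE(baseline)`.  Scores are signed; a
#' negative value means occlusion helped.
#'
#' @param model A fitted model accepted by [predict_ages()].
#' @param x Patch array `(bands, P, P, n)` or a `cohort_dataset`.
#' @param truth True ages (days), one per sample (taken from the dataset
#'   metadata when `x` is a `cohort_dataset`).
#' @param replacement Occlusion policy: `"train_mean"` replaces the band by
#'   `band_means[b]`, `"zero"` by 0, `"identity"` by the band's own values
#'   (a no-op control yielding all-zero scores).
#' @param band_means Per-band replacement values (required for
#'   `"train_mean"`; typically the training-set per-band mean reflectance).
#' @return A `band_score` with method `"occlusion"` and attribute
#'   `baseline_mae`.
#' @export
occlusion_importance <- function(model, x, truth = NULL,
                                 replacement = c("train_mean", "zero", "identity"),
                                 band_means = NULL) {
  replacement <- match.arg(replacement)
  if (inherits(x, "cohort_dataset") && is.null(truth)) truth <- x$metadata$age_days
  p <- .as_patches(x)
  nb <- dim(p)[1]
  if (is.null(truth) || length(truth) != dim(p)[4]) {
    stop("`truth` must give one age per sample", call. = FALSE)
  }
  if (replacement == "train_mean") {
    if (is.null(band_means) || length(band_means) != nb) {
      stop("`band_means` (one value per band) is required for train_mean replacement",
           call. = FALSE)
    }
  }
  baseline <- mean(abs(predict_ages(model, p) - truth))
  scores <- vapply(seq_len(nb), function(b) {
    pb <- p
    pb[b, , , ] <- switch(replacement,
      train_mean = band_means[b],
      zero = 0,
      identity = pb[b, , , ]
    )
    mean(abs(predict_ages(model, pb) - truth)) - baseline
  }, numeric(1))
  out <- new_band_score(scores, "occlusion")
  attr(out, "baseline_mae") <- baseline
  out
}

#' Consensus rank of two band-importance scores
#'
#' Ranks bands within each method (rank 1 = highest score = most
#' important, ties receive average ranks) and averages the two ranks.
#' Lower consensus values mean more important bands.  The operation is
#' symmetric in its arguments.
#'
#' @param a,b `band_score` objects of equal length (any method other than
#'   `consensus-rank`).
#' @return A `band_score` with method `"consensus-rank"` whose `scores`
#'   are the averaged ranks.
#' @export
rank_consensus <- function(a, b) {
  stopifnot(inherits(a, "band_score"), inherits(b, "band_score"))
  if (length(a$scores) != length(b$scores)) {
    stop("band score lengths differ", call. = FALSE)
  }
  ra <- rank(-a$scores, ties.method = "average")
  rb <- rank(-b$scores, ties.method = "average")
  new_band_score((ra + rb) / 2, "consensus-rank")
}

#' Top-k band subset from a consensus score
#'
#' Selects the `k` bands with the smallest consensus rank; ties at the cut
#' are broken toward the lower band index.  The result is sorted by band
#' index.
#'
#' @param consensus A `band_score` with method `"consensus-rank"`.
#' @param k Number of bands (default 20).
#' @param axis Optional `wavelength_axis` to attach wavelengths.
#' @return A `band_subset` named `"topk"`.
#' @export
top_k <- function(consensus, k = 20L, axis = NULL) {
  stopifnot(inherits(consensus, "band_score"))
  n <- length(consensus$scores)
  if (k > n) stop(sprintf("k = %d exceeds band count %d", k, n), call. = FALSE)
  ord <- order(consensus$scores, seq_len(n))
  idx <- sort(ord[seq_len(k)])
  new_band_subset("topk", idx, axis)
}

new_band_subset <- function(name, indices, axis = NULL) {
  structure(
    list(
      name = name, indices = as.integer(indices),
      wavelengths = if (!is.null(axis)) axis$centers[indices] else NULL
    ),
    class = "band_subset"
  )
}

#' @export
print.band_subset <- function(x, ...) {
  cat(sprintf("<band_subset> %s: %d bands\n", x$name, length(x$indices)))
  invisible(x)
}

#' Construct one of the standard spectral input configurations
#'
#' Four acquisition configurations share one CNN architecture: `rgb`
#' (bands nearest 460/540/650 nm, emulating Bayer-filter color imaging),
#' `physio` (`rgb` plus the hemoglobin-sensitive 504/569/578 nm bands),
#' `full` (all bands), and `topk` (the `k` best consensus-ranked bands).
#'
#' @param name One of `"rgb"`, `"physio"`, `"full"`, `"topk"`.
#' @param axis A `wavelength_axis`.
#' @param consensus For `"topk"`: a consensus `band_score`.
#' @param k For `"topk"`: subset size (default 20).
#' @return A `band_subset`.
#' @export
make_subset <- function(name = c("rgb", "physio", "full", "topk"), axis,
                        consensus = NULL, k = 20L) {
  name <- match.arg(name)
  stopifnot(inherits(axis, "wavelength_axis"))
  rgb_nm <- c(460, 540, 650)
  physio_nm <- c(504, 569, 578)
  if (name == "rgb") {
    idx <- sort(unique(vapply(rgb_nm, nearest_band, integer(1), axis = axis)))
    return(new_band_subset("rgb", idx, axis))
  }
  if (name == "physio") {
    idx <- sort(unique(vapply(c(rgb_nm, physio_nm), nearest_band, integer(1),
                              axis = axis)))
    return(new_band_subset("physio", idx, axis))
  }
  if (name == "full") {
    return(new_band_subset("full", seq_along(axis$centers), axis))
  }
  if (is.null(consensus)) {
    stop("a consensus band score is required for the topk subset", call. = FALSE)
  }
  out <- top_k(consensus, k, axis)
  out
}

#' Restrict a dataset to a band subset
#'
#' @param dataset A `cohort_dataset`.
#' @param subset A `band_subset` with indices valid for the dataset.
#' @return A `cohort_dataset` whose patches and wavelength axis are
#'   restricted to the subset bands (in index order).
#' @export
apply_subset <- function(dataset, subset) {
  stopifnot(inherits(dataset, "cohort_dataset"), inherits(subset, "band_subset"))
  nb <- dim(dataset$patches)[1]
  if (any(subset$indices < 1 | subset$indices > nb)) {
    stop("subset band indices out of range", call. = FALSE)
  }
  out <- dataset
  out$patches <- dataset$patches[subset$indices, , , , drop = FALSE]
  out$axis <- subset_axis(dataset$axis, subset$indices)
  out$informative_bands <-
    which(subset$indices %in% dataset$informative_bands)
  out
}

#' Tabulate band-importance results
#'
#' @param smoothgrad,occlusion,consensus `band_score` objects.
#' @param axis A `wavelength_axis`.
#' @param topk Optional `band_subset` marking selected bands.
#' @return A data.frame with one row per band: `band_index`,
#'   `wavelength_nm`, `score_smoothgrad`, `score_occlusion`,
#'   `consensus_rank`, `selected_topk`.
#' @export
band_importance_table <- function(smoothgrad, occlusion, consensus, axis,
                                  topk = NULL) {
  n <- length(consensus$scores)
  data.frame(
    band_index = seq_len(n),
    wavelength_nm = axis$centers,
    score_smoothgrad = smoothgrad$scores,
    score_occlusion = occlusion$scores,
    consensus_rank = consensus$scores,
    selected_topk = if (is.null(topk)) FALSE else seq_len(n) %in% topk$indices
  )
}
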