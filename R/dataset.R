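# CohortDataset: the unit handed to the models and to LOSO evaluation.
# Holds all extracted patches as one array (bands, P, P, n) plus per-sample
# metadata; subjects are the grouping unit for cross-validation.

new_cohort_dataset <- function(patches, metadata, axis, exclusions = NULL,
                               informative_bands = integer()) {
  stopifnot(is.array(patches), length(dim(patches)) == 4,
            dim(patches)[4] == nrow(metadata))
  structure(
    list(
      patches = patches, metadata = metadata, axis = axis,
      exclusions = if (is.null(exclusions))
        data.frame(sample_id = character(), reason = character()) else exclusions,
      informative_bands = informative_bands
    ),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  d <- dim(x$patches)
  cat(sprintf(
    "<cohort_dataset> %d samples (%d subjects), %d bands, %dx%d patches, %d excluded\n",
    d[4], length(unique(x$metadata$subject_id)), d[1], d[2], d[3],
    nrow(x$exclusions)
  ))
  invisible(x)
}

#' Number of samples in a cohort dataset
#' @param x A `cohort_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "cohort_dataset"))
  dim(x$patches)[4]
}

#' Subset a cohort dataset by sample indices
#' @param x A `cohort_dataset`.
#' @param i Sample indices (or logical vector).
#' @param ... Unused.
#' @return A `cohort_dataset` with the selected samples.
#' @export
`[.cohort_dataset` <- function(x, i, ...) {
  new_cohort_dataset(
    x$patches[, , , i, drop = FALSE],
    x$metadata[i, , drop = FALSE],
    x$axis, x$exclusions, x$informative_bands
  )
}

#' Build a patch dataset from a phantom cohort or an on-disk metadata table
#'
#' Runs the full preprocessing pipeline per sample: radiometric
#' normalization, lesion localization (built-in segmenter, externally
#' supplied masks, or the phantom's ground-truth masks), centroid
#' computation, and fixed-size patch extraction.  Samples for which no
#' lesion is found are excluded and logged with a reason; mask provenance
#' is recorded per sample.
#'
#' @param x A [generate_cohort()] result, or the path of a metadata CSV
#'   with columns `sample_id`, `subject_id`, `age_days`, `stage`,
#'   `path_cube`, `path_white`, `path_dark` and (for external/truth masks)
#'   `path_mask`, referencing ENVI files as written by
#'   [write_phantom_cohort()].
#' @param patch_size Patch side length; defaults to 64 or the largest size
#'   the frames allow, whichever is smaller.
#' @param masks Mask source: `"builtin"` (spectral-contrast segmenter),
#'   `"truth"` (phantom ground-truth masks), or `"external"`
#'   (`path_mask` files; file input only).
#' @param min_contrast Visibility threshold passed to [segment_lesion()]
#'   when `masks = "builtin"`.
#' @param ... Unused.
#' @return A `cohort_dataset`: `patches` `(bands, P, P, n)` reflectance
#'   array, `metadata` (with `mask_provenance` column), `axis`,
#'   `exclusions`, and (phantom input) `informative_bands`.
#' @export
build_dataset <- function(x, ...) UseMethod("build_dataset")

.assemble_dataset <- function(items, axis, patch_size, informative_bands) {
  kept <- Filter(function(it) is.null(it$reason), items)
  excl <- Filter(function(it) !is.null(it$reason), items)
  if (!length(kept)) stop("no samples survived preprocessing", call. = FALSE)
  nb <- dim(kept[[1]]$patch)[1]
  patches <- array(0, dim = c(nb, patch_size, patch_size, length(kept)))
  for (i in seq_along(kept)) patches[, , , i] <- kept[[i]]$patch
  metadata <- do.call(rbind, lapply(kept, `[[`, "meta"))
  rownames(metadata) <- NULL
  exclusions <- if (length(excl)) {
    do.call(rbind, lapply(excl, function(it) {
      data.frame(sample_id = it$sample_id, reason = it$reason,
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  new_cohort_dataset(patches, metadata, axis, exclusions, informative_bands)
}

.process_one <- function(raw, white, dark, mask, meta, patch_size,
                         masks, min_contrast) {
  refl <- radiometric_normalize(raw, white, dark)
  provenance <- switch(masks,
    builtin = "builtin-segmenter",
    truth = "ground-truth",
    external = "external-file"
  )
  if (masks == "builtin") {
    mask <- segment_lesion(refl, min_contrast = min_contrast)
    if (is.null(mask)) {
      return(list(sample_id = meta$sample_id,
                  reason = "lesion not found (no visible hematoma)"))
    }
  } else if (is.null(mask) || !any(mask > 0)) {
    return(list(sample_id = meta$sample_id, reason = "empty supplied mask"))
  }
  ctr <- mask_center(mask)
  patch <- extract_patch(refl, ctr, patch_size)
  meta$mask_provenance <- provenance
  list(patch = patch, meta = meta)
}

#' @rdname build_dataset
#' @export
build_dataset.phantom_cohort <- function(x, patch_size = NULL,
                                         masks = c("truth", "builtin"),
                                         min_contrast = 0.025, ...) {
  masks <- match.arg(masks)
  sz <- x$params$image_size
  if (is.null(patch_size)) patch_size <- min(64L, sz[1], sz[2])
  items <- lapply(seq_along(x$samples), function(i) {
    s <- x$samples[[i]]
    .process_one(s$radiance, s$white, s$dark, s$mask,
                 x$metadata[i, c("sample_id", "subject_id", "age_days", "stage")],
                 patch_size, masks, min_contrast)
  })
  .assemble_dataset(items, x$axis, patch_size, x$informative_bands)
}

#' @rdname build_dataset
#' @export
build_dataset.character <- function(x, patch_size = 64L,
                                    masks = c("builtin", "external", "truth"),
                                    min_contrast = 0.025, ...) {
  masks <- match.arg(masks)
  md <- utils::read.csv(x, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "age_days", "stage",
            "path_cube", "path_white", "path_dark")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop(sprintf("metadata is missing column(s): %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  axis <- NULL
  items <- lapply(seq_len(nrow(md)), function(i) {
    row <- md[i, ]
    for (p in c(row$path_cube, row$path_white, row$path_dark)) {
      if (!file.exists(p)) {
        stop(sprintf("metadata row %d ('%s'): missing file '%s'",
                     i, row$sample_id, p), call. = FALSE)
      }
    }
    cube <- read_envi(row$path_cube)
    if (is.null(axis) && !is.null(cube$wavelengths)) {
      axis <<- structure(
        list(centers = cube$wavelengths,
             range_min = min(cube$wavelengths),
             range_max = max(cube$wavelengths)),
        class = "wavelength_axis"
      )
    }
    white <- read_envi(row$path_white)$values
    dark <- read_envi(row$path_dark)$values
    mask <- NULL
    if (masks %in% c("external", "truth")) {
      if (is.null(row$path_mask) || !file.exists(row$path_mask)) {
        stop(sprintf("metadata row %d ('%s'): missing mask file", i, row$sample_id), call. = FALSE)
      }
      m <- read_envi(row$path_mask)$values
      mask <- (m[1, , ] > 0) * 1L
    }
    .process_one(cube$values, white, dark, mask,
                 row[, c("sample_id", "subject_id", "age_days", "stage")],
                 patch_size, masks, min_contrast)
  })
  .assemble_dataset(items, axis, patch_size, integer())
}

#' Spatially averaged spectral signature of each sample
#'
#' Averages all pixel spectra of each patch, yielding one feature vector of
#' per-band mean reflectance per sample -- the input representation of the
#' Lasso baseline, which by construction discards all spatial information.
#'
#' @param x A `cohort_dataset`, or a single patch array `(bands, P, P)`.
#' @return For a dataset, a numeric matrix `n_samples x n_bands`; for a
#'   single patch, a numeric vector of length `n_bands`.
#' @export
spatial_average <- function(x) {
  if (inherits(x, "cohort_dataset")) {
    d <- dim(x$patches)
    m <- matrix(x$patches, nrow = d[1])          # bands x (P*P*n)
    px <- d[2] * d[3]
    out <- t(sapply(seq_len(d[4]), function(i) {
      rowMeans(m[, ((i - 1) * px + 1):(i * px), drop = FALSE])
    }))
    dimnames(out) <- list(x$metadata$sample_id, NULL)
    out
  } else {
    stopifnot(is.array(x), length(dim(x)) == 3)
    rowMeans(matrix(x, nrow = dim(x)[1]))
  }
}

#' Write a patch dataset container to disk
#'
#' Serializes the dataset as a single self-describing RDS container with
#' named datasets (`patches`, `age_days`, `subject_id`, `stage`,
#' `wavelengths`) plus an `exclusions.csv` alongside it.
#'
#' @param dataset A `cohort_dataset`.
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
write_patch_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  saveRDS(list(
    patches = dataset$patches,
    age_days = dataset$metadata$age_days,
    subject_id = dataset$metadata$subject_id,
    sample_id = dataset$metadata$sample_id,
    stage = dataset$metadata$stage,
    mask_provenance = dataset$metadata$mask_provenance,
    wavelengths = dataset$axis$centers,
    informative_bands = dataset$informative_bands
  ), path)
  utils::write.csv(dataset$exclusions,
                   file.path(dirname(path), "exclusions.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read a patch dataset container written by [write_patch_dataset()]
#' @param path Path of the `.rds` container.
#' @return A `cohort_dataset`.
#' @export
read_patch_dataset <- function(path) {
  x <- readRDS(path)
  axis <- structure(
    list(centers = x$wavelengths, range_min = min(x$wavelengths),
         range_max = max(x$wavelengths)),
    class = "wavelength_axis"
  )
  md <- data.frame(
    sample_id = x$sample_id, subject_id = x$subject_id,
    age_days = x$age_days, stage = x$stage,
    mask_provenance = x$mask_provenance, stringsAsFactors = FALSE
  )
  new_cohort_dataset(x$patches, md, axis,
                     informative_bands = x$informative_bands)
}
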