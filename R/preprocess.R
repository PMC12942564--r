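# Radiometric normalization, lesion localization and patch extraction.
#
# Coordinate convention used throughout: 1-based (row, col) indices, closed
# windows [start, start + size - 1], matching R array indexing.

#' Radiometric normalization of a radiance cube to relative reflectance
#'
#' Converts raw radiance to relative reflectance with white and dark
#' reference measurements:
#' `reflectance = (raw - dark) / (white - dark)`, element-wise.  Values are
#' retained at full floating precision and are deliberately NOT clipped to
#' `[0, 1]`: noise can push reflectance slightly outside the unit interval
#' and later stages expect the unquantized values.
#'
#' @param raw Radiance array `(bands, rows, cols)`.
#' @param white,dark Reference measurements: either full cubes with the
#'   same shape as `raw` or per-band spectra (length `bands`, broadcast
#'   over pixels) -- in-scene white tiles and shared references are both
#'   common in practice.
#' @return Reflectance array with the shape of `raw`.
#' @examples
#' raw <- array(0.55, dim = c(2, 2, 2))
#' radiometric_normalize(raw, white = c(1, 1), dark = c(0.1, 0.1))  # 0.5
#' @export
radiometric_normalize <- function(raw, white, dark) {
  stopifnot(is.array(raw), length(dim(raw)) == 3)
  d <- dim(raw)
  expand <- function(x, nm) {
    if (is.array(x) && length(dim(x)) == 3) {
      if (!all(dim(x) == d)) stop(sprintf("`%s` cube shape does not match `raw`", nm), call. = FALSE)
      x
    } else if (is.numeric(x) && is.null(dim(x))) {
      if (length(x) != d[1]) stop(sprintf("`%s` spectrum must have one value per band", nm), call. = FALSE)
      array(x, dim = d)   # band index is fastest-varying: clean broadcast
    } else stop(sprintf("`%s` must be a cube or a per-band spectrum", nm), call. = FALSE)
  }
  w <- expand(white, "white")
  k <- expand(dark, "dark")
  denom <- w - k
  bad <- which(denom == 0)
  if (length(bad)) {
    idx <- arrayInd(bad[1], d)
    stop(sprintf(
      "degenerate reference: white == dark at band %d, pixel (%d, %d) (%d element(s) total)",
      idx[1], idx[2], idx[3], length(bad)
    ), call. = FALSE)
  }
  (raw - k) / denom
}

#' Spectral angle between two spectra
#'
#' The angle (radians) between two spectra treated as vectors: an
#' illumination-robust dissimilarity, 0 for proportional spectra.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Angle in radians, in `[0, pi]`.
#' @export
spectral_angle <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  acos(min(1, max(-1, sum(a * b) / (na * nb))))
}

# per-pixel spectral angle of a cube against a reference spectrum
.angle_map <- function(cube, ref) {
  d <- dim(cube)
  m <- matrix(cube, nrow = d[1])              # bands x pixels
  ref_n <- ref / sqrt(sum(ref^2))
  norms <- sqrt(colSums(m^2))
  norms[norms == 0] <- 1
  cosang <- colSums(m * ref_n) / norms
  matrix(acos(pmin(1, pmax(-1, cosang))), d[2], d[3])
}

#' Locate the hematoma with the built-in spectral-contrast segmenter
#'
#' A deterministic stand-in for interactive foundation-model segmentation:
#' every pixel is scored by its spectral angle to a reference "healthy skin"
#' spectrum (the median spectrum of the prompt-box border, or of the image
#' border when no box is given), the score map is thresholded by Otsu's
#' method, and the largest connected component inside the prompt box is
#' returned.  Precomputed external masks can be used instead via
#' [build_dataset()].
#'
#' @param cube Reflectance array `(bands, rows, cols)`.
#' @param prompt_box Optional rectangle `c(row_min, row_max, col_min,
#'   col_max)` (1-based, inclusive) restricting the search.
#' @param min_contrast Minimum peak spectral-angle contrast (radians) for a
#'   lesion to count as visible; below it the sample is treated as having no
#'   visible hematoma.
#' @return A binary `rows x cols` matrix with attribute
#'   `provenance = "builtin-segmenter"`, or `NULL` -- the explicit
#'   lesion-not-found signal (the caller should exclude the sample).
#' @export
segment_lesion <- function(cube, prompt_box = NULL, min_contrast = 0.025) {
  stopifnot(is.array(cube), length(dim(cube)) == 3)
  d <- dim(cube)
  rows <- d[2]; cols <- d[3]
  if (is.null(prompt_box)) {
    box <- c(1L, rows, 1L, cols)
  } else {
    box <- as.integer(prompt_box)
    stopifnot(length(box) == 4, box[1] >= 1, box[2] <= rows,
              box[3] >= 1, box[4] <= cols, box[1] <= box[2], box[3] <= box[4])
  }
  # reference spectrum: median over the box border (assumed healthy skin)
  br <- box[1]:box[2]; bc <- box[3]:box[4]
  border_idx <- rbind(
    cbind(box[1], bc), cbind(box[2], bc),
    cbind(br, box[3]), cbind(br, box[4])
  )
  border_idx <- unique(border_idx)
  border_spectra <- apply(border_idx, 1, function(p) cube[, p[1], p[2]])
  ref <- apply(border_spectra, 1, stats::median)
  score <- .angle_map(cube, ref)
  # search restricted to the prompt box
  inside <- matrix(FALSE, rows, cols)
  inside[br, bc] <- TRUE
  score[!inside] <- 0
  peak <- max(score)
  if (!is.finite(peak) || peak < min_contrast) return(NULL)
  th <- EBImage::otsu(EBImage::Image(score / peak), range = c(0, 1))
  bw <- (score / peak > th) & inside
  if (!any(bw)) return(NULL)
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  lab <- EBImage::imageData(lab)
  counts <- table(lab[lab > 0])
  keep <- as.integer(names(counts)[which.max(counts)])
  mask <- (lab == keep) * 1L
  attr(mask, "provenance") <- "builtin-segmenter"
  mask
}

#' Integer centroid of a lesion mask
#'
#' @param mask Binary `rows x cols` matrix with at least one positive pixel.
#' @return Integer `(row, col)` centroid of the positive pixels, each
#'   coordinate rounded half up.
#' @export
mask_center <- function(mask) {
  pos <- which(mask > 0, arr.ind = TRUE)
  if (nrow(pos) == 0) stop("empty mask: no positive pixels", call. = FALSE)
  floor(colMeans(pos) + 0.5)
}

#' Extract a fixed-size spectral-spatial patch
#'
#' Cuts a `size x size` window nominally centered at `center`, retaining
#' all bands.  Windows that would overrun the image are shifted (clamped)
#' inside it, so the output always has exactly `size x size` real pixels
#' and is never padded.
#'
#' @param cube Array `(bands, rows, cols)`.
#' @param center Integer `(row, col)` nominal patch center (1-based).
#' @param size Patch side length in pixels (default 64); must not exceed
#'   either spatial extent.
#' @return Array `(bands, size, size)` with attribute `center` (the
#'   realized window center after clamping is recoverable from `origin`).
#' @export
extract_patch <- function(cube, center, size = 64L) {
  stopifnot(is.array(cube), length(dim(cube)) == 3)
  d <- dim(cube)
  size <- as.integer(size)
  if (size > min(d[2], d[3])) {
    stop(sprintf("patch size %d exceeds image extent %dx%d", size, d[2], d[3]), call. = FALSE)
  }
  start_r <- min(max(center[1] - size %/% 2L, 1L), d[2] - size + 1L)
  start_c <- min(max(center[2] - size %/% 2L, 1L), d[3] - size + 1L)
  patch <- cube[, start_r:(start_r + size - 1L), start_c:(start_c + size - 1L), drop = FALSE]
  attr(patch, "origin") <- c(start_r, start_c)
  patch
}
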