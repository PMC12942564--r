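#' Construct an evenly spaced wavelength axis
#'
#' The Specim IQ-style acquisition geometry assumed throughout the package
#' samples reflectance at evenly spaced band centers.  The default axis has
#' 204 bands spanning 400--1000 nm, the visible to near-infrared window in
#' which hematoma chromophores (hemoglobin species, bilirubin, melanin)
#' absorb.
#'
#' @param n_bands Number of spectral bands (>= 2).
#' @param range_min,range_max Wavelength range endpoints in nanometres.
#' @return An object of class `wavelength_axis`: a list with `centers`
#'   (length `n_bands`, strictly increasing, endpoints at the range limits),
#'   `range_min` and `range_max`.
#' @examples
#' ax <- make_wavelength_axis()
#' ax$centers[c(1, 204)]   # 400, 1000
#' @export
make_wavelength_axis <- function(n_bands = 204L, range_min = 400, range_max = 1000) {
  if (length(n_bands) != 1L || is.na(n_bands) || n_bands < 2 || n_bands != round(n_bands)) {
    stop("`n_bands` must be a single integer >= 2", call. = FALSE)
  }
  if (!(range_min < range_max)) {
    stop("`range_min` must be strictly less than `range_max`", call. = FALSE)
  }
  n_bands <- as.integer(n_bands)
  centers <- range_min + (seq_len(n_bands) - 1) * (range_max - range_min) / (n_bands - 1)
  structure(
    list(centers = centers, range_min = range_min, range_max = range_max),
    class = "wavelength_axis"
  )
}

#' @export
print.wavelength_axis <- function(x, ...) {
  cat(sprintf(
    "<wavelength_axis> %d bands, %.1f-%.1f nm (spacing %.2f nm)\n",
    length(x$centers), x$range_min, x$range_max,
    diff(x$centers[1:2])
  ))
  invisible(x)
}

#' @export
length.wavelength_axis <- function(x) length(x$centers)

#' Subset a wavelength axis by band indices
#'
#' Used when restricting a dataset to a band subset; the result keeps the
#' selected centers (not necessarily evenly spaced) and updates the range.
#'
#' @param axis A `wavelength_axis`.
#' @param indices 1-based band indices, strictly increasing.
#' @return A `wavelength_axis` over the selected centers.
#' @export
subset_axis <- function(axis, indices) {
  stopifnot(inherits(axis, "wavelength_axis"))
  if (any(indices < 1 | indices > length(axis$centers))) {
    stop("band indices out of range", call. = FALSE)
  }
  centers <- axis$centers[indices]
  structure(
    list(centers = centers, range_min = min(centers), range_max = max(centers)),
    class = "wavelength_axis"
  )
}

#' Find the band whose center is nearest a target wavelength
#'
#' Maps a nominal wavelength (e.g. the 460/540/650 nm Bayer-filter peaks of
#' an RGB sensor) onto the acquisition grid.  Ties are broken toward the
#' lower band index.
#'
#' @param axis A `wavelength_axis`.
#' @param target Target wavelength in nm.  Must lie within the axis range
#'   extended by one band spacing on each side.
#' @return 1-based band index.
#' @export
nearest_band <- function(axis, target) {
  stopifnot(inherits(axis, "wavelength_axis"))
  if (length(target) != 1L || !is.finite(target)) {
    stop("`target` must be a single finite wavelength", call. = FALSE)
  }
  spacing <- if (length(axis$centers) > 1L) diff(axis$centers[1:2]) else 0
  if (target < axis$range_min - spacing || target > axis$range_max + spacing) {
    stop(sprintf(
      "target %.1f nm lies outside axis range [%.1f, %.1f] nm (+/- one spacing)",
      target, axis$range_min, axis$range_max
    ), call. = FALSE)
  }
  d <- abs(axis$centers - target)
  # which.min returns the first (lowest-index) minimizer: the tie rule
  which.min(d)
}
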