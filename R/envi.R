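# Minimal ENVI cube I/O: a text header (`<path>.hdr`) plus a flat binary
# file (`<path>`).  Supports BSQ/BIL/BIP interleaves, data types 1 (uint8),
# 4 (float32), 5 (float64) and 12 (uint16), little-endian, and a wavelength
# list in the header.  Cubes are represented in R as arrays with dimensions
# (bands, rows, cols); ENVI "lines" = rows and "samples" = cols.

.envi_type <- function(data_type) {
  switch(as.character(data_type),
    "1"  = list(what = "integer", size = 1L, signed = FALSE),
    "4"  = list(what = "numeric", size = 4L, signed = TRUE),
    "5"  = list(what = "numeric", size = 8L, signed = TRUE),
    "12" = list(what = "integer", size = 2L, signed = FALSE),
    stop(sprintf("unsupported ENVI data type %s", data_type), call. = FALSE)
  )
}

#' Write a hyperspectral cube in ENVI format
#'
#' @param cube Array `(bands, rows, cols)`.
#' @param path Output binary path; the header is written to `<path>.hdr`.
#' @param wavelengths Optional numeric vector of band-center wavelengths
#'   (nm) stored in the header.
#' @param interleave One of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI data type code: 1 (uint8), 4 (float32, default),
#'   5 (float64) or 12 (uint16).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, wavelengths = NULL,
                       interleave = c("bil", "bsq", "bip"), data_type = 4L) {
  interleave <- match.arg(interleave)
  stopifnot(is.array(cube), length(dim(cube)) == 3)
  d <- dim(cube)  # bands, rows, cols
  tp <- .envi_type(data_type)
  # reorder to the on-disk element order (fastest index first)
  perm <- switch(interleave,
    bsq = c(3, 2, 1),  # samples, lines, bands
    bil = c(3, 1, 2),  # samples, bands, lines
    bip = c(1, 3, 2)   # bands, samples, lines
  )
  vals <- as.vector(aperm(cube, perm))
  if (tp$what == "integer") vals <- as.integer(round(vals))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(vals, con, size = tp$size, endian = "little")
  hdr <- c(
    "ENVI",
    "description = {hematochron phantom cube}",
    sprintf("samples = %d", d[3]),
    sprintf("lines = %d", d[2]),
    sprintf("bands = %d", d[1]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0"
  )
  if (!is.null(wavelengths)) {
    hdr <- c(hdr, "wavelength units = nm", sprintf(
      "wavelength = {%s}",
      paste(formatC(wavelengths, format = "f", digits = 4), collapse = ", ")
    ))
  }
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

# parse an ENVI header into a named list; {}-delimited values may span lines
.parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  out <- list()
  # join multi-line brace blocks, then split on newlines outside braces
  pos <- 1L
  n <- nchar(txt)
  fields <- character()
  buf <- ""
  depth <- 0L
  for (ch in strsplit(txt, "", fixed = TRUE)[[1]]) {
    if (ch == "{") depth <- depth + 1L
    if (ch == "}") depth <- depth - 1L
    if (ch == "\n" && depth == 0L) {
      fields <- c(fields, buf); buf <- ""
    } else buf <- paste0(buf, ch)
  }
  if (nzchar(buf)) fields <- c(fields, buf)
  for (f in fields) {
    if (!grepl("=", f, fixed = TRUE)) next
    key <- trimws(tolower(sub("=.*$", "", f)))
    val <- trimws(sub("^[^=]*=", "", f))
    out[[key]] <- val
  }
  out
}

#' Read an ENVI cube
#'
#' @param path Path to the binary file (header at `<path>.hdr`) or directly
#'   to a `.hdr` file.
#' @return A list with `values` (array `(bands, rows, cols)`) and
#'   `wavelengths` (numeric or `NULL`).
#' @export
read_envi <- function(path) {
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  bin_path <- sub("\\.hdr$", "", path)
  if (!file.exists(hdr_path)) stop(sprintf("missing ENVI header '%s'", hdr_path), call. = FALSE)
  if (!file.exists(bin_path)) stop(sprintf("missing ENVI data file '%s'", bin_path), call. = FALSE)
  h <- .parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop(sprintf("ENVI header missing field(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  samples <- as.integer(h[["samples"]]); lines_n <- as.integer(h[["lines"]])
  bands <- as.integer(h[["bands"]])
  interleave <- tolower(h[["interleave"]])
  tp <- .envi_type(h[["data type"]])
  offset <- if (!is.null(h[["header offset"]])) as.integer(h[["header offset"]]) else 0L
  n_vals <- samples * lines_n * bands
  con <- file(bin_path, "rb")
  on.exit(close(con), add = TRUE)
  if (offset > 0) readBin(con, "raw", n = offset)
  vals <- readBin(con, tp$what, n = n_vals, size = tp$size,
                  signed = tp$signed, endian = "little")
  if (length(vals) != n_vals) {
    stop(sprintf("ENVI data file '%s' truncated (%d of %d values)",
                 bin_path, length(vals), n_vals), call. = FALSE)
  }
  dims <- switch(interleave,
    bsq = c(samples, lines_n, bands),
    bil = c(samples, bands, lines_n),
    bip = c(bands, samples, lines_n),
    stop(sprintf("unsupported interleave '%s'", interleave), call. = FALSE)
  )
  arr <- array(as.numeric(vals), dim = dims)
  cube <- switch(interleave,
    bsq = aperm(arr, c(3, 2, 1)),
    bil = aperm(arr, c(2, 3, 1)),
    bip = aperm(arr, c(1, 3, 2))
  )
  wl <- NULL
  if (!is.null(h[["wavelength"]])) {
    wl <- as.numeric(strsplit(gsub("[{}]", "", h[["wavelength"]]), ",")[[1]])
  }
  list(values = cube, wavelengths = wl)
}

#' Write a phantom cohort to disk as ENVI cubes plus a metadata table
#'
#' Each sample's radiance, white and dark cubes are written as float32 ENVI
#' files and its ground-truth mask as a single-band 8-bit ENVI image
#' (0 = background, 1 = lesion).  The metadata CSV has columns `sample_id`,
#' `subject_id`, `age_days`, `stage`, `path_cube`, `path_white`,
#' `path_dark`, `path_mask`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param interleave ENVI interleave for the cubes.
#' @return Path of the metadata CSV, invisibly.
#' @export
write_phantom_cohort <- function(cohort, dir, interleave = "bil") {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md <- cohort$metadata
  wl <- cohort$axis$centers
  paths <- lapply(seq_len(nrow(md)), function(i) {
    s <- cohort$samples[[i]]
    base <- file.path(dir, md$sample_id[i])
    write_envi(s$radiance, paste0(base, "_cube.raw"), wl, interleave)
    write_envi(s$white, paste0(base, "_white.raw"), wl, interleave)
    write_envi(s$dark, paste0(base, "_dark.raw"), wl, interleave)
    mask_cube <- array(s$mask, dim = c(1, nrow(s$mask), ncol(s$mask)))
    write_envi(mask_cube, paste0(base, "_mask.raw"), NULL, "bsq", data_type = 1L)
    data.frame(
      path_cube = paste0(base, "_cube.raw"),
      path_white = paste0(base, "_white.raw"),
      path_dark = paste0(base, "_dark.raw"),
      path_mask = paste0(base, "_mask.raw"),
      stringsAsFactors = FALSE
    )
  })
  out <- cbind(md[, c("sample_id", "subject_id", "age_days", "stage")],
               do.call(rbind, paths))
  csv <- file.path(dir, "metadata.csv")
  utils::write.csv(out, csv, row.names = FALSE)
  invisible(csv)
}
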