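# Hyperspectral cube I/O, reflectance calibration (white/dark correction),
# region-of-interest extraction and replicate averaging.

#' Hyperspectral cube of raw intensity counts
#'
#' @param data 3-D numeric array, rows x cols x bands.
#' @param wavelengths strictly increasing band-centre wavelengths (nm).
#' @param meta free-form list of acquisition annotations.
#' @return object of class `hsi_cube`.
#' @export
hsi_cube <- function(data, wavelengths, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("dimension error: cube data must be a rows x cols x bands array",
         call. = FALSE)
  }
  wavelengths <- as.numeric(wavelengths)
  if (dim(data)[3L] != length(wavelengths)) {
    stop("dimension error: band count must equal wavelength count",
         call. = FALSE)
  }
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(dim(data)[1:2] < 1L)) stop("cube must have >= 1 row and column",
                                     call. = FALSE)
  structure(list(data = data, wavelengths = wavelengths, meta = meta),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

# ENVI data type codes supported (code -> list(what, size)).
envi_types <- list(
  `2`  = list(what = "integer", size = 2L),
  `4`  = list(what = "double",  size = 4L),
  `5`  = list(what = "double",  size = 8L),
  `12` = list(what = "integer", size = 2L, unsigned = TRUE)
)

parse_envi_header <- function(hdr_path) {
  txt <- readLines(hdr_path, warn = FALSE)
  joined <- paste(txt, collapse = "\n")
  get_field <- function(name, required = TRUE) {
    pat <- paste0("(?mi)^\\s*", name, "\\s*=\\s*")
    m <- regexpr(pat, joined, perl = TRUE)
    if (m == -1L) {
      if (required) stop("format error: missing ENVI header field '", name,
                         "'", call. = FALSE)
      return(NULL)
    }
    rest <- substring(joined, m + attr(m, "match.length"))
    if (substring(rest, 1L, 1L) == "{") {
      end <- regexpr("}", rest, fixed = TRUE)
      if (end == -1L) stop("format error: unterminated '{' in ENVI field '",
                           name, "'", call. = FALSE)
      val <- substring(rest, 2L, end - 1L)
    } else {
      val <- sub("\n.*$", "", rest)
    }
    trimws(val)
  }
  samples <- as.integer(get_field("samples"))
  lines <- as.integer(get_field("lines"))
  bands <- as.integer(get_field("bands"))
  dtype <- get_field("data type")
  interleave <- tolower(get_field("interleave"))
  byte_order <- get_field("byte order", required = FALSE)
  wl_raw <- get_field("wavelength")
  wl <- as.numeric(strsplit(wl_raw, ",")[[1L]])
  if (anyNA(wl)) stop("format error: non-numeric entry in ENVI field ",
                      "'wavelength'", call. = FALSE)
  if (anyNA(c(samples, lines, bands))) {
    stop("format error: non-integer ENVI dimension field", call. = FALSE)
  }
  if (length(wl) != bands) {
    stop("dimension error: ENVI 'wavelength' count (", length(wl),
         ") does not match 'bands' (", bands, ")", call. = FALSE)
  }
  if (!interleave %in% c("bsq", "bil", "bip")) {
    stop("format error: unsupported ENVI field 'interleave' = ", interleave,
         call. = FALSE)
  }
  if (is.null(envi_types[[dtype]])) {
    stop("format error: unsupported ENVI field 'data type' = ", dtype,
         call. = FALSE)
  }
  list(samples = samples, lines = lines, bands = bands, dtype = dtype,
       interleave = interleave,
       endian = if (!is.null(byte_order) && byte_order == "1") "big"
                else "little",
       wavelengths = wl)
}

#' Read a hyperspectral cube
#'
#' Two dialects are supported: `"envi"` (a binary cube beside a `.hdr`
#' header; BSQ, BIL and BIP interleaves, wavelengths taken from the
#' `wavelength` header field) and `"flat_table"` (a plain-text format used
#' for small fixtures: a header line `rows cols bands`, a line of
#' wavelengths, then one line per band-major value).
#'
#' @param path for `"envi"`, the path of either the header or the binary
#'   file; for `"flat_table"`, the text file path.
#' @param dialect `"envi"` or `"flat_table"`.
#' @return an [hsi_cube()].
#' @export
read_cube <- function(path, dialect = c("envi", "flat_table")) {
  dialect <- match.arg(dialect)
  if (dialect == "flat_table") return(read_cube_flat(path))
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  bin_path <- sub("\\.hdr$", "", path)
  if (!file.exists(hdr_path)) stop("file not found: ", hdr_path,
                                   call. = FALSE)
  if (!file.exists(bin_path)) stop("file not found: ", bin_path,
                                   call. = FALSE)
  h <- parse_envi_header(hdr_path)
  ty <- envi_types[[h$dtype]]
  n <- h$samples * h$lines * h$bands
  expected_bytes <- n * ty$size
  if (file.size(bin_path) < expected_bytes) {
    stop("format error: binary file smaller than header dimensions imply",
         call. = FALSE)
  }
  con <- file(bin_path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = ty$what, n = n, size = ty$size,
               signed = !isTRUE(ty$unsigned), endian = h$endian)
  v <- as.double(v)
  # file order fastest-to-slowest: bsq col,row,band; bil col,band,row;
  # bip band,col,row
  a <- switch(h$interleave,
    bsq = aperm(array(v, dim = c(h$samples, h$lines, h$bands)), c(2, 1, 3)),
    bil = aperm(array(v, dim = c(h$samples, h$bands, h$lines)), c(3, 1, 2)),
    bip = aperm(array(v, dim = c(h$bands, h$samples, h$lines)), c(3, 2, 1)))
  hsi_cube(a, h$wavelengths, meta = list(interleave = h$interleave,
                                         source = bin_path))
}

read_cube_flat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  dims <- as.integer(strsplit(trimws(txt[1L]), "\\s+")[[1L]])
  if (length(dims) != 3L || anyNA(dims)) {
    stop("format error: flat_table first line must be 'rows cols bands'",
         call. = FALSE)
  }
  wl <- as.numeric(strsplit(trimws(txt[2L]), "\\s+")[[1L]])
  if (length(wl) != dims[3L] || anyNA(wl)) {
    stop("dimension error: wavelength line does not match band count",
         call. = FALSE)
  }
  v <- as.numeric(txt[-(1:2)])
  if (length(v) != prod(dims)) {
    stop("format error: flat_table value count does not match dimensions",
         call. = FALSE)
  }
  # values stored row-fastest within band (band-major blocks)
  a <- aperm(array(v, dim = c(dims[1L], dims[2L], dims[3L])), c(1, 2, 3))
  hsi_cube(a, wl)
}

#' Write a hyperspectral cube
#'
#' Companion of [read_cube()]. The ENVI dialect writes 64-bit floats so the
#' read-back is bit-identical; flat tables use 17 significant digits.
#'
#' @param cube an [hsi_cube()].
#' @param path output path (for ENVI, the binary path; `.hdr` is added).
#' @param dialect `"envi"` or `"flat_table"`.
#' @param interleave ENVI interleave to write: `"bsq"`, `"bil"` or `"bip"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, dialect = c("envi", "flat_table"),
                       interleave = c("bsq", "bil", "bip")) {
  dialect <- match.arg(dialect)
  d <- dim(cube$data)
  if (dialect == "flat_table") {
    out <- c(paste(d, collapse = " "),
             paste(sprintf("%.17g", cube$wavelengths), collapse = " "),
             sprintf("%.17g", as.vector(cube$data)))
    writeLines(out, path)
    return(invisible(path))
  }
  interleave <- match.arg(interleave)
  a <- switch(interleave,
    bsq = aperm(cube$data, c(2, 1, 3)),
    bil = aperm(cube$data, c(2, 3, 1)),
    bip = aperm(cube$data, c(3, 2, 1)))
  con <- file(path, "wb")
  writeBin(as.vector(a), con, size = 8L, endian = "little")
  close(con)
  hdr <- c("ENVI",
           paste0("samples = ", d[2L]),
           paste0("lines = ", d[1L]),
           paste0("bands = ", d[3L]),
           "data type = 5",
           paste0("interleave = ", interleave),
           "byte order = 0",
           paste0("wavelength = {",
                  paste(sprintf("%.17g", cube$wavelengths), collapse = ", "),
                  "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Convert raw counts to calibrated reflectance
#'
#' Applies the white/dark reference correction
#' `R = (raw - dark) / (white - dark) * 100` per pixel and band. Pixels where
#' `white - dark <= 0` are flagged invalid and set to `NaN`; reflectance is
#' deliberately not clamped to \[0, 100\] (scatter correction downstream is
#' affine-invariant).
#'
#' @param cube an [hsi_cube()] of raw counts.
#' @param frames a list with elements `white` and `dark`: matrices
#'   (rows x cols, shared across bands) or 3-D arrays matching the cube.
#'   When both a 2-D and 3-D frame could apply, the array form wins.
#' @return object of class `reflectance_cube` with fields `data` (percent),
#'   `wavelengths` and `invalid_mask` (same shape as `data`).
#' @export
calibrate_reflectance <- function(cube, frames) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$data)
  expand <- function(f, name) {
    if (is.null(dim(f))) {
      if (length(f) != 1L) stop("dimension error: ", name,
                                " frame must be scalar, matrix or array",
                                call. = FALSE)
      return(array(as.numeric(f), dim = d))
    }
    if (length(dim(f)) == 2L) {
      if (!all(dim(f) == d[1:2])) {
        stop("dimension error: ", name, " frame spatial shape mismatch",
             call. = FALSE)
      }
      return(array(rep(as.numeric(f), d[3L]), dim = d))
    }
    if (length(dim(f)) == 3L) {
      if (!all(dim(f) == d)) stop("dimension error: ", name,
                                  " frame shape mismatch", call. = FALSE)
      return(f)
    }
    stop("dimension error: ", name, " frame must be 2-D or 3-D",
         call. = FALSE)
  }
  white <- expand(frames$white, "white")
  dark <- expand(frames$dark, "dark")
  denom <- white - dark
  invalid <- denom <= 0
  if (all(invalid)) {
    stop("calibration error: white - dark <= 0 everywhere", call. = FALSE)
  }
  refl <- (cube$data - dark) / denom * 100
  refl[invalid] <- NaN
  structure(list(data = refl, wavelengths = cube$wavelengths,
                 invalid_mask = invalid),
            class = "reflectance_cube")
}

# Binary erosion with a square structuring element of the given pixel
# radius; plain shift-and intersection, adequate for ROI-sized masks.
erode_mask <- function(mask, radius) {
  if (radius == 0L) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  padded <- matrix(FALSE, nr + 2L * radius, nc + 2L * radius)
  padded[radius + seq_len(nr), radius + seq_len(nc)] <- mask
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      out <- out & padded[radius + dr + seq_len(nr),
                          radius + dc + seq_len(nc)]
    }
  }
  out
}

#' Build a region-of-interest mask by edge erosion
#'
#' The sample ROI is the foreground interior after excluding a margin band
#' along the edge (edge pixels are specular and uneven). The margin in
#' millimetres is converted to pixels with the supplied resolution and the
#' foreground is morphologically eroded by that many pixels (square
#' structuring element).
#'
#' @param foreground logical matrix, TRUE on sample pixels.
#' @param margin_mm non-negative margin to strip from the edge, in mm
#'   (default 2, the centre-area convention).
#' @param px_per_mm spatial resolution in pixels per mm (instrument specific,
#'   required).
#' @return object of class `roi_mask` with fields `mask` and `margin_px`.
#' @export
build_roi_mask <- function(foreground, margin_mm = 2, px_per_mm = 1) {
  if (!is.matrix(foreground) || !is.logical(foreground)) {
    stop("`foreground` must be a logical matrix", call. = FALSE)
  }
  if (!any(foreground)) stop("ROI error: empty foreground", call. = FALSE)
  if (margin_mm < 0 || px_per_mm <= 0) {
    stop("parameter error: margin_mm >= 0 and px_per_mm > 0 required",
         call. = FALSE)
  }
  margin_px <- as.integer(round(margin_mm * px_per_mm))
  mask <- erode_mask(foreground, margin_px)
  if (!any(mask)) {
    stop("ROI error: erosion by ", margin_px,
         " px emptied the mask; use a smaller margin", call. = FALSE)
  }
  structure(list(mask = mask, margin_px = margin_px), class = "roi_mask")
}

#' Mean spectrum over a region of interest
#'
#' Per-band arithmetic mean of all valid ROI pixels; pixels flagged invalid
#' by [calibrate_reflectance()] are excluded.
#'
#' @param cube a `reflectance_cube`.
#' @param roi an [build_roi_mask()] result or a logical matrix.
#' @return numeric vector of reflectance (percent), one entry per band.
#' @export
roi_mean_spectrum <- function(cube, roi) {
  stopifnot(inherits(cube, "reflectance_cube"))
  mask <- if (inherits(roi, "roi_mask")) roi$mask else roi
  d <- dim(cube$data)
  if (!is.matrix(mask) || !all(dim(mask) == d[1:2])) {
    stop("dimension error: ROI shape must match cube spatial dims",
         call. = FALSE)
  }
  if (!any(mask)) stop("ROI error: empty ROI", call. = FALSE)
  idx <- which(mask)
  flat <- matrix(cube$data, nrow = d[1L] * d[2L], ncol = d[3L])
  inv <- matrix(cube$invalid_mask, nrow = d[1L] * d[2L], ncol = d[3L])
  sub <- flat[idx, , drop = FALSE]
  sub_inv <- inv[idx, , drop = FALSE]
  valid_n <- colSums(!sub_inv)
  if (any(valid_n == 0L)) {
    stop("ROI error: ROI entirely invalid in at least one band",
         call. = FALSE)
  }
  sub[sub_inv] <- 0
  colSums(sub) / valid_n
}

#' Average replicate scans
#'
#' Elementwise mean of repeated per-scan spectra of the same sample
#' (replicate averaging is done after ROI extraction: a mean of means).
#'
#' @param spectra list of numeric vectors of equal length (one per scan).
#' @return numeric vector.
#' @export
average_replicates <- function(spectra) {
  if (!is.list(spectra) || length(spectra) < 1L) {
    stop("parameter error: need >= 1 replicate spectra", call. = FALSE)
  }
  len <- lengths(spectra)
  if (length(unique(len)) != 1L) {
    stop("dimension error: replicate spectra lengths differ", call. = FALSE)
  }
  Reduce(`+`, lapply(spectra, as.numeric)) / length(spectra)
}
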