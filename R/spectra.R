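#' Spectra container for one physical form
#'
#' A `spectra_set` is the currency of the pipeline: a samples x wavelengths
#' reflectance matrix (percent) together with its wavelength axis (nm),
#' unique sample identifiers and the physical form of the specimens
#' ("crushed" or "full").
#'
#' @param X numeric matrix, samples in rows, wavelengths in columns
#'   (reflectance, percent).
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, one per column of `X`.
#' @param sample_ids character vector of unique sample labels, one per row.
#'   Defaults to `rownames(X)`.
#' @param form physical form of the samples: `"crushed"` or `"full"`.
#' @return an object of class `spectra_set` with fields `X`, `wavelengths`,
#'   `sample_ids`, `form`.
#' @examples
#' s <- spectra_set(matrix(rnorm(6), 2, 3), c(900, 1000, 1100),
#'                  c("a", "b"), "crushed")
#' @export
spectra_set <- function(X, wavelengths, sample_ids = rownames(X),
                        form = c("crushed", "full")) {
  form <- match.arg(form)
  X <- as_numeric_matrix(X)
  wavelengths <- as.numeric(wavelengths)
  if (ncol(X) != length(wavelengths)) {
    stop("dimension error: column count must equal wavelength count",
         call. = FALSE)
  }
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(X)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(X)) {
    stop("dimension error: row count must equal sample_id count",
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("format error: duplicate sample_id", call. = FALSE)
  }
  dimnames(X) <- list(sample_ids, format_wavelength(wavelengths))
  structure(list(X = X, wavelengths = wavelengths, sample_ids = sample_ids,
                 form = form),
            class = "spectra_set")
}

format_wavelength <- function(w) sprintf("%.17g", w)

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d bands (%.1f-%.1f nm), form=%s\n",
              nrow(x$X), ncol(x$X), min(x$wavelengths), max(x$wavelengths),
              x$form))
  invisible(x)
}

#' @export
`[.spectra_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$X))
  if (missing(j)) j <- seq_along(x$wavelengths)
  if (is.character(i)) i <- match(i, x$sample_ids)
  spectra_set(x$X[i, j, drop = FALSE], x$wavelengths[j],
              x$sample_ids[i], x$form)
}

#' Spectra aligned with reference values
#'
#' Pairs a [spectra_set()] with reference log10 CFU/g values and an optional
#' calibration/prediction partition.
#'
#' @param spectra a [spectra_set()].
#' @param y numeric vector of reference values (log10 CFU/g), aligned with
#'   the rows of `spectra`, or a named vector matched by sample id.
#' @param calibration_ids,prediction_ids optional disjoint id vectors
#'   partitioning the samples.
#' @return an object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(spectra, y, calibration_ids = NULL,
                             prediction_ids = NULL) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (!is.null(names(y))) {
    if (!all(spectra$sample_ids %in% names(y))) {
      stop("alignment error: y names do not cover all sample ids",
           call. = FALSE)
    }
    y <- y[spectra$sample_ids]
  }
  y <- as.numeric(y)
  if (length(y) != nrow(spectra$X)) {
    stop("dimension error: y length must equal sample count", call. = FALSE)
  }
  if (!is.null(calibration_ids) || !is.null(prediction_ids)) {
    ids <- spectra$sample_ids
    if (!all(c(calibration_ids, prediction_ids) %in% ids)) {
      stop("alignment error: partition ids not in sample ids", call. = FALSE)
    }
    if (length(intersect(calibration_ids, prediction_ids))) {
      stop("partition sets must be disjoint", call. = FALSE)
    }
  }
  structure(list(spectra = spectra, y = stats::setNames(y, spectra$sample_ids),
                 calibration_ids = calibration_ids,
                 prediction_ids = prediction_ids),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset> %d samples, form=%s, y in [%.3f, %.3f] log10 CFU/g\n",
    nrow(x$spectra$X), x$spectra$form, min(x$y), max(x$y)))
  if (!is.null(x$calibration_ids)) {
    cat(sprintf("  partition: %d calibration / %d prediction\n",
                length(x$calibration_ids), length(x$prediction_ids)))
  }
  invisible(x)
}

# Subset helpers returning matrices/vectors for a named partition.
dataset_part <- function(ds, which = c("calibration", "prediction")) {
  which <- match.arg(which)
  ids <- if (which == "calibration") ds$calibration_ids else ds$prediction_ids
  if (is.null(ids)) stop("dataset has no ", which, " partition", call. = FALSE)
  idx <- match(ids, ds$spectra$sample_ids)
  list(X = ds$spectra$X[idx, , drop = FALSE], y = unname(ds$y[idx]), ids = ids)
}

#' Read a delimited spectra table
#'
#' The expected layout is: first column `sample_id`, remaining column headers
#' numeric wavelengths in nm, cells reflectance in percent. Comma and tab
#' separated files are auto-detected from the extension (`.tsv`/`.txt` read
#' as tab). Columns whose wavelengths are out of order are re-sorted
#' ascending with a message.
#'
#' @param path file path.
#' @param form physical form recorded on the returned set.
#' @return a [spectra_set()].
#' @export
read_spectra_table <- function(path, form = c("crushed", "full")) {
  form <- match.arg(form)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("format error: need sample_id plus spectra columns",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("format error: duplicate sample_id",
                               call. = FALSE)
  wl <- suppressWarnings(as.numeric(colnames(df)[-1L]))
  if (anyNA(wl)) {
    bad <- colnames(df)[-1L][is.na(wl)]
    stop("format error: non-numeric wavelength header: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(X) <- "double"
  if (is.unsorted(wl, strictly = TRUE)) {
    ord <- order(wl)
    message("read_spectra_table: wavelength columns re-sorted ascending")
    wl <- wl[ord]
    X <- X[, ord, drop = FALSE]
  }
  spectra_set(X, wl, ids, form)
}

#' Write a spectra table
#'
#' Inverse of [read_spectra_table()]; `write` then `read` is the identity up
#' to floating-point text formatting (17 significant digits are written).
#'
#' @param s a [spectra_set()].
#' @param path output path; `.tsv`/`.txt` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  header <- paste(c("sample_id", format_wavelength(s$wavelengths)),
                  collapse = sep)
  rows <- vapply(seq_len(nrow(s$X)), function(i) {
    paste(c(s$sample_ids[i], sprintf("%.17g", s$X[i, ])), collapse = sep)
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}
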