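# Multiplicative scatter correction (MSC).
#
# Each spectrum is regressed on a standard (mean) spectrum,
# x_i = a_i * ref + b_i + e_i, and corrected by inverting the fitted affine
# map: x_i' = (x_i - b_i) / a_i. The reference is frozen at fit time so new
# (prediction or transfer) spectra are corrected against the calibration
# mean rather than their own mean, preventing information leakage.

#' Fit a multiplicative scatter correction model
#'
#' The standard spectrum is the column mean of `spectra`; each sample is then
#' regressed on it by ordinary least squares, yielding one (slope, intercept)
#' pair per sample.
#'
#' @param spectra a [spectra_set()] or numeric matrix (samples x bands).
#' @return object of class `msc_model` with fields `reference`, `slopes`,
#'   `intercepts`.
#' @export
msc_fit <- function(spectra) {
  X <- as_numeric_matrix(spectra, "spectra")
  if (nrow(X) < 2L) stop("parameter error: MSC needs >= 2 samples",
                         call. = FALSE)
  reference <- colMeans(X)
  if (stats::var(reference) < .Machine$double.eps) {
    stop("degenerate-fit error: constant reference spectrum", call. = FALSE)
  }
  co <- msc_coefs(X, reference)
  structure(list(reference = reference, slopes = co$slope,
                 intercepts = co$intercept),
            class = "msc_model")
}

# Row-wise OLS of each spectrum on the reference (closed form).
msc_coefs <- function(X, reference) {
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  slope <- as.vector(X %*% rc) / denom  # rc has zero mean, so no centering of X needed
  intercept <- rowMeans(X) - slope * mean(reference)
  list(slope = slope, intercept = intercept)
}

#' @export
print.msc_model <- function(x, ...) {
  cat(sprintf("<msc_model> %d bands, fitted on %d samples\n",
              length(x$reference), length(x$slopes)))
  invisible(x)
}

#' Apply multiplicative scatter correction
#'
#' Regresses each incoming spectrum on the model's stored reference and
#' inverts the fitted affine map. Works for the spectra the model was fitted
#' on and, identically, for new spectra (fresh regressions against the same
#' frozen reference).
#'
#' @param model an [msc_fit()] result.
#' @param spectra a [spectra_set()] or matrix with the model's band count.
#' @return corrected spectra of the same type as the input.
#' @export
msc_apply <- function(model, spectra) {
  stopifnot(inherits(model, "msc_model"))
  X <- as_numeric_matrix(spectra, "spectra")
  if (ncol(X) != length(model$reference)) {
    stop("dimension error: band count does not match MSC reference",
         call. = FALSE)
  }
  co <- msc_coefs(X, model$reference)
  if (any(abs(co$slope) < 1e-12)) {
    stop("degenerate-sample error: |slope| below tolerance", call. = FALSE)
  }
  corrected <- (X - co$intercept) / co$slope
  if (inherits(spectra, "spectra_set")) {
    spectra_set(corrected, spectra$wavelengths, spectra$sample_ids,
                spectra$form)
  } else {
    corrected
  }
}
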