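# Model performance metrics: RMSE (calibration / cross-validation /
# prediction flavours), coefficient of determination, RPD and RER, plus the
# between-model improvement report.

#' Root mean square error
#'
#' @param y measured values.
#' @param yhat predicted values, same length.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) == 0L || length(y) != length(yhat)) {
    stop("parameter error: y and yhat must be equal nonzero lengths",
         call. = FALSE)
  }
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' `1 - SSres/SStot` against the mean of `y`.
#'
#' @inheritParams rmse
#' @return scalar R squared.
#' @export
r2 <- function(y, yhat) {
  if (length(y) < 2L || length(y) != length(yhat)) {
    stop("parameter error: need >= 2 paired values", call. = FALSE)
  }
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) stop("undefined-R2 error: constant y", call. = FALSE)
  1 - sum((y - yhat)^2) / sstot
}

#' Ratio of performance to deviation
#'
#' Standard deviation (n-1 denominator) of the evaluation-set reference
#' values divided by RMSEP. Values above 2.5 are conventionally read as a
#' reliable model; the returned value carries a `reliable` attribute with
#' that flag.
#'
#' @param y_ref evaluation-set reference values (>= 2).
#' @param rmsep root mean square error of prediction (> 0; 0 yields +Inf
#'   with a warning).
#' @return scalar RPD with attribute `reliable` (`RPD > 2.5`).
#' @export
rpd <- function(y_ref, rmsep) {
  if (length(y_ref) < 2L) stop("parameter error: need >= 2 reference values",
                               call. = FALSE)
  if (rmsep < 0) stop("parameter error: rmsep must be >= 0", call. = FALSE)
  if (rmsep == 0) {
    warning("rmsep is zero; RPD reported as +Inf")
    return(structure(Inf, reliable = TRUE))
  }
  val <- stats::sd(y_ref) / rmsep
  structure(val, reliable = val > 2.5)
}

#' Range error ratio
#'
#' Range (max - min) of the evaluation-set reference values divided by
#' RMSEP. Conventional utility bands: below 3 little practical utility,
#' 3-10 good utility, above 10 high efficiency; the returned value carries
#' a `utility` attribute with that label.
#'
#' @inheritParams rpd
#' @return scalar RER with attribute `utility`.
#' @export
rer <- function(y_ref, rmsep) {
  if (length(y_ref) < 1L) stop("parameter error: empty reference values",
                               call. = FALSE)
  if (rmsep < 0) stop("parameter error: rmsep must be >= 0", call. = FALSE)
  if (rmsep == 0) {
    warning("rmsep is zero; RER reported as +Inf")
    return(structure(Inf, utility = "high efficiency"))
  }
  val <- (max(y_ref) - min(y_ref)) / rmsep
  utility <- if (val < 3) "little utility" else if (val <= 10) "good utility"
             else "high efficiency"
  structure(val, utility = utility)
}

#' Assemble a full metrics report
#'
#' Computes the R2/RMSE pairs for the calibration, cross-validation and
#' prediction stages plus RPD and RER. SD, Max and Min are taken from the
#' prediction (evaluation) set reference values, read literally from the
#' metric definitions.
#'
#' @param y_cal,yhat_cal calibration-set measured and fitted values.
#' @param y_pred,yhat_pred prediction-set measured and predicted values.
#' @param y_cv,yhat_cv optional pooled out-of-fold cross-validation pairs.
#' @return object of class `metrics_report` (a list with fields `Rc2`,
#'   `Rcv2`, `Rp2`, `RMSEC`, `RMSECV`, `RMSEP`, `SD`, `Max`, `Min`, `RPD`,
#'   `RER`; cross-validation fields are `NA` when not supplied).
#' @export
metrics_report <- function(y_cal, yhat_cal, y_pred, yhat_pred,
                           y_cv = NULL, yhat_cv = NULL) {
  rep <- list(
    Rc2 = r2(y_cal, yhat_cal),
    RMSEC = rmse(y_cal, yhat_cal),
    Rcv2 = if (is.null(y_cv)) NA_real_ else r2(y_cv, yhat_cv),
    RMSECV = if (is.null(y_cv)) NA_real_ else rmse(y_cv, yhat_cv),
    Rp2 = r2(y_pred, yhat_pred),
    RMSEP = rmse(y_pred, yhat_pred),
    SD = stats::sd(y_pred),
    Max = max(y_pred),
    Min = min(y_pred))
  rep$RPD <- as.numeric(rpd(y_pred, rep$RMSEP))
  rep$RER <- as.numeric(rer(y_pred, rep$RMSEP))
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  Rc2 %.4f  RMSEC %.4f\n", x$Rc2, x$RMSEC))
  if (!is.na(x$Rcv2)) cat(sprintf("  Rcv2 %.4f  RMSECV %.4f\n",
                                  x$Rcv2, x$RMSECV))
  cat(sprintf("  Rp2 %.4f  RMSEP %.4f  RPD %.2f  RER %.2f\n",
              x$Rp2, x$RMSEP, x$RPD, x$RER))
  invisible(x)
}

#' Percent-change comparison between two models
#'
#' For error metrics (RMSEC, RMSECV, RMSEP) the percent change is
#' `100 * (a - b) / a`, so a positive value means model `b` improved on
#' model `a`. For gain metrics (R2 variants, RPD, RER) it is
#' `100 * (b - a) / a`, with the same sign convention. Raw signed deltas
#' (`b - a`) are also returned.
#'
#' @param a,b `metrics_report` objects or plain named lists holding any
#'   subset of the metric fields.
#' @return data.frame with columns `metric`, `a`, `b`, `delta`,
#'   `pct_change` (positive = improvement) and `kind`.
#' @export
compare_models <- function(a, b) {
  err <- c("RMSEC", "RMSECV", "RMSEP")
  gain <- c("Rc2", "Rcv2", "Rp2", "RPD", "RER")
  fields <- intersect(c(err, gain), intersect(names(a), names(b)))
  if (length(fields) == 0L) stop("parameter error: no shared metric fields",
                                 call. = FALSE)
  rows <- lapply(fields, function(f) {
    av <- as.numeric(a[[f]]); bv <- as.numeric(b[[f]])
    if (is.na(av) || is.na(bv)) return(NULL)
    is_err <- f %in% err
    pct <- if (av == 0) NA_real_
           else if (is_err) 100 * (av - bv) / av else 100 * (bv - av) / av
    data.frame(metric = f, a = av, b = bv, delta = bv - av,
               pct_change = pct, kind = if (is_err) "error" else "gain",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "undefined_change") <- anyNA(out$pct_change)
  out
}
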