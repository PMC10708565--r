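# Direct standardization (DS) calibration transfer.
#
# Paired standard spectra measured on the master (whose model is kept) and
# the slave (whose spectra must be transformed) are column-centered, and the
# band-to-band transformation matrix F is the least-norm solution of
# Sms = Sss %*% F, obtained from a truncated-SVD pseudoinverse of the
# centered slave standards. The rank-one residual term (one offset per
# wavelength) is handled exactly by centering: unknown slave spectra are
# centered with the slave standard mean, multiplied by F, and shifted by the
# master standard mean.

#' Estimate a direct standardization transfer model
#'
#' @param master standard spectra measured on the master form/instrument
#'   (m x n matrix, rows aligned by sample with `slave`).
#' @param slave matching standard spectra measured on the slave.
#' @param svd_tol relative singular-value cutoff: singular values below
#'   `svd_tol * max(singular value)` are truncated (default 1e-6).
#' @param standard_ids optional sample ids, kept for provenance.
#' @return object of class `transfer_model` with fields `F` (n x n), `rank`,
#'   `svd_tol`, `Sss_pinv`, `master_mean`, `slave_mean`, `standard_ids`.
#' @export
compute_transfer <- function(master, slave, svd_tol = 1e-6,
                             standard_ids = rownames(slave)) {
  master <- as_numeric_matrix(master, "master")
  slave <- as_numeric_matrix(slave, "slave")
  if (!all(dim(master) == dim(slave))) {
    stop("dimension error: master and slave standards must match in shape",
         call. = FALSE)
  }
  m <- nrow(slave)
  if (m < 2L) stop("parameter error: need >= 2 standard samples",
                   call. = FALSE)
  if (!all(is.finite(master)) || !all(is.finite(slave))) {
    stop("data error: non-finite standard spectra", call. = FALSE)
  }
  master_mean <- colMeans(master)
  slave_mean <- colMeans(slave)
  Sms <- sweep(master, 2L, master_mean)
  Sss <- sweep(slave, 2L, slave_mean)
  sv <- svd(Sss)
  keep <- sv$d > svd_tol * sv$d[1L]
  rank <- sum(keep)
  if (rank == 0L || sv$d[1L] == 0) {
    stop("degeneracy error: centered slave standards have rank 0 ",
         "(all standards identical)", call. = FALSE)
  }
  pinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  F_mat <- pinv %*% Sms
  structure(list(F = F_mat, rank = rank, svd_tol = svd_tol,
                 Sss_pinv = pinv,
                 master_mean = master_mean, slave_mean = slave_mean,
                 standard_ids = standard_ids),
            class = "transfer_model")
}

#' @export
print.transfer_model <- function(x, ...) {
  cat(sprintf("<transfer_model> %d bands, rank %d (svd_tol %g), %d standards\n",
              ncol(x$F), x$rank, x$svd_tol,
              if (is.null(x$standard_ids)) NA_integer_
              else length(x$standard_ids)))
  invisible(x)
}

#' Transfer slave spectra into the master space
#'
#' `X_t = (X_un - slave_mean) %*% F + master_mean`. The centering/offset
#' convention makes the per-wavelength residual term of the DS model exact:
#' the slave standard mean always maps exactly onto the master standard
#' mean.
#'
#' @param model a [compute_transfer()] result.
#' @param X_un unknown slave spectra (matrix or [spectra_set()]).
#' @return transferred spectra, same type and shape as `X_un`.
#' @export
apply_transfer <- function(model, X_un) {
  stopifnot(inherits(model, "transfer_model"))
  X <- as_numeric_matrix(X_un, "X_un")
  if (ncol(X) != ncol(model$F)) {
    stop("dimension error: band count does not match transfer model",
         call. = FALSE)
  }
  Xt <- sweep(X, 2L, model$slave_mean) %*% model$F
  Xt <- sweep(Xt, 2L, model$master_mean, `+`)
  if (inherits(X_un, "spectra_set")) {
    spectra_set(Xt, X_un$wavelengths, X_un$sample_ids, X_un$form)
  } else {
    dimnames(Xt) <- dimnames(X)
    Xt
  }
}

#' Optimize the standard sample number by minimum RMSEP
#'
#' For each candidate count `n`: select standard samples (KS or SPXY on the
#' form named by `scheme`), estimate the DS transfer, transfer the slave
#' form's prediction spectra into the master space, predict them with the
#' master-form model, and record the RMSEP. The optimal count is the RMSEP
#' minimizer.
#'
#' @param cs,fs [spectral_dataset()] objects (crushed and full form) sharing
#'   ids and carrying a calibration/prediction partition. The crushed form
#'   is the master: its calibration model is kept and full-form spectra are
#'   transferred into its space.
#' @param scheme,method see [select_standards()].
#' @param candidate_ns candidate standard sample counts.
#' @param model a fitted master model (any object with a `predict` method
#'   taking a spectra matrix), or `NULL` to train an epsilon-SVR on the
#'   crushed calibration set with `model_config`.
#' @param model_config [svr_config()] used when `model` is `NULL`.
#' @param svd_tol passed to [compute_transfer()].
#' @param seed RNG seed for model training.
#' @return object of class `ssn_curve` with fields `candidate_ns`, `rmsep`,
#'   `best_n`, `scheme`, `method`.
#' @export
optimize_ssn <- function(cs, fs,
                         scheme = c("crushed_as_standard",
                                    "full_as_standard"),
                         method = c("spxy", "ks"),
                         candidate_ns = seq(5, 80, by = 5),
                         model = NULL, model_config = svr_config(),
                         svd_tol = 1e-6, seed = 1L) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  cal <- dataset_part(cs, "calibration")
  n_cal <- length(cal$ids)
  candidate_ns <- as.integer(candidate_ns)
  if (any(candidate_ns < 2L) || any(candidate_ns > n_cal)) {
    stop("parameter error: candidate_ns must lie in [2, |calibration|]",
         call. = FALSE)
  }
  if (is.null(model)) {
    model <- train_svr(cal$X, cal$y, config = model_config, seed = seed)
  }
  fs_pred <- dataset_part(fs, "prediction")
  rmsep <- vapply(candidate_ns, function(n) {
    sel <- select_standards(cs, fs, scheme = scheme, method = method, n = n)
    pair <- pair_standard_sets(sel, cs, fs, master = "crushed")
    tm <- tryCatch(
      compute_transfer(pair$master, pair$slave, svd_tol = svd_tol,
                       standard_ids = pair$ids),
      error = function(e) stop("optimize_ssn failed at n = ", n, ": ",
                               conditionMessage(e), call. = FALSE))
    Xt <- apply_transfer(tm, fs_pred$X)
    rmse(fs_pred$y, predict(model, Xt))
  }, numeric(1L))
  structure(list(candidate_ns = candidate_ns, rmsep = rmsep,
                 best_n = candidate_ns[which.min(rmsep)],
                 scheme = scheme, method = method),
            class = "ssn_curve")
}

#' @export
print.ssn_curve <- function(x, ...) {
  cat(sprintf("<ssn_curve> %s/%s: best n = %d (RMSEP %.4f)\n",
              x$method, x$scheme, x$best_n, min(x$rmsep)))
  invisible(x)
}
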