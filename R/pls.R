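# Minimal SIMPLS partial least squares engine. Used only as the coefficient
# provider inside CARS and for its cross-validated RMSECV; not exposed as a
# headline model.

#' Fit a PLS regression by SIMPLS
#'
#' @param X predictor matrix (samples x variables).
#' @param y numeric response.
#' @param ncomp maximum number of latent components; silently truncated to
#'   the achievable rank.
#' @return object of class `pls_fit` with a `coefficients` matrix
#'   (variables x components, cumulative per component count), matching
#'   `intercepts`, and `ncomp` actually fitted.
#' @keywords internal
#' @export
pls_fit <- function(X, y, ncomp) {
  X <- as_numeric_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("dimension error: y length mismatch",
                           call. = FALSE)
  ncomp <- min(ncomp, n - 1L, p)
  if (ncomp < 1L) stop("parameter error: cannot fit 0 components",
                       call. = FALSE)
  xmeans <- colMeans(X)
  ymean <- mean(y)
  Xc <- sweep(X, 2L, xmeans)
  yc <- y - ymean
  S <- crossprod(Xc, yc)
  R <- matrix(0, p, ncomp); Q <- numeric(ncomp); V <- matrix(0, p, ncomp)
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    r <- S
    t <- Xc %*% r
    normt <- sqrt(sum(t^2))
    if (!is.finite(normt) || normt < 1e-12) break
    t <- t / normt
    r <- r / normt
    p_a <- crossprod(Xc, t)
    q_a <- sum(yc * t)
    v <- p_a
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p_a)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; Q[a] <- q_a; V[, a] <- v
    a_done <- a
  }
  if (a_done == 0L) stop("degenerate-fit error: X has no usable variance",
                         call. = FALSE)
  R <- R[, seq_len(a_done), drop = FALSE]
  Q <- Q[seq_len(a_done)]
  # cumulative regression vectors: B_a = R[,1:a] %*% Q[1:a]
  B <- sapply(seq_len(a_done), function(a)
    R[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)])
  B <- matrix(B, nrow = p)
  intercepts <- ymean - as.vector(xmeans %*% B)
  structure(list(coefficients = B, intercepts = intercepts,
                 ncomp = a_done),
            class = "pls_fit")
}

#' Predict from a SIMPLS fit
#'
#' @param fit a [pls_fit()] object.
#' @param X new predictor matrix.
#' @param ncomp component count to use (default: all fitted).
#' @return numeric vector of predictions.
#' @keywords internal
#' @export
pls_predict <- function(fit, X, ncomp = fit$ncomp) {
  ncomp <- min(ncomp, fit$ncomp)
  as.vector(as_numeric_matrix(X) %*% fit$coefficients[, ncomp] +
              fit$intercepts[ncomp])
}

# k-fold cross-validated RMSECV per component count (pooled out-of-fold
# residuals). Returns the RMSECV vector; attribute "best" holds the argmin.
pls_cv_rmsecv <- function(X, y, max_ncomp, n_folds, seed) {
  n <- nrow(X)
  folds <- cv_folds(n, n_folds, seed)
  max_fit <- min(max_ncomp, ncol(X), n - max(table(folds)) - 1L)
  if (max_fit < 1L) stop("partitioning error: folds too small for PLS",
                         call. = FALSE)
  press <- matrix(NA_real_, n, max_fit)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    fit <- pls_fit(X[tr, , drop = FALSE], y[tr], max_fit)
    for (a in seq_len(fit$ncomp)) {
      press[!tr, a] <- pls_predict(fit, X[!tr, , drop = FALSE], a)
    }
    if (fit$ncomp < max_fit) {
      for (a in seq(fit$ncomp + 1L, max_fit)) {
        press[!tr, a] <- press[!tr, fit$ncomp]
      }
    }
  }
  rmsecv <- sqrt(colMeans((press - y)^2))
  structure(rmsecv, best = which.min(rmsecv))
}
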