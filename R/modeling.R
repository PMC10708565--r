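# Epsilon-SVR regression with seeded cross-validated hyperparameter tuning.
#
# The quadratic program is solved by a compact SMO routine (src/svr_smo.cpp)
# equivalent to the classic libsvm dual; predictors are standardized
# internally (training-set mean/sd) so the RBF gamma grid is scale-free,
# while the response is left on its native log10 CFU/g scale so the epsilon
# tube keeps physical units.

#' Epsilon-SVR configuration
#'
#' Hyperparameters left `NULL` are tuned by seeded k-fold grid search
#' minimizing RMSECV; fixed values switch tuning off for that parameter.
#'
#' @param kernel `"rbf"` or `"linear"`.
#' @param C,gamma,epsilon fixed hyperparameters, or `NULL` to tune.
#' @param C_grid,gamma_grid,epsilon_grid search grids (defaults:
#'   `2^seq(-5, 15, 2)`, `2^seq(-15, 3, 2)`, `c(0.01, 0.05, 0.1)`).
#' @param n_folds folds for the tuning search (default 10).
#' @param tol SMO convergence tolerance (default 1e-3).
#' @param max_iter SMO iteration cap per fit.
#' @param scale standardize predictor columns (default TRUE).
#' @return a list of class `svr_config`.
#' @export
svr_config <- function(kernel = c("rbf", "linear"),
                       C = NULL, gamma = NULL, epsilon = NULL,
                       C_grid = 2^seq(-5, 15, by = 2),
                       gamma_grid = 2^seq(-15, 3, by = 2),
                       epsilon_grid = c(0.01, 0.05, 0.1),
                       n_folds = 10L, tol = 1e-3, max_iter = 200000L,
                       scale = TRUE) {
  kernel <- match.arg(kernel)
  for (nm in c("C", "gamma", "epsilon")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || v <= 0)) {
      stop("parameter error: ", nm, " must be positive", call. = FALSE)
    }
  }
  structure(list(kernel = kernel, C = C, gamma = gamma, epsilon = epsilon,
                 C_grid = C_grid, gamma_grid = gamma_grid,
                 epsilon_grid = epsilon_grid, n_folds = n_folds,
                 tol = tol, max_iter = max_iter, scale = scale),
            class = "svr_config")
}

# Squared Euclidean distances between rows of A and rows of B.
sqdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  d[d < 0] <- 0
  d
}

kernel_matrix <- function(kernel, A, B, gamma, D2 = NULL) {
  if (kernel == "linear") return(tcrossprod(A, B))
  if (is.null(D2)) D2 <- sqdist(A, B)
  exp(-gamma * D2)
}

svr_solve <- function(K, y, C, epsilon, tol, max_iter) {
  sol <- .svr_smo(K, y, C, epsilon, tol, as.integer(max_iter))
  if (!sol$converged) {
    warning("SVR solver hit the iteration cap (", max_iter,
            "); solution may be inexact")
  }
  sol
}

scale_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv)
}

scale_apply <- function(X, sc) sweep(sweep(X, 2L, sc$mu), 2L, sc$sd, `/`)

#' Train an epsilon-SVR model
#'
#' @param X training spectra (matrix or [spectra_set()]); columns may be a
#'   selected-wavelength subset.
#' @param y reference values.
#' @param config an [svr_config()]; any `NULL` hyperparameter triggers a
#'   seeded grid search minimizing k-fold RMSECV.
#' @param seed RNG seed controlling fold assignment (same seed, same model).
#' @param selected_wavelengths optional nm set recorded on the model.
#' @return object of class `svr_model` (supports `predict(model, X)`), with
#'   fields `kernel`, `C`, `gamma`, `epsilon`, `beta`, `b`, support data,
#'   scaling, `tuning` (RMSECV table when tuned), `fit_ids`, `seed`.
#' @export
train_svr <- function(X, y, config = svr_config(), seed = 1L,
                      selected_wavelengths = NULL) {
  fit_ids <- if (inherits(X, "spectra_set")) X$sample_ids else rownames(X)
  X <- as_numeric_matrix(X)
  y <- as.numeric(y)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("data error: non-finite features or response", call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("dimension error: y length mismatch",
                                 call. = FALSE)
  sc <- if (config$scale) scale_fit(X) else list(mu = rep(0, ncol(X)),
                                                 sd = rep(1, ncol(X)))
  Xs <- scale_apply(X, sc)

  need_tuning <- is.null(config$C) || is.null(config$epsilon) ||
    (config$kernel == "rbf" && is.null(config$gamma))
  tuning <- NULL
  if (need_tuning) {
    if (nrow(Xs) < 2L * config$n_folds) {
      stop("parameter error: need >= 2 * n_folds samples to tune",
           call. = FALSE)
    }
    tuning <- svr_grid_search(Xs, y, config, seed)
    config$C <- tuning$best$C
    config$gamma <- tuning$best$gamma
    config$epsilon <- tuning$best$epsilon
  }
  if (config$kernel == "linear") config$gamma <- NA_real_

  K <- kernel_matrix(config$kernel, Xs, Xs, config$gamma)
  sol <- svr_solve(K, y, config$C, config$epsilon, config$tol,
                   config$max_iter)
  structure(list(kernel = config$kernel, C = config$C, gamma = config$gamma,
                 epsilon = config$epsilon, beta = sol$beta, b = sol$b,
                 X_train = Xs, scaling = sc,
                 selected_wavelengths = selected_wavelengths,
                 tuning = tuning$table, fit_ids = fit_ids, seed = seed),
            class = "svr_model")
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf(
    "<svr_model> kernel=%s C=%g gamma=%s epsilon=%g, %d training samples\n",
    x$kernel, x$C, ifelse(is.na(x$gamma), "-", format(x$gamma)), x$epsilon,
    nrow(x$X_train)))
  invisible(x)
}

#' Predict from an epsilon-SVR model
#'
#' @param object an `svr_model`.
#' @param newdata spectra matrix or [spectra_set()] with the training band
#'   count.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  X <- as_numeric_matrix(newdata, "newdata")
  if (ncol(X) != ncol(object$X_train)) {
    stop("dimension error: feature count does not match the trained model",
         call. = FALSE)
  }
  Xs <- scale_apply(X, object$scaling)
  Kx <- kernel_matrix(object$kernel, Xs, object$X_train, object$gamma)
  as.vector(Kx %*% object$beta + object$b)
}

# Grid search over (C, gamma, epsilon) by pooled out-of-fold RMSECV.
# Fold squared-distance blocks are precomputed once so each gamma costs one
# exp() per fold and each (C, epsilon) one SMO solve.
svr_grid_search <- function(Xs, y, config, seed) {
  n <- nrow(Xs)
  folds <- cv_folds(n, config$n_folds, seed)
  gammas <- if (config$kernel == "rbf") {
    if (is.null(config$gamma)) config$gamma_grid else config$gamma
  } else NA_real_
  Cs <- if (is.null(config$C)) config$C_grid else config$C
  epss <- if (is.null(config$epsilon)) config$epsilon_grid else config$epsilon

  blocks <- lapply(seq_len(config$n_folds), function(f) {
    tr <- folds != f
    if (config$kernel == "rbf") {
      list(tr = tr,
           D2tt = sqdist(Xs[tr, , drop = FALSE], Xs[tr, , drop = FALSE]),
           D2pt = sqdist(Xs[!tr, , drop = FALSE], Xs[tr, , drop = FALSE]))
    } else {
      list(tr = tr,
           Ktt = tcrossprod(Xs[tr, , drop = FALSE]),
           Kpt = tcrossprod(Xs[!tr, , drop = FALSE], Xs[tr, , drop = FALSE]))
    }
  })

  grid <- expand.grid(C = Cs, gamma = gammas, epsilon = epss,
                      KEEP.OUT.ATTRS = FALSE)
  rmsecv <- numeric(nrow(grid))
  for (gi in seq_along(gammas)) {
    g <- gammas[gi]
    rows <- which(grid$gamma %in% g | is.na(g))
    preds <- matrix(NA_real_, n, length(rows))
    for (blk in blocks) {
      tr <- blk$tr
      if (config$kernel == "rbf") {
        Ktt <- exp(-g * blk$D2tt); Kpt <- exp(-g * blk$D2pt)
      } else {
        Ktt <- blk$Ktt; Kpt <- blk$Kpt
      }
      for (ri in seq_along(rows)) {
        pars <- grid[rows[ri], ]
        sol <- svr_solve(Ktt, y[tr], pars$C, pars$epsilon, config$tol,
                         config$max_iter)
        preds[!tr, ri] <- as.vector(Kpt %*% sol$beta + sol$b)
      }
    }
    rmsecv[rows] <- sqrt(colMeans((preds - y)^2))
  }
  grid$RMSECV <- rmsecv
  best <- grid[which.min(grid$RMSECV), ]
  list(best = as.list(best), table = grid)
}

#' Seeded k-fold cross-validation of an epsilon-SVR configuration
#'
#' Out-of-fold predictions are pooled before computing the metrics. Fixed
#' hyperparameters in `config` are used as-is; `NULL` ones are tuned once up
#' front on the full set and then held fixed across folds (the standard
#' practice when reporting RMSECV curves).
#'
#' @inheritParams train_svr
#' @param n_folds number of folds (default 10); `n_folds = nrow(X)` gives
#'   leave-one-out.
#' @return list with `Rcv2`, `RMSECV`, `predictions` (pooled out-of-fold)
#'   and `folds`.
#' @export
cross_validate <- function(X, y, config = svr_config(), n_folds = 10L,
                           seed = 1L) {
  X <- as_numeric_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  folds <- cv_folds(n, n_folds, seed)
  if (min(table(folds)) < 1L || n - max(table(folds)) < 2L) {
    stop("partitioning error: fold too small", call. = FALSE)
  }
  if (is.null(config$C) || is.null(config$epsilon) ||
      (config$kernel == "rbf" && is.null(config$gamma))) {
    tuned <- train_svr(X, y, config, seed = seed)
    config$C <- tuned$C; config$gamma <- tuned$gamma
    config$epsilon <- tuned$epsilon
  }
  preds <- rep(NA_real_, n)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    fit <- train_svr(X[tr, , drop = FALSE], y[tr], config,
                     seed = derive_seed(seed, f))
    preds[!tr] <- predict(fit, X[!tr, , drop = FALSE])
  }
  list(Rcv2 = r2(y, preds), RMSECV = rmse(y, preds), predictions = preds,
       folds = folds)
}

#' Fit and evaluate a model with the full metric suite
#'
#' Trains an epsilon-SVR on the calibration pairs, optionally
#' cross-validates it, predicts the evaluation pairs and assembles a
#' [metrics_report()].
#'
#' @param X_cal,y_cal calibration spectra and references.
#' @param X_pred,y_pred evaluation spectra and references.
#' @param config an [svr_config()].
#' @param cv run the k-fold cross-validation stage (default TRUE).
#' @param n_folds folds for the cross-validation stage.
#' @param seed RNG seed.
#' @return list with `model` (the `svr_model`) and `metrics`
#'   (a `metrics_report`).
#' @export
fit_and_evaluate <- function(X_cal, y_cal, X_pred, y_pred,
                             config = svr_config(), cv = TRUE,
                             n_folds = 10L, seed = 1L) {
  model <- train_svr(X_cal, y_cal, config, seed = seed)
  fixed <- svr_config(kernel = model$kernel, C = model$C,
                      gamma = if (model$kernel == "rbf") model$gamma else NULL,
                      epsilon = model$epsilon, tol = config$tol,
                      max_iter = config$max_iter, scale = config$scale)
  cvres <- if (cv) cross_validate(as_numeric_matrix(X_cal), y_cal, fixed,
                                  n_folds = n_folds, seed = seed) else NULL
  metrics <- metrics_report(
    y_cal, predict(model, X_cal), y_pred, predict(model, X_pred),
    y_cv = if (cv) y_cal else NULL,
    yhat_cv = if (cv) cvres$predictions else NULL)
  list(model = model, metrics = metrics)
}
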