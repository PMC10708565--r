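# Hybrid calibration-set augmentation: the crushed-form (base) calibration
# set is extended with a chosen number of full-form spectra -- raw or
# DS-transferred -- to widen the spectral space the model covers.

#' Build a hybrid (augmented) calibration set
#'
#' The base calibration rows are kept and the first `k` rows of the added
#' pool (in SPXY selection order by default, so the most space-filling
#' samples enter first) are appended. Provenance labels are retained.
#'
#' @param base_X,base_y base-form calibration spectra and references.
#' @param added_X,added_y other-form spectra pool (raw or transferred) and
#'   references.
#' @param k number of added rows, `0 <= k <= nrow(added_X)`.
#' @param transferred logical flag recorded on the result: whether
#'   `added_X` was DS-transferred.
#' @param order `"spxy"` (default) ranks the pool by SPXY before taking the
#'   first `k`; `"random"` takes a seeded random subset; `"given"` keeps the
#'   pool's row order.
#' @param seed used when `order = "random"`.
#' @return list with `X`, `y`, `source` (per-row `"base"`/`"added"` labels),
#'   `k_added`, `transferred`.
#' @export
build_hybrid <- function(base_X, base_y, added_X, added_y, k,
                         transferred = FALSE,
                         order = c("spxy", "random", "given"), seed = 1L) {
  order <- match.arg(order)
  base_X <- as_numeric_matrix(base_X, "base_X")
  added_X <- as_numeric_matrix(added_X, "added_X")
  if (ncol(base_X) != ncol(added_X)) {
    stop("dimension error: band grids of base and added spectra differ",
         call. = FALSE)
  }
  if (k < 0 || k > nrow(added_X)) {
    stop("parameter error: k must lie in [0, |added|]", call. = FALSE)
  }
  take <- if (k == 0L) integer(0)
  else switch(order,
    spxy = if (k >= 2L) spxy_select(added_X, added_y, k)
           else spxy_select(added_X, added_y, 2L)[1L],
    random = with_seed(seed, sample.int(nrow(added_X), k)),
    given = seq_len(k))
  take <- take[seq_len(min(k, length(take)))]
  X <- rbind(base_X, added_X[take, , drop = FALSE])
  y <- c(base_y, added_y[take])
  list(X = X, y = y,
       source = c(rep("base", nrow(base_X)), rep("added", length(take))),
       k_added = length(take), transferred = transferred)
}

#' Sweep the hybrid added-sample count
#'
#' One model is retrained per `k` in `k_grid` on the augmented calibration
#' set and evaluated on the held-out set; rows are ordered by `k`. To keep
#' sweeps cheap the hyperparameters are tuned once on the base set (or taken
#' from `config` when fixed) and reused for every `k`; set `retune = TRUE`
#' to re-run the grid search per `k`.
#'
#' @inheritParams build_hybrid
#' @param k_grid added-sample counts (default `seq(5, 80, by = 5)`, the
#'   16-row sweep).
#' @param eval_X,eval_y evaluation spectra and references.
#' @param config an [svr_config()].
#' @param retune re-run the hyperparameter search for every `k`.
#' @param cv compute the cross-validation metrics per row (slower; default
#'   FALSE).
#' @param seed RNG seed.
#' @return object of class `hybrid_sweep` with a `table` data.frame (one row
#'   per `k`: `k_added`, `transferred`, `Rc2`, `RMSEC`, `Rp2`, `RMSEP`,
#'   `RPD`, `RER`), a `metrics` list of full [metrics_report()]s and
#'   `best_k` (RMSEP minimizer).
#' @export
hybrid_sweep <- function(base_X, base_y, added_X, added_y,
                         k_grid = seq(5, 80, by = 5), transferred = FALSE,
                         eval_X, eval_y, config = svr_config(),
                         order = c("spxy", "random", "given"),
                         retune = FALSE, cv = FALSE, seed = 1L) {
  order <- match.arg(order)
  k_grid <- sort(as.integer(k_grid))
  if (any(k_grid < 0) || any(k_grid > nrow(as_numeric_matrix(added_X)))) {
    stop("parameter error: k_grid must lie in [0, |added|]", call. = FALSE)
  }
  if (!retune) {
    base_model <- train_svr(base_X, base_y, config, seed = seed)
    config <- svr_config(
      kernel = base_model$kernel, C = base_model$C,
      gamma = if (base_model$kernel == "rbf") base_model$gamma else NULL,
      epsilon = base_model$epsilon, tol = config$tol,
      max_iter = config$max_iter, scale = config$scale)
  }
  reports <- vector("list", length(k_grid))
  for (i in seq_along(k_grid)) {
    k <- k_grid[i]
    hy <- tryCatch(
      build_hybrid(base_X, base_y, added_X, added_y, k,
                   transferred = transferred, order = order, seed = seed),
      error = function(e) stop("hybrid_sweep failed at k = ", k, ": ",
                               conditionMessage(e), call. = FALSE))
    fe <- fit_and_evaluate(hy$X, hy$y, eval_X, eval_y, config = config,
                           cv = cv, seed = seed)
    reports[[i]] <- fe$metrics
  }
  tab <- data.frame(
    k_added = k_grid, transferred = transferred,
    Rc2 = vapply(reports, `[[`, numeric(1), "Rc2"),
    RMSEC = vapply(reports, `[[`, numeric(1), "RMSEC"),
    Rp2 = vapply(reports, `[[`, numeric(1), "Rp2"),
    RMSEP = vapply(reports, `[[`, numeric(1), "RMSEP"),
    RPD = vapply(reports, `[[`, numeric(1), "RPD"),
    RER = vapply(reports, `[[`, numeric(1), "RER"))
  structure(list(table = tab, metrics = reports,
                 best_k = k_grid[which.min(tab$RMSEP)]),
            class = "hybrid_sweep")
}

#' @export
print.hybrid_sweep <- function(x, ...) {
  cat(sprintf("<hybrid_sweep> %d rows; best k = %d (RMSEP %.4f)\n",
              nrow(x$table), x$best_k, min(x$table$RMSEP)))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
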