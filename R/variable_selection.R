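# Competitive adaptive reweighted sampling (CARS) wavelength screening and
# the union rule for variable sets screened on different physical forms.
#
# CARS shrinks the wavelength set over a fixed number of sampling runs. Each
# run fits a PLS model on a Monte-Carlo subsample of the calibration rows and
# ranks the currently retained variables by absolute regression coefficient.
# An exponentially decreasing function (EDF) dictates how many variables
# survive the run: the top half of the scheduled count is retained by force
# (the enforced EDF cut) and the remainder is filled by a weighted draw
# without replacement with probability proportional to |coefficient| (the
# adaptive reweighted sampling step), so the retained count follows the EDF
# schedule exactly. The subset whose 10-fold cross-validated RMSECV is
# minimal wins.

#' Exponentially decreasing retention schedule
#'
#' Retained-variable counts per CARS iteration:
#' `count_i = round(p * a * exp(-k * i))` with `a = (p/2)^(1/(N-1))` and
#' `k = log(p/2)/(N-1)`, so that `count_1 = p` and `count_N = 2`; values are
#' clipped to at least 2.
#'
#' @param p number of candidate variables (>= 2).
#' @param N number of iterations (>= 2).
#' @return integer vector of length `N`, non-increasing, from `p` to 2.
#' @export
edf_schedule <- function(p, N) {
  stopifnot_scalar_count(p, "p", min = 2L)
  stopifnot_scalar_count(N, "N", min = 2L)
  a <- (p / 2)^(1 / (N - 1))
  k <- log(p / 2) / (N - 1)
  counts <- round(p * a * exp(-k * seq_len(N)))
  pmax(as.integer(counts), 2L)
}

#' Run CARS wavelength screening
#'
#' @param X calibration spectra matrix (samples x variables) or a
#'   [spectra_set()].
#' @param y reference values aligned with the rows of `X`.
#' @param n_iterations number of sampling runs (default 50).
#' @param n_folds folds for the cross-validated RMSECV (default 10).
#' @param mc_ratio fraction of calibration samples drawn per Monte-Carlo
#'   run (default 0.8).
#' @param max_ncomp cap on PLS components; the component count used for each
#'   RMSECV is chosen per iteration by cross-validation up to this cap
#'   (default 10).
#' @param seed RNG seed; identical seeds give identical results.
#' @param wavelengths optional wavelength axis (taken from a `spectra_set`
#'   automatically) so the selection can be reported in nm.
#' @return object of class `cars_result` with fields `n_iterations`,
#'   `retained_sets` (list of integer index sets, one per iteration),
#'   `rmsecv_curve`, `best_iteration`, `selected` (index set at the RMSECV
#'   minimum), `selected_wavelengths` (nm, when a grid was available) and
#'   `seed`.
#' @export
cars_run <- function(X, y, n_iterations = 50L, n_folds = 10L,
                     mc_ratio = 0.8, max_ncomp = 10L, seed = 1L,
                     wavelengths = NULL) {
  if (inherits(X, "spectra_set")) {
    if (is.null(wavelengths)) wavelengths <- X$wavelengths
    X <- X$X
  }
  X <- as_numeric_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("dimension error: y length mismatch",
                           call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("data error: non-finite inputs", call. = FALSE)
  }
  if (n < n_folds || n_folds < 2L) {
    stop("partitioning error: need samples >= n_folds >= 2", call. = FALSE)
  }
  if (mc_ratio <= 0 || mc_ratio > 1) {
    stop("parameter error: mc_ratio in (0, 1]", call. = FALSE)
  }
  schedule <- edf_schedule(p, n_iterations)
  m <- max(2L, round(mc_ratio * n))

  retained <- seq_len(p)
  retained_sets <- vector("list", n_iterations)
  rmsecv_curve <- numeric(n_iterations)
  with_seed(seed, {
    for (i in seq_len(n_iterations)) {
      sub <- sample.int(n, m)
      fit <- pls_fit(X[sub, retained, drop = FALSE], y[sub],
                     min(max_ncomp, length(retained), m - 1L))
      w <- abs(fit$coefficients[, fit$ncomp])
      target <- min(schedule[i], length(retained))
      if (target < length(retained)) {
        ord <- order(-w, seq_along(w))
        n_forced <- ceiling(target / 2)
        forced <- ord[seq_len(n_forced)]
        rest <- setdiff(seq_along(w), forced)
        n_draw <- target - n_forced
        drawn <- if (n_draw > 0L) {
          pr <- w[rest]
          if (sum(pr) <= 0) pr <- rep(1, length(rest))
          rest[sample.int(length(rest), n_draw, prob = pr)]
        } else integer(0)
        retained <- sort(retained[c(forced, drawn)])
      }
      retained_sets[[i]] <- retained
      cv <- pls_cv_rmsecv(X[, retained, drop = FALSE], y,
                          max_ncomp = min(max_ncomp, length(retained)),
                          n_folds = n_folds,
                          seed = sample.int(.Machine$integer.max, 1L))
      rmsecv_curve[i] <- min(cv)
    }
  })
  best <- which.min(rmsecv_curve)
  structure(list(n_iterations = n_iterations,
                 retained_sets = retained_sets,
                 rmsecv_curve = rmsecv_curve,
                 best_iteration = best,
                 selected = retained_sets[[best]],
                 selected_wavelengths =
                   if (!is.null(wavelengths))
                     wavelengths[retained_sets[[best]]] else NULL,
                 schedule = schedule,
                 seed = seed),
            class = "cars_result")
}

#' @export
print.cars_result <- function(x, ...) {
  cat(sprintf(paste0("<cars_result> %d iterations; RMSECV minimum %.4f at ",
                     "run %d with %d variables\n"),
              x$n_iterations, min(x$rmsecv_curve), x$best_iteration,
              length(x$selected)))
  invisible(x)
}

#' Merge characteristic-wavelength sets from two physical forms
#'
#' Wavelength sets screened separately on the two physical forms are pooled
#' into one variable set: the set union, ascending, duplicates dropped.
#'
#' @param set_a,set_b numeric wavelength sets (nm).
#' @return sorted union.
#' @export
merge_variable_sets <- function(set_a, set_b) {
  sort(unique(c(as.numeric(set_a), as.numeric(set_b))))
}

#' Map wavelengths to band indices on a grid
#'
#' Nearest grid point per wavelength; exact ties resolve to the lower index;
#' duplicate hits collapse to one index. Queries farther than one grid step
#' outside the grid range raise an error.
#'
#' @param wavelengths query wavelengths (nm).
#' @param grid strictly increasing wavelength grid (nm).
#' @return sorted integer index set into `grid`.
#' @export
map_wavelengths_to_bands <- function(wavelengths, grid) {
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("parameter error: grid must be strictly increasing", call. = FALSE)
  }
  step <- if (length(grid) > 1L) max(diff(grid)) else Inf
  idx <- vapply(as.numeric(wavelengths), function(w) {
    if (w < grid[1L] - step || w > grid[length(grid)] + step) {
      stop("mapping error: wavelength ", w,
           " outside grid range by more than one grid step", call. = FALSE)
    }
    which.min(abs(grid - w))
  }, integer(1L))
  sort(unique(idx))
}
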