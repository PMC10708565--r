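# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that library calls do not perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Stage seeds are derived from one master seed by fixed offsets so a single
# --seed reproduces a whole pipeline run. Kept below 2^31 - 1.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1000 + offset) %% .Machine$integer.max)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

as_numeric_matrix <- function(x, name = "X") {
  if (inherits(x, "spectra_set")) x <- x$X
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  x
}

# Seeded fold labels, balanced sizes, for k-fold cross-validation.
cv_folds <- function(n, n_folds, seed) {
  stopifnot_scalar_count(n_folds, "n_folds", min = 2L)
  if (n < n_folds) {
    stop("partitioning error: fewer samples than folds", call. = FALSE)
  }
  with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
}
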