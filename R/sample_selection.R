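# Standard-sample and calibration-set selection: Kennard-Stone, SPXY, the
# 4:1 random split and pairing of standard samples across physical forms.
#
# Both KS and SPXY are greedy max-min procedures on a pairwise distance
# matrix; they differ only in the distance. Ties are broken deterministically
# (lowest index; lexicographically smallest seed pair).

# Greedy max-min selection on a precomputed symmetric distance matrix.
# Returns indices in selection order.
maxmin_select <- function(D, n) {
  m <- nrow(D)
  if (n < 2L || n > m) {
    stop("parameter error: n must satisfy 2 <= n <= sample count",
         call. = FALSE)
  }
  # seed pair: argmax distance; first strict maximum scanning i<j in
  # lexicographic order = lexicographically smallest tied pair
  best <- c(1L, 2L); bestd <- -Inf
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
    }
  }
  selected <- best
  candidates <- setdiff(seq_len(m), selected)
  mind <- pmin(D[candidates, best[1L]], D[candidates, best[2L]])
  while (length(selected) < n) {
    pick <- which.max(mind)  # which.max returns the first (lowest-index) tie
    newi <- candidates[pick]
    selected <- c(selected, newi)
    candidates <- candidates[-pick]
    mind <- mind[-pick]
    if (length(candidates)) {
      mind <- pmin(mind, D[candidates, newi])
    }
  }
  selected
}

#' Kennard-Stone sample selection
#'
#' Greedy max-min Euclidean selection: the pair of samples with the largest
#' spectral distance seeds the set; each further step adds the candidate
#' whose minimum distance to the already-selected set is maximal. Ties take
#' the lowest index (lexicographically smallest pair for the seed).
#'
#' @param X sample matrix (samples x variables) or [spectra_set()].
#' @param n number of samples to select (2 <= n <= nrow).
#' @return integer indices in selection order.
#' @export
ks_select <- function(X, n) {
  X <- as_numeric_matrix(X)
  maxmin_select(as.matrix(stats::dist(X)), n)
}

# Normalized joint X-Y distance: dx/max(dx) + dy/max(dy); a degenerate y
# (max dy = 0) contributes 0, reducing SPXY to KS.
spxy_distance <- function(X, y) {
  dx <- as.matrix(stats::dist(X))
  dy <- abs(outer(y, y, `-`))
  mdx <- max(dx); mdy <- max(dy)
  dxn <- if (mdx > 0) dx / mdx else dx
  dyn <- if (mdy > 0) dy / mdy else dy * 0
  dxn + dyn
}

#' SPXY sample selection
#'
#' Kennard-Stone greedy procedure on the joint X-Y distance
#' `d_xy(p,q) = d_x(p,q)/max(d_x) + d_y(p,q)/max(d_y)`, where `d_x` is the
#' Euclidean spectral distance and `d_y = |y_p - y_q|`. When `y` is constant
#' the `d_y` term is defined as 0 and the selection equals [ks_select()].
#'
#' @inheritParams ks_select
#' @param y response values aligned with the rows of `X`.
#' @return integer indices in selection order.
#' @export
spxy_select <- function(X, y, n) {
  X <- as_numeric_matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("dimension error: y length mismatch",
                                 call. = FALSE)
  maxmin_select(spxy_distance(X, y), n)
}

#' Random calibration/prediction split
#'
#' Seeded uniform split of sample ids in a given ratio (default 4:1, i.e.
#' 100 samples give an 80/20 split). Sizes round to the nearest integer with
#' the calibration side at least as large as the prediction side.
#'
#' @param ids sample identifiers.
#' @param ratio two-element vector, calibration : prediction (default 4:1).
#' @param seed RNG seed.
#' @return object of class `split_result` with `calibration_ids`,
#'   `prediction_ids` and `seed`.
#' @export
random_split <- function(ids, ratio = c(4, 1), seed = 1L) {
  ids <- as.character(ids)
  n <- length(ids)
  if (n < 5L) stop("parameter error: need >= 5 samples to split",
                   call. = FALSE)
  if (length(ratio) != 2L || any(ratio <= 0)) {
    stop("parameter error: ratio must be two positive numbers",
         call. = FALSE)
  }
  n_cal <- round(n * ratio[1L] / sum(ratio))
  n_cal <- max(n_cal, n - n_cal)  # calibration >= prediction
  cal <- with_seed(seed, sample(ids, n_cal))
  structure(list(calibration_ids = sort(cal),
                 prediction_ids = sort(setdiff(ids, cal)),
                 seed = seed),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d calibration / %d prediction (seed %d)\n",
              length(x$calibration_ids), length(x$prediction_ids),
              as.integer(x$seed)))
  invisible(x)
}

#' Select standard samples on one physical form
#'
#' Runs KS or SPXY on the calibration rows of the form named by `scheme`
#' ("crushed_as_standard" selects on the crushed spectra) and records the
#' chosen calibration ids.
#'
#' @param cs,fs [spectral_dataset()] objects for the crushed and full form,
#'   sharing sample ids and carrying a calibration partition.
#' @param scheme `"crushed_as_standard"` or `"full_as_standard"`.
#' @param method `"ks"` or `"spxy"`.
#' @param n number of standard samples.
#' @return object of class `standard_set_selection` with fields `scheme`,
#'   `method`, `n`, `ids` (selected calibration ids, selection order) and
#'   `indices` (positions within the calibration id list).
#' @export
select_standards <- function(cs, fs,
                             scheme = c("crushed_as_standard",
                                        "full_as_standard"),
                             method = c("spxy", "ks"), n) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  src <- if (scheme == "crushed_as_standard") cs else fs
  part <- dataset_part(src, "calibration")
  idx <- if (method == "ks") ks_select(part$X, n)
         else spxy_select(part$X, part$y, n)
  structure(list(scheme = scheme, method = method, n = n,
                 ids = part$ids[idx], indices = idx),
            class = "standard_set_selection")
}

#' Pair standard samples across physical forms
#'
#' Whatever form supplied the selection distances, the SAME sample ids must
#' be measured in both forms: the returned matrices are row-aligned by id,
#' slave (the form whose spectra will be transferred) first, master second.
#'
#' @param selection a [select_standards()] result.
#' @param cs,fs [spectral_dataset()] objects sharing sample ids.
#' @param master which form's model is kept (default `"crushed"`); the other
#'   form is the slave.
#' @return list with `slave` and `master` spectra matrices (rows aligned by
#'   id), `ids`, and the forms each matrix came from.
#' @export
pair_standard_sets <- function(selection, cs, fs, master = c("crushed",
                                                             "full")) {
  master <- match.arg(master)
  stopifnot(inherits(selection, "standard_set_selection"))
  ids <- selection$ids
  take <- function(ds, ids) {
    pos <- match(ids, ds$spectra$sample_ids)
    if (anyNA(pos)) stop("alignment error: standard ids missing from the ",
                         ds$spectra$form, " form", call. = FALSE)
    ds$spectra$X[pos, , drop = FALSE]
  }
  master_ds <- if (master == "crushed") cs else fs
  slave_ds <- if (master == "crushed") fs else cs
  list(slave = take(slave_ds, ids), master = take(master_ds, ids),
       ids = ids, slave_form = slave_ds$spectra$form,
       master_form = master_ds$spectra$form)
}
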