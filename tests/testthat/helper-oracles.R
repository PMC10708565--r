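# Independent brute-force oracles, deliberately written with explicit loops
# and no shared code with the package internals.

# Euclidean distance between two rows, by explicit summation.
brute_euclid <- function(a, b) sqrt(sum((a - b)^2))

brute_distance_matrix <- function(X, y = NULL) {
  m <- nrow(X)
  D <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) D[i, j] <- brute_euclid(X[i, ], X[j, ])
  }
  if (is.null(y)) return(D)
  DY <- abs(outer(y, y, `-`))
  mD <- max(D); mY <- max(DY)
  (if (mD > 0) D / mD else D) + (if (mY > 0) DY / mY else DY * 0)
}

# Greedy max-min selection with the documented tie rules, from scratch.
brute_maxmin <- function(D, n) {
  m <- nrow(D)
  bi <- 1L; bj <- 2L; bd <- -Inf
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      if (D[i, j] > bd) { bd <- D[i, j]; bi <- i; bj <- j }
    }
  }
  sel <- c(bi, bj)
  while (length(sel) < n) {
    cand <- setdiff(seq_len(m), sel)
    best <- cand[1L]; bestd <- -Inf
    for (c in cand) {
      dmin <- Inf
      for (s in sel) dmin <- min(dmin, D[c, s])
      if (dmin > bestd) { bestd <- dmin; best <- c }
    }
    sel <- c(sel, best)
  }
  sel
}

brute_ks <- function(X, n) brute_maxmin(brute_distance_matrix(X), n)
brute_spxy <- function(X, y, n) brute_maxmin(brute_distance_matrix(X, y), n)

# Binary erosion by a square structuring element, pixel by pixel.
brute_erode <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ok <- TRUE
      for (di in -r:r) {
        for (dj in -r:r) {
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj]) {
            ok <- FALSE; break
          }
        }
        if (!ok) break
      }
      out[i, j] <- ok
    }
  }
  out
}

# Small reproducible spectra-like matrix.
rand_mat <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# Tiny paired-form fixture with cheap experiment settings for module tests.
small_experiment <- function(seed, ...) {
  transfer_experiment(
    seed = seed,
    fixture_cfg = fixture_config(n_samples = 60L, n_bands = 48L,
                                 seed = seed),
    svr = svr_config(C_grid = 2^seq(-1, 9, by = 2),
                     gamma_grid = 2^seq(-9, -1, by = 2),
                     epsilon_grid = 0.05, n_folds = 5L),
    cars = list(n_iterations = 25L, n_folds = 5L, mc_ratio = 0.8,
                max_ncomp = 8L),
    standards = list(method = "spxy", scheme = "crushed_as_standard",
                     n = 40L),
    k_grid = seq(4, 48, by = 8), cv = FALSE, ...)
}
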