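# Direct standardization: pseudoinverse estimation, application and the
# standard-sample-number curve.

smooth_spectra <- function(m, p, seed) {
  set.seed(seed)
  u <- seq(0, 1, length.out = p)
  t(vapply(seq_len(m), function(i) {
    40 + rnorm(1, 0, 4) + 10 * rnorm(1) * sin(2 * pi * u + runif(1, 0, 6)) +
      5 * rnorm(1) * u
  }, numeric(p)))
}

test_that("self-transfer is the identity on the standards", {
  MS <- smooth_spectra(10, 8, seed = 1)
  tm <- compute_transfer(MS, MS)
  expect_lt(max(abs(apply_transfer(tm, MS) - MS)), 1e-10)
  # the slave mean maps exactly to the master mean
  expect_equal(as.vector(apply_transfer(tm, matrix(tm$slave_mean, 1))),
               unname(tm$master_mean), tolerance = 1e-12)
})

test_that("a constructed linear map is recovered on held-out samples", {
  set.seed(2)
  A <- diag(8) + matrix(rnorm(64, 0, 0.15), 8, 8)
  SS <- smooth_spectra(12, 8, seed = 3) +
    matrix(rnorm(96, 0, 2), 12, 8)  # roughen so the row space is full rank
  MS <- SS %*% A
  tm <- compute_transfer(MS, SS)
  expect_equal(tm$rank, 8)
  # held-out samples from the same affine family: slave mean + row-space
  # combinations of the centered standards
  W <- matrix(rnorm(5 * 12, 0, 0.4), 5, 12)
  X_un <- rep(1, 5) %o% colMeans(SS) + W %*% sweep(SS, 2, colMeans(SS))
  X_master <- rep(1, 5) %o% colMeans(MS) +
    (W %*% sweep(SS, 2, colMeans(SS))) %*% A
  expect_lt(max(abs(apply_transfer(tm, X_un) - X_master)), 1e-6)
})

test_that("rank truncation and residual orthogonality hold for m < n", {
  SS <- smooth_spectra(3, 8, seed = 5)
  MS <- smooth_spectra(3, 8, seed = 6)
  tm <- compute_transfer(MS, SS)
  expect_lte(tm$rank, 2)  # centered 3 rows have rank <= 2
  Sss <- sweep(SS, 2, colMeans(SS))
  Sms <- sweep(MS, 2, colMeans(MS))
  resid <- Sss %*% tm$F - Sms
  sv <- svd(Sss)
  kept <- sv$d > tm$svd_tol * sv$d[1]
  expect_lt(max(abs(crossprod(sv$u[, kept, drop = FALSE], resid))), 1e-8)
})

test_that("svd_tol controls the retained rank monotonically", {
  set.seed(9)
  SS <- smooth_spectra(10, 6, seed = 7)
  # compress one direction so there is a small singular value to cut
  SS[, 6] <- SS[, 1] + 1e-5 * rnorm(10)
  MS <- smooth_spectra(10, 6, seed = 8)
  ranks <- vapply(c(1e-2, 1e-4, 1e-8, 1e-12),
                  function(tol) compute_transfer(MS, SS, svd_tol = tol)$rank,
                  integer(1))
  expect_true(all(diff(ranks) >= 0))
})

test_that("degenerate and mismatched standards raise errors", {
  flat <- matrix(5, 4, 6)
  expect_error(compute_transfer(flat, flat), "degeneracy error")
  MS <- smooth_spectra(4, 6, seed = 1)
  expect_error(compute_transfer(MS, MS[, 1:5]), "dimension error")
  expect_error(compute_transfer(MS[1, , drop = FALSE],
                                MS[1, , drop = FALSE]), ">= 2 standard")
  tm <- compute_transfer(MS, MS)
  expect_error(apply_transfer(tm, MS[, 1:5]), "dimension error")
})

make_split_pair <- function(n, p, seed) {
  pr <- generate_dataset_pair(fixture_config(n_samples = n, n_bands = p,
                                             seed = seed))
  sp <- random_split(pr$cs$spectra$sample_ids, seed = seed + 500)
  mk <- function(ds) spectral_dataset(ds$spectra, ds$y, sp$calibration_ids,
                                      sp$prediction_ids)
  list(cs = mk(pr$cs), fs = mk(pr$fs))
}

fast_cfg <- svr_config(C_grid = 2^seq(-1, 9, by = 2),
                       gamma_grid = 2^seq(-9, -1, by = 2),
                       epsilon_grid = 0.05, n_folds = 5)

test_that("optimize_ssn returns a full finite curve and its minimizer", {
  d <- make_split_pair(60, 24, seed = 11)
  ns <- seq(30, 45, by = 5)
  curve <- optimize_ssn(d$cs, d$fs, candidate_ns = ns,
                        model_config = fast_cfg, seed = 1)
  expect_identical(curve$candidate_ns, as.integer(ns))
  expect_length(curve$rmsep, length(ns))
  expect_true(all(is.finite(curve$rmsep)))
  expect_identical(curve$best_n,
                   curve$candidate_ns[which.min(curve$rmsep)])
  single <- optimize_ssn(d$cs, d$fs, candidate_ns = 40,
                         model_config = fast_cfg, seed = 1)
  expect_identical(single$best_n, 40L)
  expect_error(optimize_ssn(d$cs, d$fs, candidate_ns = c(2, 5000),
                            model_config = fast_cfg), "candidate_ns")
})

test_that("more standards help when estimation error dominates", {
  # constructed monotone scenario: 200 samples whose full form carries
  # percent-scale heterogeneity, so the F estimate keeps improving with m
  # and the largest candidate wins
  for (s in 0:2) {
    pr <- generate_dataset_pair(fixture_config(n_samples = 200,
                                               n_bands = 40, seed = s))
    sp <- random_split(pr$cs$spectra$sample_ids, seed = s + 100)
    mk <- function(ds) spectral_dataset(ds$spectra, ds$y,
                                        sp$calibration_ids,
                                        sp$prediction_ids)
    curve <- optimize_ssn(mk(pr$cs), mk(pr$fs),
                          candidate_ns = c(10, 20, 40, 80, 160),
                          model_config = svr_config(
                            C_grid = 2^seq(-1, 9, 2),
                            gamma_grid = 2^seq(-9, -1, 2),
                            epsilon_grid = 0.05),
                          seed = s)
    expect_identical(curve$best_n, 160L)
  }
})
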