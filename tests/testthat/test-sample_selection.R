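# Kennard-Stone, SPXY, the random split and cross-form standard pairing.

test_that("ks_select reproduces the worked 1-D example", {
  X <- matrix(c(0, 1, 4, 9, 10), ncol = 1)
  expect_identical(ks_select(X, 2), c(1L, 5L))       # the farthest pair
  expect_identical(ks_select(X, 3), c(1L, 5L, 3L))   # then the value 4
  expect_identical(sort(ks_select(X, 5)), 1:5)       # exhaustion
  expect_error(ks_select(X, 1), "parameter error")
  expect_error(ks_select(X, 6), "parameter error")
})

test_that("spxy_select weighs the response distance", {
  X <- matrix(c(0, 1, 4, 9, 10), ncol = 1)
  y <- c(0, 0, 10, 0, 0)
  got <- sort(spxy_select(X, y, 2))
  # brute force over all pairs under the normalized joint distance
  D <- brute_distance_matrix(X, y)
  best <- c(1, 2); bd <- -Inf
  for (i in 1:4) for (j in (i + 1):5) {
    if (D[i, j] > bd) { bd <- D[i, j]; best <- c(i, j) }
  }
  expect_identical(got, as.integer(best))
  expect_identical(sort(spxy_select(X, y, 5)), 1:5)
})

test_that("spxy degrades to ks when y is constant", {
  for (s in 1:5) {
    X <- rand_mat(9, 4, seed = s)
    y <- rep(2.5, 9)
    for (n in c(2, 5, 9)) {
      expect_identical(spxy_select(X, y, n), ks_select(X, n))
    }
  }
})

test_that("greedy selections are nested: first n is a prefix of first n+1", {
  X <- rand_mat(15, 6, seed = 42)
  y <- rnorm(15)
  for (n in 2:14) {
    expect_identical(ks_select(X, n), ks_select(X, n + 1)[1:n])
    expect_identical(spxy_select(X, y, n), spxy_select(X, y, n + 1)[1:n])
  }
})

test_that("ks/spxy match the brute-force oracle on small sets", {
  for (s in 1:10) {
    set.seed(1000 + s)
    m <- sample(4:12, 1)
    X <- matrix(rnorm(m * 3), m, 3)
    y <- rnorm(m)
    for (n in 2:m) {
      expect_identical(ks_select(X, n), as.integer(brute_ks(X, n)))
      expect_identical(spxy_select(X, y, n), as.integer(brute_spxy(X, y, n)))
    }
  }
})

test_that("tie rules are deterministic on duplicate rows", {
  X <- matrix(c(0, 0, 5, 5, 2), ncol = 1)  # duplicate extremes
  expect_identical(ks_select(X, 2), c(1L, 3L))  # lexicographically smallest
  expect_identical(ks_select(X, 3), c(1L, 3L, 5L))
})

test_that("random_split honours the 4:1 ratio and the seed", {
  sp <- random_split(sprintf("s%03d", 1:100), seed = 42)
  expect_length(sp$calibration_ids, 80)
  expect_length(sp$prediction_ids, 20)
  expect_length(intersect(sp$calibration_ids, sp$prediction_ids), 0)
  expect_setequal(c(sp$calibration_ids, sp$prediction_ids),
                  sprintf("s%03d", 1:100))
  sp2 <- random_split(sprintf("s%03d", 1:100), seed = 42)
  expect_identical(sp, sp2)
  expect_false(identical(sp$calibration_ids,
                         random_split(sprintf("s%03d", 1:100),
                                      seed = 43)$calibration_ids))
  expect_length(random_split(letters[1:10], seed = 1)$calibration_ids, 8)
  expect_error(random_split(letters[1:4], seed = 1), "parameter error")
})

test_that("standard sets pair the same ids across forms, row-aligned", {
  p <- generate_dataset_pair(fixture_config(n_samples = 20, n_bands = 16,
                                            seed = 8))
  ids <- p$cs$spectra$sample_ids
  sp <- random_split(ids, seed = 3)
  mk <- function(ds) spectral_dataset(ds$spectra, ds$y, sp$calibration_ids,
                                      sp$prediction_ids)
  cs <- mk(p$cs); fs <- mk(p$fs)
  sel <- select_standards(cs, fs, scheme = "crushed_as_standard",
                          method = "spxy", n = 5)
  expect_length(sel$ids, 5)
  expect_true(all(sel$ids %in% sp$calibration_ids))
  pr <- pair_standard_sets(sel, cs, fs)
  expect_identical(pr$master_form, "crushed")
  expect_identical(pr$slave_form, "full")
  expect_equal(pr$master,
               cs$spectra$X[match(sel$ids, ids), , drop = FALSE],
               ignore_attr = TRUE)

  # shuffling the slave form's row order must not break the id alignment
  ord <- sample(length(ids))
  fs_shuf <- spectral_dataset(
    spectra_set(p$fs$spectra$X[ord, ], p$fs$spectra$wavelengths,
                ids[ord], "full"),
    unname(p$fs$y[ord]), sp$calibration_ids, sp$prediction_ids)
  pr2 <- pair_standard_sets(sel, cs, fs_shuf)
  expect_equal(pr2$slave, pr$slave, ignore_attr = TRUE)

  # disjoint id universes are an alignment error
  fs_bad <- spectral_dataset(
    spectra_set(p$fs$spectra$X, p$fs$spectra$wavelengths,
                paste0("z", seq_along(ids)), "full"),
    unname(p$fs$y))
  expect_error(pair_standard_sets(sel, cs, fs_bad), "alignment error")
})
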