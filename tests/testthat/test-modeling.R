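# Metrics, epsilon-SVR training/cross-validation, hybrid construction and
# model comparison.

test_that("rmse matches hand arithmetic and the shift identity", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(round(rmse(c(1, 2, 3), c(1, 2, 4)), 5), 0.57735)
  y <- rnorm(20)
  expect_equal(rmse(y, y + 0.3), 0.3, tolerance = 1e-12)
  expect_error(rmse(numeric(0), numeric(0)), "parameter error")
})

test_that("r2 covers the perfect, mean and worked cases", {
  y <- c(1, 2, 3)
  expect_equal(r2(y, y), 1)
  expect_equal(r2(y, rep(mean(y), 3)), 0)
  expect_equal(r2(y, c(1, 2, 4)), 0.5)
  expect_error(r2(rep(1, 3), c(1, 2, 3)), "undefined-R2")
})

test_that("rpd and rer match their definitions and flags", {
  y <- c(1, 2, 3)  # SD = 1, range = 2
  expect_equal(round(as.numeric(rpd(y, 0.57735)), 5), 1.73205)
  expect_equal(as.numeric(rpd(y, sd(y))), 1)
  expect_true(attr(rpd(y, 0.3), "reliable"))     # RPD 3.33 > 2.5
  expect_false(attr(rpd(y, 0.5), "reliable"))
  expect_equal(round(as.numeric(rer(y, 0.57735)), 4), 3.4641)
  expect_equal(as.numeric(rer(y, 2)), 1)
  expect_equal(as.numeric(rer(rep(2, 4), 0.1)), 0)
  expect_identical(attr(rer(y, 0.1), "utility"), "high efficiency")
  expect_identical(attr(rer(y, 0.4), "utility"), "good utility")
  expect_identical(attr(rer(y, 1), "utility"), "little utility")
  expect_warning(v <- rpd(y, 0), "Inf")
  expect_identical(as.numeric(v), Inf)
})

test_that("metric identities hold on random vectors", {
  set.seed(123)
  for (i in 1:100) {
    y <- rnorm(sample(5:30, 1))
    rm <- runif(1, 0.01, 2)
    expect_equal(as.numeric(rer(y, rm)) / as.numeric(rpd(y, rm)),
                 (max(y) - min(y)) / sd(y), tolerance = 1e-12)
    expect_equal(rmse(y, y + rm), rm, tolerance = 1e-12)
    expect_equal(r2(y, rep(mean(y), length(y))), 0, tolerance = 1e-12)
  }
})

test_that("train_svr fits a realizable linear function to near zero error", {
  set.seed(3)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- 1.7 * X[, 2] + 0.4
  m <- train_svr(X, y, svr_config(kernel = "linear", C = 100,
                                  epsilon = 1e-4), seed = 1)
  expect_lt(rmse(y, predict(m, X)), 1e-3)
})

test_that("train_svr is deterministic under a fixed seed", {
  set.seed(4)
  X <- matrix(rnorm(50 * 4), 50, 4)
  y <- sin(X[, 1]) + 0.1 * rnorm(50)
  cfg <- svr_config(C_grid = 2^(0:4), gamma_grid = 2^(-4:-1),
                    epsilon_grid = c(0.05, 0.1), n_folds = 5)
  m1 <- train_svr(X, y, cfg, seed = 11)
  m2 <- train_svr(X, y, cfg, seed = 11)
  expect_identical(predict(m1, X), predict(m2, X))
  expect_identical(c(m1$C, m1$gamma, m1$epsilon),
                   c(m2$C, m2$gamma, m2$epsilon))
})

test_that("the tuned model cross-validates well on a dominant-signal fixture", {
  for (s in 0:2) {
    pr <- generate_dataset_pair(fixture_config(n_samples = 80, n_bands = 24,
                                               seed = s))
    X <- pr$cs$spectra$X
    y <- unname(pr$cs$y)
    cfg <- svr_config(C_grid = 2^seq(-1, 9, 2), gamma_grid = 2^seq(-9, -1, 2),
                      epsilon_grid = 0.05, n_folds = 5)
    tuned <- train_svr(X, y, cfg, seed = s)
    cvres <- cross_validate(X, y,
                            svr_config(C = tuned$C, gamma = tuned$gamma,
                                       epsilon = tuned$epsilon),
                            n_folds = 10, seed = s)
    expect_gt(cvres$Rcv2, 0.8)
  }
})

test_that("cross_validate honours its contracts", {
  set.seed(6)
  X <- matrix(rnorm(30 * 2), 30, 2)
  y <- 2 * X[, 1] - X[, 2]
  cfg <- svr_config(kernel = "linear", C = 100, epsilon = 1e-4)
  cvres <- cross_validate(X, y, cfg, n_folds = 5, seed = 2)
  expect_lt(cvres$RMSECV, 1e-3)  # noiseless realizable
  # leave-one-out: as many folds as samples
  loo <- cross_validate(X, y, cfg, n_folds = 30, seed = 2)
  expect_identical(sort(unique(loo$folds)), 1:30)
  # fold determinism
  expect_identical(cross_validate(X, y, cfg, n_folds = 5, seed = 9)$folds,
                   cross_validate(X, y, cfg, n_folds = 5, seed = 9)$folds)
  expect_error(cross_validate(X[1:4, ], y[1:4], cfg, n_folds = 5, seed = 1),
               "partitioning error|fewer samples")
})

test_that("train_svr rejects non-finite features", {
  X <- matrix(rnorm(20), 10, 2); X[3, 1] <- Inf
  expect_error(train_svr(X, rnorm(10),
                         svr_config(C = 1, gamma = 1, epsilon = 0.1)),
               "data error")
})

test_that("build_hybrid augments by SPXY order and respects k", {
  set.seed(8)
  base_X <- matrix(rnorm(40 * 5), 40, 5); base_y <- rnorm(40)
  add_X <- matrix(rnorm(20 * 5), 20, 5); add_y <- rnorm(20)
  h0 <- build_hybrid(base_X, base_y, add_X, add_y, k = 0)
  expect_identical(h0$X, base_X)
  expect_identical(h0$k_added, 0L)
  cfg <- svr_config(C = 2, gamma = 0.25, epsilon = 0.05)
  p_base <- predict(train_svr(base_X, base_y, cfg, seed = 5), base_X)
  p_h0 <- predict(train_svr(h0$X, h0$y, cfg, seed = 5), base_X)
  expect_identical(p_base, p_h0)  # k = 0 is a no-op

  hall <- build_hybrid(base_X, base_y, add_X, add_y, k = 20)
  expect_identical(nrow(hall$X), 60L)
  expect_identical(hall$source,
                   c(rep("base", 40), rep("added", 20)))
  h5 <- build_hybrid(base_X, base_y, add_X, add_y, k = 5)
  expect_identical(unname(h5$X[41:45, ]),
                   unname(add_X[spxy_select(add_X, add_y, 5), ]))
  expect_error(build_hybrid(base_X, base_y, add_X[, 1:4], add_y, 5),
               "dimension error")
  expect_error(build_hybrid(base_X, base_y, add_X, add_y, 21),
               "parameter error")
})

test_that("hybrid_sweep yields one ordered row per k and is deterministic", {
  set.seed(10)
  base_X <- matrix(rnorm(50 * 4), 50, 4)
  base_y <- base_X[, 1] + 0.2 * rnorm(50)
  add_X <- matrix(rnorm(90 * 4), 90, 4)
  add_y <- add_X[, 1] + 0.3 * rnorm(90)
  ev_X <- matrix(rnorm(15 * 4), 15, 4)
  ev_y <- ev_X[, 1] + 0.2 * rnorm(15)
  cfg <- svr_config(C = 4, gamma = 0.25, epsilon = 0.05)
  sw <- hybrid_sweep(base_X, base_y, add_X, add_y,
                     k_grid = seq(5, 80, by = 5), transferred = TRUE,
                     eval_X = ev_X, eval_y = ev_y, config = cfg, seed = 2)
  expect_identical(nrow(sw$table), 16L)
  expect_identical(sw$table$k_added, as.integer(seq(5, 80, by = 5)))
  expect_true(all(is.finite(sw$table$RMSEP)))
  sw2 <- hybrid_sweep(base_X, base_y, add_X, add_y,
                      k_grid = seq(5, 80, by = 5), transferred = TRUE,
                      eval_X = ev_X, eval_y = ev_y, config = cfg, seed = 2)
  expect_identical(sw$table, sw2$table)

  sw0 <- hybrid_sweep(base_X, base_y, add_X, add_y, k_grid = 0,
                      eval_X = ev_X, eval_y = ev_y, config = cfg, seed = 2)
  base_fit <- fit_and_evaluate(base_X, base_y, ev_X, ev_y, config = cfg,
                               cv = FALSE, seed = 2)
  expect_equal(sw0$table$RMSEP, base_fit$metrics$RMSEP)
  expect_equal(sw0$table$Rp2, base_fit$metrics$Rp2)
})

test_that("compare_models reports signed percent changes per metric kind", {
  a <- list(RMSEP = 0.1691, RPD = 2.98)
  b <- list(RMSEP = 0.1535, RPD = 3.10)
  cm <- compare_models(a, b)
  expect_equal(round(cm$pct_change[cm$metric == "RMSEP"], 2), 9.23)
  expect_gt(cm$pct_change[cm$metric == "RPD"], 0)
  cm2 <- compare_models(a, a)
  expect_true(all(cm2$pct_change == 0))
  cm3 <- compare_models(list(RMSEP = 0.2), list(RMSEP = 0.1))
  expect_equal(cm3$pct_change, 50)
  cm4 <- compare_models(list(RMSEP = 0), list(RMSEP = 0.1))
  expect_true(attr(cm4, "undefined_change"))
})
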