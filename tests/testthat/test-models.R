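test_that("fit_linear recovers exact and hand-computed OLS solutions", {
  x <- c(1, 2, 3, 4)
  f <- fit_linear(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$fitted, 2 * x + 1)
  flat <- fit_linear(x, rep(5, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$intercept, 5)
  # hand OLS on 3 points: slope 0.5, intercept 1.0
  h <- fit_linear(c(1, 2, 3), c(1, 3, 2))
  expect_equal(h$slope, 0.5)
  expect_equal(h$intercept, 1.0)
  expect_equal(h$predict(10), 6)
  expect_error(fit_linear(rep(2, 5), 1:5), "constant")
})

test_that("mtry tuning minimizes out-of-bag RMSE verifiably", {
  set.seed(3)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- X[, 1]
  tuned <- tune_mtry(X, y, 1:5, n_trees = 200, seed = 11)
  # exhaustive refit of every candidate with its own deterministic seed
  refit <- vapply(1:5, function(m) {
    fit_rf(X, y, n_trees = 200, m_try = m, seed = 11 + m)$oob_rmse
  }, numeric(1))
  expect_equal(unname(tuned$oob_rmse), refit, tolerance = 1e-12)
  expect_true(all(tuned$oob_rmse[as.character(tuned$best_mtry)] <= tuned$oob_rmse))
  # single-element range: no choice; reruns identical
  expect_equal(tune_mtry(X, y, 3L, n_trees = 50, seed = 2)$best_mtry, 3L)
  t1 <- tune_mtry(X, y, 1:5, n_trees = 100, seed = 7)
  t2 <- tune_mtry(X, y, 1:5, n_trees = 100, seed = 7)
  expect_identical(t1, t2)
  expect_error(tune_mtry(X, y, integer(0)), "empty")
  expect_error(tune_mtry(X, y, 1:9), "n_features")
})

test_that("random forests are seeded, bounded and constant-safe", {
  set.seed(8)
  X <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 5 + X[, 1] + rnorm(60, 0, 0.2)
  f1 <- fit_rf(X, y, n_trees = 100, m_try = 2, seed = 5)
  f2 <- fit_rf(X, y, n_trees = 100, m_try = 2, seed = 5)
  expect_identical(f1$predict(X), f2$predict(X))
  newX <- matrix(rnorm(30 * 3, sd = 3), 30, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  p <- f1$predict(newX)
  expect_true(all(p >= min(y) & p <= max(y)))
  fc <- suppressWarnings(fit_rf(X, rep(4.2, 60), n_trees = 50, m_try = 1, seed = 1))
  expect_equal(unname(fc$predict(X)), rep(4.2, 60))
  expect_error(fit_rf(X, y, m_try = 7), "features")
  expect_error(fit_rf(X[1:5, ], y[1:5], m_try = 1), "10 samples")
})

test_that("a strong linear signal is recovered on held-out data", {
  set.seed(12)
  n <- 300
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- 3 * X[, 1] + rnorm(n, 0, 0.1)
  hold <- seq(1, n, by = 3)
  f <- fit_rf(X[-hold, ], y[-hold], n_trees = 300, m_try = 2, seed = 4)
  expect_gt(r_squared(y[hold], f$predict(X[hold, ])), 0.9)
})

test_that("importance normalization is proportional and sums to 100", {
  expect_equal(unname(normalize_importance(c(1, 1, 1, 1))), rep(25, 4))
  expect_equal(unname(normalize_importance(c(3, 1))), c(75, 25))
  expect_equal(unname(normalize_importance(7)), 100)
  expect_error(normalize_importance(c(0, 0)), "zero")
  expect_error(normalize_importance(c(-1, 2)), ">= 0")
})

test_that("all six strategies run with the right shapes and tuning ranges", {
  out <- run_som_pipeline(config = synth_config(n_samples = 45, seed = 2),
                          grid_step = 5, search_step = 20, n_trees = 60,
                          seed = 2)
  expect_setequal(out$summary$strategy,
                  c("1DV", "2DI", "3DI", "1DV+2DI", "1DV+3DI", "2DI+3DI"))
  res <- out$results
  for (nm in names(res)) {
    ncol_expect <- if (grepl("+", nm, fixed = TRUE)) 10L else 5L
    expect_length(res[[nm]]$importance, ncol_expect)
    expect_equal(sum(res[[nm]]$importance), 100, tolerance = 1e-6)
    expect_true(all(res[[nm]]$importance >= 0))
    max_mtry <- if (grepl("+", nm, fixed = TRUE)) 10L else 5L
    expect_lte(res[[nm]]$m_try, max_mtry)
    expect_length(res[[nm]]$oob_rmse, max_mtry)
    expect_length(res[[nm]]$predictions$val, length(out$split$validation$som))
  }
  # reproducibility end to end
  out2 <- run_som_pipeline(config = synth_config(n_samples = 45, seed = 2),
                           grid_step = 5, search_step = 20, n_trees = 60,
                           seed = 2)
  expect_identical(out$summary, out2$summary)
})
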