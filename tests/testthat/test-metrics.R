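test_that("r_squared is the squared Pearson correlation", {
  obs <- c(1, 2, 3, 4)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, 3 + 2 * obs), 1)      # affine invariance
  # independent hand computation: r = 3.5 / sqrt(5 * 4.75)
  expect_equal(r_squared(obs, c(2, 4, 5, 4)), (3.5 / sqrt(5 * 4.75))^2,
               tolerance = 1e-12)
  expect_equal(r_squared(obs, c(2, 4, 5, 4)), r_squared(c(2, 4, 5, 4), obs))
  expect_warning(rz <- r_squared(obs, rep(1, 4)), "constant")
  expect_equal(rz, 0)
  expect_error(r_squared(rep(1, 4), obs), "constant")
  # the residual-based variant penalizes bias where squared-r does not
  expect_equal(r_squared_ss(obs, obs), 1)
  expect_lt(r_squared_ss(obs, obs + 10), r_squared(obs, obs + 10))
})

test_that("rmse matches hand computations", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  expect_equal(rmse(c(0, 0, 0), c(1, 2, 2)), sqrt(3))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(rmse(1:3, 1:4), "mismatch")
})

test_that("rpiq reproduces the published worked examples", {
  # validation IQR 10.30 with published RMSEs
  expect_equal(round(rpiq(10.30, 2.52, is_iqr = TRUE), 2), 4.09)
  expect_equal(round(rpiq(10.30, 3.27, is_iqr = TRUE), 2), 3.15)
  expect_equal(round(rpiq(10.30, 6.86, is_iqr = TRUE), 2), 1.50)
  expect_equal(rpiq(5, 5, is_iqr = TRUE), 1)
  # vector form uses type-7 quantiles
  expect_equal(rpiq(1:8, 2), 3.5 / 2)
  expect_error(rpiq(1:8, 0), "rmse")
  expect_error(rpiq(1:3, 1), "4 validation")
  # scale invariance
  expect_equal(rpiq(3 * (1:8), 3 * 2), rpiq(1:8, 2))
})

test_that("rpiq categories follow the A-D thresholds with closed-down bounds", {
  expect_equal(rpiq_category(4.09), "A")
  expect_equal(rpiq_category(3.15), "C")
  expect_equal(rpiq_category(1.50), "D")
  expect_equal(rpiq_category(4.05), "B")
  expect_equal(rpiq_category(3.37), "C")
  expect_equal(rpiq_category(2.70), "D")
  # monotone non-decreasing in rpiq
  cats <- vapply(seq(0.5, 6, by = 0.1), rpiq_category, character(1))
  expect_true(all(diff(match(cats, c("D", "C", "B", "A"))) >= 0))
  expect_error(rpiq_category(0), "positive")
})

test_that("prediction bands strictly contain confidence bands and shrink with n", {
  set.seed(14)
  obs <- runif(40, 0, 10)
  pred <- obs + rnorm(40)
  b <- interval_bands(obs, pred)
  expect_true(all(b$pi_lo < b$ci_lo))
  expect_true(all(b$pi_hi > b$ci_hi))
  # doubling n with identical structure narrows the confidence band at the
  # mean point
  obs2 <- c(obs, obs); pred2 <- c(pred, pred)
  m <- mean(obs)
  w1 <- with(interval_bands(obs, pred, newdata = m), ci_hi - ci_lo)
  w2 <- with(interval_bands(obs2, pred2, newdata = m), ci_hi - ci_lo)
  expect_lt(w2, w1)
  expect_error(interval_bands(rep(1, 5), rnorm(5)), "constant")
})

test_that("evaluate_predictions bundles consistent metrics", {
  set.seed(20)
  cal_obs <- runif(30, 1, 30); cal_pred <- cal_obs + rnorm(30)
  val_obs <- runif(15, 1, 30); val_pred <- val_obs + rnorm(15)
  mt <- evaluate_predictions(cal_obs, cal_pred, val_obs, val_pred)
  expect_equal(mt$rmse_val, rmse(val_obs, val_pred))
  expect_equal(mt$rpiq, rpiq(val_obs, mt$rmse_val))
  expect_equal(mt$category, rpiq_category(mt$rpiq))
  expect_true(mt$r2_cal >= 0 && mt$r2_cal <= 1)
})

test_that("stability check reuses the two-group ANOVA", {
  r2c <- c(0.44, 0.74, 0.89, 0.83, 0.91, 0.94)
  r2v <- c(0.43, 0.70, 0.90, 0.82, 0.90, 0.93)
  expect_equal(stability_anova(r2c, r2v), anova_p(r2c, r2v))
  expect_gt(stability_anova(r2c, r2v), 0.05)
})

test_that("render_report writes a deterministic, re-parsable file set", {
  out <- run_som_pipeline(config = synth_config(n_samples = 36, seed = 5),
                          grid_step = 5, search_step = 20, n_trees = 50,
                          seed = 5)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  cal_som <- out$split$calibration$som
  val_som <- out$split$validation$som
  f1 <- render_report(out$results, cal_som, val_som, selected = out$selected,
                      out_dir = d1, figures = FALSE)
  f2 <- render_report(out$results, cal_som, val_som, selected = out$selected,
                      out_dir = d2, figures = FALSE)
  expect_true(all(file.exists(f1)))
  # byte-identical CSVs on rerun
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
  # summary round-trips the in-memory metrics
  smry <- utils::read.csv(file.path(d1, "strategy_summary.csv"))
  expect_equal(smry$rmse_val, out$summary$rmse_val, tolerance = 1e-9)
  expect_equal(smry$rpiq, out$summary$rpiq, tolerance = 1e-9)
  # six strategies -> six prediction and six importance tables
  expect_length(list.files(d1, pattern = "^predictions_"), 6)
  expect_length(list.files(d1, pattern = "^importance_"), 6)
})
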