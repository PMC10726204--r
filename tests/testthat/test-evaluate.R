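test_that("accuracy metrics match hand-evaluated formulas", {
  y <- c(1, 2, 3); p <- c(1, 2, 4)
  expect_equal(r_squared(y, p), 0.5, tolerance = 1e-12)   # SS_res 1, SS_tot 2
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2), tolerance = 1e-12)
  expect_equal(rmse(5, 2), 3)
  expect_equal(rmse(y, y), 0)
  expect_error(r_squared(c(2, 2), c(1, 3)), class = "viselect_degenerate_error")
})

test_that("R2 and RMSE satisfy their algebraic identity on shared vectors", {
  set.seed(1)
  y <- rnorm(50, 8, 1.4); p <- y + rnorm(50, 0, 0.5)
  ss_tot <- sum((y - mean(y))^2)
  expect_equal(r_squared(y, p), 1 - (rmse(y, p)^2 * 50) / ss_tot, tolerance = 1e-12)
  expect_equal(r_squared(y, p), oracle_r2(y, p), tolerance = 1e-12)
  expect_equal(rmse(y, p), oracle_rmse(y, p), tolerance = 1e-12)
})

test_that("k-fold CV partitions the plots and reports honest means", {
  pt <- simulate_planted_vitable(n = 60, seed = 3)
  cv <- kfold_cv(pt$vitable, pt$yield, subset = vi_names()[1:5],
                 spec = model_spec("cubist"), k = 5, seed = 2)
  expect_identical(sort(unique(cv$fold_id)), 1:5)
  expect_identical(length(cv$fold_id), 60L)          # every plot in one fold
  expect_identical(sum(cv$folds$n_val), 60L)
  expect_equal(cv$mean_r2, mean(cv$folds$r2))
  expect_equal(cv$mean_rmse, mean(cv$folds$rmse))
  # same seed, same partition and metrics
  cv2 <- kfold_cv(pt$vitable, pt$yield, subset = vi_names()[1:5],
                  spec = model_spec("cubist"), k = 5, seed = 2)
  expect_identical(cv$folds, cv2$folds)
  expect_error(kfold_cv(pt$vitable[1:4, ], pt$yield[1:4], k = 10),
               class = "viselect_sample_size_error")
})

test_that("leave-one-out is the k = n edge case", {
  pt <- simulate_planted_vitable(n = 20, seed = 4)
  cv <- kfold_cv(pt$vitable, pt$yield, subset = "NDVI",
                 spec = model_spec("cubist"), k = 20, seed = 1)
  expect_true(all(cv$folds$n_val == 1L))
  expect_true(all(is.na(cv$folds$r2)))  # single-point folds have no R2
  expect_true(all(is.finite(cv$folds$rmse)))
})

test_that("a constant-prediction model cannot exceed R2 = 0 under CV", {
  # intercept-only rule tree: min_split too high for any region structure
  pt <- simulate_planted_vitable(n = 50, planted = character(), seed = 5)
  cv <- kfold_cv(pt$vitable, pt$yield, subset = "NDVI",
                 spec = model_spec("cubist", min_split = 1e6, smooth = FALSE),
                 k = 5, seed = 3)
  expect_lte(cv$mean_r2, 0.05)
})

test_that("yield summaries reproduce hand-computed descriptive statistics", {
  s <- describe_yield(c(8, 10))
  expect_equal(s$mean, 9)
  expect_equal(s$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(s$cv_pct, 100 * sqrt(2) / 9, tolerance = 1e-6)
  s2 <- describe_yield(rep(4.2, 6))
  expect_equal(s2$sd, 0)
  expect_equal(s2$cv_pct, 0)
  expect_true(all(s2[c("min", "q25", "q50", "q75", "max")] == 4.2))
})

test_that("grouped summaries order quantiles and add up", {
  tr <- simulate_experiment(sim_config(seed = 6))
  s <- describe_yield(tr$plots$yield_t_ha, tr$plots$treatment)
  expect_identical(s$group, c("W1", "W2", "W3", "W4", "All"))
  expect_identical(sum(s$n[s$group != "All"]), s$n[s$group == "All"])
  for (i in seq_len(nrow(s))) {
    expect_true(with(s[i, ], min <= q25 && q25 <= q50 && q50 <= q75 && q75 <= max))
  }
})

test_that("pairwise Welch tests match the direct formula oracle", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  out <- treatment_ttest(c(a, b), rep(c("W1", "W2"), each = 3))
  o <- oracle_welch(a, b)
  expect_equal(out$t, o$t, tolerance = 1e-10)
  expect_equal(out$df, o$df, tolerance = 1e-10)
  expect_equal(out$p_value, o$p, tolerance = 1e-10)
  # symmetry: swapping groups negates t, keeps p
  out2 <- treatment_ttest(c(b, a), rep(c("W1", "W2"), each = 3))
  expect_equal(out2$t, -out$t, tolerance = 1e-12)
  expect_equal(out2$p_value, out$p_value, tolerance = 1e-12)
})

test_that("identical groups give t = 0, p = 1; all pairs are reported", {
  vals <- c(1, 2, 3, 1, 2, 3)
  out <- treatment_ttest(vals, rep(c("W1", "W2"), each = 3))
  expect_equal(out$t, 0)
  expect_equal(out$p_value, 1)
  tr <- simulate_experiment(sim_config(seed = 7))
  tab <- treatment_ttest(tr$plots$yield_t_ha, tr$plots$treatment)
  expect_identical(nrow(tab), 6L)  # all unordered treatment pairs
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
})

test_that("Welch reduces to Student for equal sizes and variances", {
  a <- c(1, 2, 3, 4); b <- a + 2  # same spread, same n
  out <- treatment_ttest(c(a, b), rep(c("W1", "W2"), each = 4))
  student <- t.test(a, b, var.equal = TRUE)
  expect_equal(out$t, unname(student$statistic), tolerance = 1e-10)
  expect_equal(out$df, unname(student$parameter), tolerance = 1e-10)
  expect_equal(out$p_value, student$p.value, tolerance = 1e-10)
})

test_that("degenerate pairs raise an undefined-test error", {
  vals <- c(5, 5, 5, 5, 1, 2)
  expect_error(treatment_ttest(vals[1:4], rep(c("W1", "W2"), each = 2)),
               class = "viselect_degenerate_error")
  expect_error(treatment_ttest(c(1), "W1"), class = "viselect_schema_error")
})
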