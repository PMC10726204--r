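test_that("pearson ranking matches the covariance-formula oracle", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  expect_equal(oracle_pearson(x, y), 0.8)  # exact rational value 4/5
  ft <- named_features(NDVI = x)
  rk <- pearson_ranking(ft, y)
  expect_equal(rk$score[rk$feature == "NDVI"], 0.8, tolerance = 1e-12)
})

test_that("pearson scores are |r|: perfect fits and anticorrelation score 1", {
  y <- c(2.3, 4.1, 5.0, 7.7, 9.2)
  ft <- named_features(NDVI = 2 * y + 1, RI = -y)
  rk <- pearson_ranking(ft, y)
  expect_equal(unname(rk$score), c(1, 1), tolerance = 1e-12)
  expect_true(all(rk$score >= 0 & rk$score <= 1))
})

test_that("pearson ranking is invariant to affine rescaling of a feature", {
  set.seed(1)
  y <- rnorm(40)
  x <- rnorm(40)
  a <- pearson_ranking(named_features(NDVI = x), y)$score
  b <- pearson_ranking(named_features(NDVI = -3.2 * x + 7), y)$score
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("degenerate inputs are handled: constant yield errors, constant feature scores 0", {
  ft <- named_features(NDVI = c(1, 2, 3), SAVI = c(5, 5, 5))
  expect_error(pearson_ranking(ft, c(4, 4, 4)), class = "viselect_degenerate_error")
  expect_warning(rk <- pearson_ranking(ft, c(1, 2, 4)), "SAVI")
  expect_equal(rk$score[rk$feature == "SAVI"], 0)
})

test_that("forest ranking is deterministic and finds a planted feature", {
  pt <- simulate_planted_vitable(n = 200, planted = "NDVI", rho = 1,
                                 signal = 0.95, seed = 8)
  rk1 <- rf_ranking(pt$vitable, pt$yield, seed = 3)
  rk2 <- rf_ranking(pt$vitable, pt$yield, seed = 3)
  expect_identical(rk1, rk2)
  expect_identical(rk1$feature[1], "NDVI")
  expect_error(rf_ranking(pt$vitable[1:5, ], pt$yield[1:5]),
               class = "viselect_sample_size_error")
})

test_that("thresholding retains strictly-exceeding scores only", {
  rk <- structure(data.frame(feature = c("NDVI", "SAVI", "RVI"),
                             score = c(0.9, 0.53, 0.2)),
                  method = "PC", class = c("vi_ranking", "data.frame"))
  expect_identical(apply_threshold(rk, 0.53)$features, "NDVI")
  expect_length(apply_threshold(rk, 0.1)$features, 3L)
  expect_length(apply_threshold(rk, 0.95)$features, 0L)
  expect_error(apply_threshold(rk, Inf), class = "viselect_schema_error")
})

test_that("threshold monotonicity: higher tau gives nested subsets", {
  pt <- simulate_planted_vitable(seed = 4)
  rk <- pearson_ranking(pt$vitable, pt$yield)
  taus <- c(0.1, 0.3, 0.5, 0.7)
  subs <- lapply(taus, function(t) apply_threshold(rk, t)$features)
  for (i in seq_len(length(taus) - 1)) {
    expect_true(all(subs[[i + 1]] %in% subs[[i]]))
  }
})

test_that("subset combination respects set arithmetic and idempotence", {
  nm <- vi_names()
  a <- vi_subset(nm[1:16])
  b <- vi_subset(nm[7:26])   # |A|=16, |B|=20, overlap 10
  expect_length(combine_subsets(a, b, "union")$features, 26L)
  expect_length(combine_subsets(a, b, "intersection")$features, 10L)
  u <- combine_subsets(a, b, "union")$features
  i <- combine_subsets(a, b, "intersection")$features
  expect_identical(length(u), length(a$features) + length(b$features) - length(i))
  expect_identical(combine_subsets(a, a, "union")$features, a$features)
})

test_that("rfe returns a contained subset whose score beats the start", {
  pt <- simulate_planted_vitable(n = 120, seed = 9)
  start <- vi_subset(vi_names()[1:12])
  cfg <- rfe_config(patience = 5, folds = 5, seed = 2)
  sel <- rfe_select(pt$vitable, pt$yield, start, cfg)
  expect_true(all(sel$features %in% start$features))
  expect_gte(length(sel$features), 1L)
  tr <- rfe_trace(sel)
  expect_lte(min(tr$rmse), tr$rmse[1])
  expect_lte(nrow(tr) - 1, length(start$features) - 1)  # at most |start|-1 drops
  expect_true(all(diff(tr$size) < 0))
  expect_error(rfe_select(pt$vitable, pt$yield, vi_subset(character()), cfg),
               class = "viselect_schema_error")
})

test_that("rfe is deterministic given its seed", {
  pt <- simulate_planted_vitable(n = 100, seed = 10)
  start <- vi_subset(vi_names()[1:8])
  cfg <- rfe_config(patience = 3, folds = 4, seed = 5)
  s1 <- rfe_select(pt$vitable, pt$yield, start, cfg)
  s2 <- rfe_select(pt$vitable, pt$yield, start, cfg)
  expect_identical(s1$features, s2$features)
  expect_identical(rfe_trace(s1), rfe_trace(s2))
})

test_that("integrated selector equals the manual chain of its four steps", {
  pt <- simulate_planted_vitable(n = 120, seed = 12)
  cfg <- rfe_config(patience = 3, folds = 4, seed = 6)
  sel <- pcrf_rfe(pt$vitable, pt$yield, config = cfg)
  rk_pc <- pearson_ranking(pt$vitable, pt$yield)
  rk_rf <- rf_ranking(pt$vitable, pt$yield, seed = cfg$seed)
  manual_union <- combine_subsets(apply_threshold(rk_pc, 0.53),
                                  apply_threshold(rk_rf, 1.9), "union")
  expect_identical(sel$subsets$union$features, manual_union$features)
  manual <- rfe_select(pt$vitable, pt$yield, manual_union, cfg)
  expect_identical(sel$features, manual$features)
})

test_that("integrated selector records its default thresholds in provenance", {
  pt <- simulate_planted_vitable(n = 100, seed = 13)
  sel <- pcrf_rfe(pt$vitable, pt$yield,
                  config = rfe_config(patience = 2, folds = 3, seed = 1))
  expect_equal(unname(sel$thresholds), c(0.53, 1.9))
  taus <- vapply(Filter(function(p) identical(p$step, "threshold"),
                        sel$provenance), `[[`, numeric(1), "tau")
  expect_true(0.53 %in% taus)
})

test_that("an empty union asks for threshold relaxation", {
  pt <- simulate_planted_vitable(n = 60, planted = character(), seed = 14)
  expect_error(pcrf_rfe(pt$vitable, pt$yield, pc_tau = 2, rf_tau = 1e6,
                        config = rfe_config(folds = 3, seed = 1)),
               "relax", class = "viselect_empty_union_error")
})
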