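make_xy <- function(n, p = 3, seed = 1, sd = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", seq_len(p))))
  list(X = X, y = 1 + 2 * X[, 1] - X[, min(2, p)] + rnorm(n, 0, sd))
}

test_that("rule tree with no admissible split reduces to global OLS", {
  d <- make_xy(8, seed = 2)
  fit <- fit_model(model_spec("cubist", min_split = 100), d$X, d$y)
  expect_equal(predict(fit, d$X), oracle_ols_fitted(d$X, d$y), tolerance = 1e-8)
  cf <- coef(fit)
  expect_named(cf, c("(Intercept)", colnames(d$X)))
})

test_that("rule tree recovers a step function as two regions", {
  set.seed(4)
  n <- 200
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("x1", "x2")))
  y <- ifelse(X[, 1] < 0, 0, 10) + rnorm(n, 0, 0.1)
  fit <- fit_model(model_spec("cubist"), X, y)
  cf <- coef(fit)
  expect_length(cf, 2L)  # two rules
  intercepts <- sort(vapply(cf, `[[`, numeric(1), "(Intercept)"))
  expect_lt(abs(intercepts[1] - 0), 0.2)
  expect_lt(abs(intercepts[2] - 10), 0.2)
})

test_that("rule tree handles degenerate targets and is order invariant", {
  d <- make_xy(60, seed = 5)
  const <- fit_model(model_spec("cubist"), d$X, rep(5, 60))
  expect_equal(predict(const, d$X), rep(5, 60))
  fit <- fit_model(model_spec("cubist"), d$X, d$y)
  perm <- sample(60)
  fit_p <- fit_model(model_spec("cubist"), d$X[perm, ], d$y[perm])
  expect_equal(predict(fit_p, d$X), predict(fit, d$X), tolerance = 1e-12)
})

test_that("rule-tree importance is zero for features outside every rule", {
  set.seed(6)
  n <- 150
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- ifelse(X[, 1] < 0, 1, 5) + rnorm(n, 0, 0.1)
  fit <- fit_model(model_spec("cubist"), X, y)
  imp <- model_importance(fit, X, y)
  expect_gt(imp$score[imp$feature == "x1"], 0)
  expect_equal(imp$score[imp$feature == "x3"], 0)
  expect_true(all(imp$score >= 0))
})

test_that("recurrent regressor fits a constant and a linear signal", {
  set.seed(7)
  X <- matrix(rnorm(300 * 6), 300, dimnames = list(NULL, paste0("f", 1:6)))
  yc <- rep(8, 300)
  fitc <- fit_model(model_spec("rnn", seed = 1), X[1:60, ], yc[1:60])
  expect_true(all(abs(predict(fitc, X[1:60, ]) - 8) < 0.05 * 8))
  y <- 3 + 1.5 * X[, 2] - 2 * X[, 5] + rnorm(300, 0, 0.05)
  fit <- fit_model(model_spec("rnn", seed = 2), X, y)
  expect_gte(r_squared(y, predict(fit, X)), 0.9)
})

test_that("recurrent regressor is deterministic and its checkpoints improve monotonically", {
  d <- make_xy(80, p = 5, seed = 9)
  f1 <- fit_model(model_spec("rnn", epochs = 120, seed = 4), d$X, d$y)
  f2 <- fit_model(model_spec("rnn", epochs = 120, seed = 4), d$X, d$y)
  expect_identical(predict(f1, d$X), predict(f2, d$X))
  expect_true(all(is.finite(f1$history$checkpoints)))
  expect_false(is.unsorted(rev(f1$history$checkpoints)))
})

test_that("permutation importance ignores a weight-dead feature and finds a dominant one", {
  d <- make_xy(150, p = 4, seed = 10)
  fit <- fit_model(model_spec("rnn", epochs = 150, seed = 5), d$X, d$y)
  # probe: zero the input weight so the network cannot see any feature;
  # permuting then changes nothing
  probe <- fit
  probe$par$win[] <- 0
  imp0 <- model_importance(probe, d$X, d$y, seed = 6)
  expect_true(all(imp0$score < 1e-8))
  imp <- model_importance(fit, d$X, d$y, seed = 6)
  expect_identical(imp$feature[1], "f1")  # the dominant planted feature
})

test_that("prediction validates feature names strictly", {
  d <- make_xy(40, seed = 11)
  fit <- fit_model(model_spec("cubist"), d$X, d$y)
  bad <- d$X
  colnames(bad) <- c("f1", "f2", "zz")
  expect_error(predict(fit, bad), "zz", class = "viselect_schema_error")
  expect_error(predict(fit, d$X[, 1:2]), "f3", class = "viselect_schema_error")
  shuffled <- d$X[, c(3, 1, 2)]
  expect_equal(predict(fit, shuffled), predict(fit, d$X))
})

test_that("serialization round-trips both families bit-exactly", {
  d <- make_xy(80, p = 4, seed = 12)
  for (fam in c("cubist", "rnn")) {
    spec <- if (fam == "rnn") model_spec("rnn", epochs = 60, seed = 3) else model_spec(fam)
    fit <- fit_model(spec, d$X, d$y)
    path <- withr::local_tempfile(fileext = ".json")
    write_model(fit, path)
    reloaded <- read_model(path)
    expect_identical(predict(reloaded, d$X), predict(fit, d$X),
                     label = fam)
  }
})

test_that("training data with missing values or too few rows is rejected", {
  d <- make_xy(20, seed = 13)
  Xna <- d$X; Xna[1, 1] <- NA
  expect_error(fit_model(model_spec("cubist"), Xna, d$y), class = "viselect_schema_error")
  expect_error(fit_model(model_spec("cubist"), d$X[1:3, ], d$y[1:3]),
               class = "viselect_sample_size_error")
  expect_error(fit_model(model_spec("rnn"), d$X[1:8, ], d$y[1:8]),
               class = "viselect_sample_size_error")
})
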