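#' @section Model evaluation:
#' Prediction accuracy is reported as the coefficient of determination
#' (R² = 1 - SS_res/SS_tot) and the root-mean-square error in yield units
#' (t/ha), estimated by k-fold cross-validation: the plots are randomly
#' partitioned into k folds, each fold serves once as the validation set,
#' and the per-fold metrics are averaged into the final accuracy.
#' @name evaluate
NULL

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; at most 1, may be negative for predictions worse
#' than the observed mean.
#'
#' @param y_obs Observed values (non-constant, length >= 2).
#' @param y_pred Predicted values, same length.
#' @return A single number.
#' @export
r_squared <- function(y_obs, y_pred) {
  y_obs <- as.numeric(y_obs); y_pred <- as.numeric(y_pred)
  if (length(y_obs) != length(y_pred)) vi_stop("lengths differ", "viselect_schema_error")
  if (length(y_obs) < 2) vi_stop("need at least 2 observations", "viselect_sample_size_error")
  ss_tot <- sum((y_obs - mean(y_obs))^2)
  if (ss_tot == 0) vi_stop("observed values are constant; R-squared undefined",
                           "viselect_degenerate_error")
  1 - sum((y_pred - y_obs)^2) / ss_tot
}

#' Root-mean-square error
#'
#' @inheritParams r_squared
#' @return A single non-negative number (t/ha when inputs are yields).
#' @export
rmse <- function(y_obs, y_pred) {
  y_obs <- as.numeric(y_obs); y_pred <- as.numeric(y_pred)
  if (length(y_obs) != length(y_pred)) vi_stop("lengths differ", "viselect_schema_error")
  if (length(y_obs) < 1) vi_stop("need at least 1 observation", "viselect_sample_size_error")
  sqrt(mean((y_pred - y_obs)^2))
}

#' k-fold cross-validated accuracy of a base model
#'
#' Randomly partitions the plots into `k` folds (simple random by default,
#' optionally stratified), fits the base model on k-1 folds and scores the
#' held-out fold, and reports per-fold and mean R²/RMSE. Deterministic
#' given `seed`; stochastic base models receive per-fold seeds derived from
#' it.
#'
#' @inheritParams pearson_ranking
#' @param subset Optional `vi_subset` (or character vector) restricting the
#'   feature columns; default all index columns present.
#' @param spec A [model_spec()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the partition.
#' @param stratify Optional grouping vector (e.g. treatment labels); folds
#'   are then drawn within each group.
#' @return An object of class `cv_result`.
#' @export
kfold_cv <- function(vitable, yield, subset = NULL, spec = model_spec("cubist"),
                     k = 10, seed = 1, stratify = NULL) {
  X <- vi_feature_matrix(vitable)
  y <- as.numeric(yield)
  if (nrow(X) != length(y)) vi_stop("vitable and yield disagree on rows", "viselect_schema_error")
  features <- if (is.null(subset)) colnames(X) else {
    if (inherits(subset, "vi_subset")) subset$features else as.character(subset)
  }
  missing <- setdiff(features, colnames(X))
  if (length(missing)) {
    vi_stop(sprintf("subset feature(s) absent from table: %s",
                    paste(missing, collapse = ", ")), "viselect_schema_error")
  }
  X <- X[, features, drop = FALSE]
  ok <- stats::complete.cases(X, y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  if (k < 2) vi_stop("k must be >= 2", "viselect_schema_error")
  if (n < k) vi_stop(sprintf("need at least k = %d plots, got %d", k, n),
                     "viselect_sample_size_error")
  fold_id <- with_seed(seed, {
    if (is.null(stratify)) {
      sample(rep_len(seq_len(k), n))
    } else {
      g <- as.factor(stratify[ok])
      id <- integer(n)
      for (lev in levels(g)) {
        rows <- which(g == lev)
        id[rows] <- sample(rep_len(seq_len(k), length(rows)))
      }
      id
    }
  })
  folds <- lapply(seq_len(k), function(f) {
    val <- fold_id == f
    fit <- fit_model(set_spec_seed(spec, mix_seed(seed, f)),
                     X[!val, , drop = FALSE], y[!val])
    pred <- predict(fit, X[val, , drop = FALSE])
    yv <- y[val]
    r2 <- if (length(yv) >= 2 && stats::sd(yv) > 0) r_squared(yv, pred) else NA_real_
    data.frame(fold = f, n_val = sum(val), r2 = r2, rmse = rmse(yv, pred))
  })
  folds <- do.call(rbind, folds)
  structure(list(folds = folds,
                 mean_r2 = mean(folds$r2, na.rm = TRUE),
                 mean_rmse = mean(folds$rmse),
                 k = k, seed = seed, family = spec$family,
                 features = features, fold_id = fold_id),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV of %s model on %d feature(s):\n",
              x$k, x$family, length(x$features)))
  cat(sprintf("  mean R2 = %.3f, mean RMSE = %.3f t/ha\n", x$mean_r2, x$mean_rmse))
  invisible(x)
}

#' Descriptive yield statistics per group
#'
#' Classic trial-summary statistics: n, min, max, sample SD, quartiles
#' (linear interpolation), mean and the coefficient of variation in percent,
#' per group and overall.
#'
#' @param yields Positive numeric yields (t/ha).
#' @param groups Optional grouping labels, one per plot. Empty groups are
#'   dropped with a warning.
#' @return A data.frame with one row per group plus an `All` row.
#' @export
describe_yield <- function(yields, groups = NULL) {
  yields <- as.numeric(yields)
  one <- function(label, v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    m <- mean(v)
    s <- stats::sd(v)
    data.frame(group = label, n = length(v), min = min(v), max = max(v),
               sd = s, q25 = q[1], q50 = q[2], q75 = q[3], mean = m,
               cv_pct = if (m > 0) 100 * s / m else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  if (!is.null(groups)) {
    g <- as.factor(groups)
    for (lev in levels(g)) {
      v <- yields[g == lev]
      if (!length(v)) {
        warning(sprintf("group '%s' is empty; omitted", lev), call. = FALSE)
        next
      }
      rows[[length(rows) + 1]] <- one(lev, v)
    }
  }
  rows[[length(rows) + 1]] <- one("All", yields)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise Welch t-tests between treatments
#'
#' Two-sided Welch (unequal-variance) two-sample t-tests for every
#' unordered pair of treatment labels, with Welch-Satterthwaite degrees of
#' freedom. P-values are reported raw by default; `adjust = "holm"` applies
#' a Holm correction.
#'
#' @param values Numeric response (e.g. observed or predicted yield).
#' @param treatment_labels Treatment label per value; at least two
#'   treatments with two or more values each.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A data.frame with columns `group1`, `group2`, `t`, `df`,
#'   `p_value` (and `p_adj` if adjusted).
#' @export
treatment_ttest <- function(values, treatment_labels, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  values <- as.numeric(values)
  g <- as.factor(treatment_labels)
  levs <- levels(droplevels(g))
  if (length(levs) < 2) vi_stop("need at least two treatments", "viselect_schema_error")
  for (lev in levs) {
    if (sum(g == lev) < 2) {
      vi_stop(sprintf("treatment '%s' has fewer than 2 plots", lev),
              "viselect_sample_size_error")
    }
  }
  pairs <- utils::combn(levs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- values[g == pairs[1, i]]
    b <- values[g == pairs[2, i]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      vi_stop(sprintf("both groups have zero variance in pair %s vs %s; test undefined",
                      pairs[1, i], pairs[2, i]), "viselect_degenerate_error")
    }
    tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p_adj <- stats::p.adjust(out$p_value, "holm")
  rownames(out) <- NULL
  out
}
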