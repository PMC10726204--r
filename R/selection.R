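#' @section Integrated feature selection:
#' Selection proceeds in two stages. First, two independent rankings are
#' computed: the absolute Pearson correlation of each index with yield
#' (filter stage) and random-forest permutation importance (embedded stage).
#' Each ranking is cut at a threshold (defaults 0.53 and 1.9, on the |r| and
#' %IncMSE scales respectively) and the union of the two retained sets seeds
#' the wrapper stage: recursive feature elimination that repeatedly drops
#' the least important feature of a base regressor, scores each candidate
#' subset by inner k-fold cross-validated RMSE, and stops after a patience
#' budget of consecutive non-improving eliminations, returning the best
#' subset seen.
#' @name selection
NULL

# ---- ranking / subset containers -------------------------------------------

new_ranking <- function(feature, score, method, details = list()) {
  ord <- order(-score, match(feature, vi_names()))
  structure(
    data.frame(feature = feature[ord], score = score[ord],
               stringsAsFactors = FALSE, row.names = NULL),
    method = method, details = details,
    class = c("vi_ranking", "data.frame")
  )
}

#' @export
print.vi_ranking <- function(x, n = 10, ...) {
  cat(sprintf("<vi_ranking> method: %s (%d features)\n", attr(x, "method"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat(sprintf("  ... %d more\n", nrow(x) - n))
  invisible(x)
}

#' Construct a feature subset
#'
#' A feature subset is a named set of vegetation indices together with a
#' provenance record describing how it was obtained. Features are stored in
#' canonical table order.
#'
#' @param features Character vector of index names.
#' @param provenance A list of provenance records (each itself a list).
#' @return An object of class `vi_subset`.
#' @export
vi_subset <- function(features, provenance = list()) {
  unknown <- setdiff(features, vi_names())
  if (length(unknown)) {
    vi_stop(sprintf("feature(s) not in the index library: %s",
                    paste(unknown, collapse = ", ")), "viselect_name_error")
  }
  features <- intersect(vi_names(), unique(features))  # canonical order
  structure(list(features = features, provenance = provenance),
            class = "vi_subset")
}

#' @export
print.vi_subset <- function(x, ...) {
  cat(sprintf("<vi_subset> %d feature(s)\n", length(x$features)))
  cat(" ", paste(x$features, collapse = ", "), "\n")
  steps <- vapply(x$provenance, function(p) p$step %||% "?", character(1))
  if (length(steps)) cat("  provenance:", paste(steps, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
length.vi_subset <- function(x) length(x$features)

# ---- filter stage ----------------------------------------------------------

#' Pearson-correlation ranking of indices against yield
#'
#' Scores every index column by the absolute Pearson correlation with the
#' yield vector (pairwise-complete observations). Indices with zero variance
#' (or fewer than three complete pairs) receive score 0 with a warning.
#' Ties are broken by canonical table order.
#'
#' @param vitable A `vi_table` or data.frame containing index columns.
#' @param yield Numeric yield vector, one value per plot.
#' @return A `vi_ranking` with scores in \[0, 1\].
#' @export
pearson_ranking <- function(vitable, yield) {
  X <- vi_feature_matrix(vitable)
  stopifnot_numeric(yield, "yield")
  if (nrow(X) != length(yield)) {
    vi_stop("vitable and yield disagree on the number of plots", "viselect_schema_error")
  }
  if (length(yield) < 3L) vi_stop("need at least 3 plots", "viselect_sample_size_error")
  if (stats::sd(yield) == 0) {
    vi_stop("yield is constant; correlations are undefined", "viselect_degenerate_error")
  }
  degenerate <- character()
  score <- vapply(colnames(X), function(nm) {
    x <- X[, nm]
    ok <- stats::complete.cases(x, yield)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0) {
      degenerate <<- c(degenerate, nm)
      return(0)
    }
    abs(stats::cor(x[ok], yield[ok]))
  }, numeric(1))
  if (length(degenerate)) {
    warning(sprintf("zero-variance or insufficient data; score set to 0: %s",
                    paste(degenerate, collapse = ", ")), call. = FALSE)
  }
  new_ranking(colnames(X), unname(score), method = "PC")
}

# ---- embedded stage --------------------------------------------------------

#' Random-forest permutation-importance ranking
#'
#' Fits a random-forest regressor of yield on the index columns and scores
#' each index by permutation importance: the mean out-of-bag increase in MSE
#' when that feature is permuted, averaged over trees and reported on the
#' normalized %IncMSE scale. Deterministic given `seed`.
#'
#' @inheritParams pearson_ranking
#' @param num_trees Number of trees (default 500).
#' @param mtry Features tried per split; default `floor(p/3)` as customary
#'   for regression forests.
#' @param seed Integer seed.
#' @return A `vi_ranking` (scores may be negative for pure-noise features).
#' @export
rf_ranking <- function(vitable, yield, num_trees = 500, mtry = NULL, seed = 1) {
  X <- vi_feature_matrix(vitable)
  stopifnot_numeric(yield, "yield")
  if (nrow(X) != length(yield)) {
    vi_stop("vitable and yield disagree on the number of plots", "viselect_schema_error")
  }
  ok <- stats::complete.cases(X, yield)
  if (sum(ok) < 10L) {
    vi_stop("need at least 10 complete plots for the forest", "viselect_sample_size_error")
  }
  X <- X[ok, , drop = FALSE]
  y <- yield[ok]
  mtry <- mtry %||% max(1L, floor(ncol(X) / 3))
  fit <- with_seed(seed,
    randomForest::randomForest(x = X, y = y, ntree = num_trees, mtry = mtry,
                               importance = TRUE))
  imp <- randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
  new_ranking(colnames(X), unname(imp), method = "RF",
              details = list(num_trees = num_trees, mtry = mtry, seed = seed))
}

# ---- thresholding and combination ------------------------------------------

#' Cut a ranking at a threshold
#'
#' Retains exactly the features whose score strictly exceeds `tau`.
#'
#' @param ranking A `vi_ranking`.
#' @param tau Finite threshold on the ranking's score scale.
#' @return A `vi_subset` recording the method and threshold in provenance.
#' @export
apply_threshold <- function(ranking, tau) {
  if (!is.finite(tau)) vi_stop("tau must be finite", "viselect_schema_error")
  keep <- ranking$feature[ranking$score > tau]
  vi_subset(keep, provenance = list(list(
    step = "threshold", method = attr(ranking, "method"),
    tau = tau, n_retained = length(keep)
  )))
}

#' Combine two feature subsets
#'
#' Set union or intersection of two subsets drawn from the index library,
#' with provenance concatenated.
#'
#' @param a,b `vi_subset` objects.
#' @param mode `"union"` or `"intersection"`.
#' @return A `vi_subset`.
#' @export
combine_subsets <- function(a, b, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  fa <- a$features
  fb <- b$features
  keep <- if (mode == "union") union(fa, fb) else intersect(fa, fb)
  vi_subset(keep, provenance = c(a$provenance, b$provenance, list(list(
    step = "combine", mode = mode,
    sizes = c(a = length(fa), b = length(fb), result = length(keep))
  ))))
}

# ---- wrapper stage: recursive feature elimination --------------------------

#' Configuration for recursive feature elimination
#'
#' @param base A [model_spec()] for the base regressor (default a rule-tree
#'   "cubist" spec).
#' @param patience Non-negative integer: the run stops after this many
#'   consecutive eliminations without improvement of the best inner-CV RMSE
#'   (default 10).
#' @param step Features removed per iteration (default 1).
#' @param folds Inner cross-validation folds used to score each candidate
#'   subset (default 10).
#' @param seed Integer seed driving fold assignment and any stochastic base
#'   model.
#' @param tol Minimal RMSE decrease counted as an improvement (default 1e-9).
#' @return A list of class `rfe_config`.
#' @export
rfe_config <- function(base = model_spec("cubist"), patience = 10, step = 1,
                       folds = 10, seed = 1, tol = 1e-9) {
  if (patience < 0) vi_stop("patience must be >= 0", "viselect_schema_error")
  if (step < 1) vi_stop("step must be >= 1", "viselect_schema_error")
  structure(list(base = base, patience = as.integer(patience),
                 step = as.integer(step), folds = as.integer(folds),
                 seed = as.integer(seed), tol = tol),
            class = "rfe_config")
}

# Inner-CV RMSE of the base model on a fixed fold assignment.
inner_cv_rmse <- function(X, y, features, fold_id, base, seed) {
  errs <- numeric(0)
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    fit <- fit_model(set_spec_seed(base, mix_seed(seed, f)),
                     X[tr, features, drop = FALSE], y[tr])
    pred <- predict(fit, X[!tr, features, drop = FALSE])
    errs <- c(errs, (pred - y[!tr])^2)
  }
  sqrt(mean(errs))
}

#' Recursive feature elimination with patience
#'
#' Starting from a candidate subset, repeatedly fits the base model on the
#' current features, scores the subset by inner cross-validated RMSE, and
#' removes the least important feature(s) according to the base model's own
#' importance measure. The best subset seen is tracked throughout; the run
#' terminates when `patience` consecutive eliminations fail to improve the
#' best RMSE (by more than `tol`) or when a single feature remains.
#'
#' @inheritParams pearson_ranking
#' @param start_subset A non-empty `vi_subset` to start from.
#' @param config An [rfe_config()].
#' @return A `vi_subset` (the best subset seen) whose provenance carries the
#'   full score trace (`iteration`, `size`, `rmse`, `dropped`, `best`).
#' @export
rfe_select <- function(vitable, yield, start_subset, config = rfe_config()) {
  if (!inherits(start_subset, "vi_subset")) start_subset <- vi_subset(start_subset)
  if (length(start_subset$features) == 0L) {
    vi_stop("start subset is empty", "viselect_schema_error")
  }
  X <- vi_feature_matrix(vitable)
  y <- as.numeric(yield)
  ok <- stats::complete.cases(X[, start_subset$features, drop = FALSE], y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  k <- min(config$folds, n)
  fold_id <- with_seed(config$seed, sample(rep_len(seq_len(k), n)))

  current <- start_subset$features
  score0 <- inner_cv_rmse(X, y, current, fold_id, config$base, config$seed)
  best <- current; best_rmse <- score0
  trace <- data.frame(iteration = 0L, size = length(current), rmse = score0,
                      dropped = NA_character_, best = TRUE,
                      stringsAsFactors = FALSE)
  no_improve <- 0L
  iter <- 0L
  while (length(current) > 1L && no_improve < config$patience) {
    iter <- iter + 1L
    fit <- tryCatch(
      fit_model(set_spec_seed(config$base, mix_seed(config$seed, 1000L + iter)),
                X[, current, drop = FALSE], y),
      error = function(e) vi_stop(
        sprintf("base model failed at RFE iteration %d: %s", iter, conditionMessage(e)),
        "viselect_fit_error"))
    imp <- model_importance(fit, X[, current, drop = FALSE], y,
                            seed = mix_seed(config$seed, 2000L + iter))
    # least important first; ties resolved by dropping the feature latest in
    # canonical table order so earlier-table features survive
    ord <- order(imp$score[match(current, imp$feature)],
                 -match(current, vi_names()))
    drop <- current[ord][seq_len(min(config$step, length(current) - 1L))]
    current <- setdiff(current, drop)
    rmse_i <- inner_cv_rmse(X, y, current, fold_id, config$base, config$seed)
    improved <- rmse_i < best_rmse - config$tol
    if (improved) {
      best <- current; best_rmse <- rmse_i; no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
    }
    trace <- rbind(trace, data.frame(
      iteration = iter, size = length(current), rmse = rmse_i,
      dropped = paste(drop, collapse = ","), best = improved,
      stringsAsFactors = FALSE))
  }
  vi_subset(best, provenance = c(start_subset$provenance, list(list(
    step = "rfe", base = config$base$family, patience = config$patience,
    folds = k, seed = config$seed, best_rmse = best_rmse,
    start_size = length(start_subset$features), trace = trace
  ))))
}

# ---- full composition ------------------------------------------------------

#' Integrated filter + embedded + wrapper feature selection
#'
#' The full two-stage selector: Pearson and random-forest rankings are cut
#' at their thresholds, the union of the retained sets is formed, and the
#' union is refined by [rfe_select()]. The returned object carries the final
#' subset together with both rankings and every intermediate subset.
#'
#' @inheritParams pearson_ranking
#' @param pc_tau Threshold on |Pearson r| (default 0.53).
#' @param rf_tau Threshold on forest %IncMSE importance (default 1.9).
#' @param config An [rfe_config()] for the wrapper stage.
#' @param rf_seed Seed for the ranking forest (defaults to the RFE seed).
#' @param num_trees Trees for the ranking forest.
#' @return An object of class `pcrf_rfe` (also a `vi_subset`): the selected
#'   features plus `$rankings`, `$subsets` (pc, rf, union, intersection) and
#'   the RFE trace in provenance.
#' @export
pcrf_rfe <- function(vitable, yield, pc_tau = 0.53, rf_tau = 1.9,
                     config = rfe_config(), rf_seed = NULL, num_trees = 500) {
  rk_pc <- pearson_ranking(vitable, yield)
  rk_rf <- rf_ranking(vitable, yield, num_trees = num_trees,
                      seed = rf_seed %||% config$seed)
  sub_pc <- apply_threshold(rk_pc, pc_tau)
  sub_rf <- apply_threshold(rk_rf, rf_tau)
  sub_union <- combine_subsets(sub_pc, sub_rf, "union")
  sub_inter <- combine_subsets(sub_pc, sub_rf, "intersection")
  if (length(sub_union$features) == 0L) {
    vi_stop(paste("no feature exceeds either threshold; relax pc_tau and/or",
                  "rf_tau and rerun"), "viselect_empty_union_error")
  }
  final <- rfe_select(vitable, yield, sub_union, config)
  structure(list(
    features = final$features,
    provenance = final$provenance,
    rankings = list(pc = rk_pc, rf = rk_rf),
    subsets = list(pc = sub_pc, rf = sub_rf, union = sub_union,
                   intersection = sub_inter),
    thresholds = c(pc = pc_tau, rf = rf_tau)
  ), class = c("pcrf_rfe", "vi_subset"))
}

#' @export
print.pcrf_rfe <- function(x, ...) {
  cat("Integrated feature selection (PC filter + RF importance + RFE)\n")
  cat(sprintf("  thresholds: |r| > %g, importance > %g\n",
              x$thresholds["pc"], x$thresholds["rf"]))
  cat(sprintf("  PC subset: %d  RF subset: %d  union: %d  intersection: %d\n",
              length(x$subsets$pc), length(x$subsets$rf),
              length(x$subsets$union), length(x$subsets$intersection)))
  cat(sprintf("  selected (%d): %s\n", length(x$features),
              paste(x$features, collapse = ", ")))
  invisible(x)
}

#' @export
summary.pcrf_rfe <- function(object, ...) {
  tr <- rfe_trace(object)
  cat("RFE score trace (inner-CV RMSE, t/ha):\n")
  print(tr, row.names = FALSE)
  invisible(tr)
}

#' Extract the RFE score trace
#'
#' @param x A `pcrf_rfe` or `vi_subset` produced by [rfe_select()].
#' @return A data.frame with one row per RFE iteration.
#' @export
rfe_trace <- function(x) {
  for (p in rev(x$provenance)) if (identical(p$step, "rfe")) return(p$trace)
  vi_stop("no RFE step found in provenance", "viselect_schema_error")
}

#' @export
plot.pcrf_rfe <- function(x, ...) {
  tr <- rfe_trace(x)
  plot(tr$size, tr$rmse, type = "b", xlab = "subset size",
       ylab = "inner-CV RMSE (t/ha)", xlim = rev(range(tr$size)), ...)
  points(tr$size[tr$best], tr$rmse[tr$best], pch = 19)
  invisible(x)
}
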