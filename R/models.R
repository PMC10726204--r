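#' @section Base regressors:
#' Two base regressors are provided behind one fitting contract: a
#' rule-based model tree in the Cubist/M5 family (recursive partitioning
#' with an ordinary-least-squares model per region, pruning by
#' complexity-corrected error and smoothing along the path) and a plain
#' recurrent-network regressor that reads the feature vector as a sequence
#' of scalars through a single tanh recurrent layer. Both are deterministic
#' given their seed and expose a native feature-importance measure used by
#' the RFE wrapper.
#' @name models
NULL

#' Specify a base regressor
#'
#' @param family `"cubist"` for the rule-based model tree, `"rnn"` for the
#'   recurrent-network regressor.
#' @param ... Passed to [cubist_control()] or [rnn_control()].
#' @param seed Integer seed (used by stochastic families; the rule tree is
#'   deterministic).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("cubist", "rnn"), ..., seed = 1L) {
  family <- match.arg(family)
  control <- switch(family, cubist = cubist_control(...), rnn = rnn_control(...))
  structure(list(family = family, control = control, seed = as.integer(seed)),
            class = "model_spec")
}

set_spec_seed <- function(spec, seed) {
  spec$seed <- as.integer(seed)
  spec
}

check_train_xy <- function(X, y, min_n) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    vi_stop("X must be a numeric matrix or data.frame", "viselect_schema_error")
  }
  if (is.null(colnames(X))) {
    vi_stop("X must have column names (feature names)", "viselect_schema_error")
  }
  y <- as.numeric(y)
  if (nrow(X) != length(y)) vi_stop("X and y lengths differ", "viselect_schema_error")
  if (anyNA(X) || anyNA(y)) vi_stop("missing values in training data", "viselect_schema_error")
  if (nrow(X) < min_n) {
    vi_stop(sprintf("need at least %d rows, got %d", min_n, nrow(X)),
            "viselect_sample_size_error")
  }
  list(X = X, y = y)
}

#' Fit a base regressor
#'
#' @param spec A [model_spec()].
#' @param X Numeric feature matrix (or data.frame) with column names.
#' @param y Numeric response.
#' @return A fitted model of class `vi_cubist` or `vi_rnn` (both inherit
#'   `vi_model`).
#' @export
fit_model <- function(spec, X, y) {
  if (!inherits(spec, "model_spec")) vi_stop("spec must be a model_spec", "viselect_schema_error")
  switch(spec$family,
         cubist = fit_cubist(X, y, spec),
         rnn = fit_rnn(X, y, spec))
}

# Validate prediction input against the training feature names and return
# the columns in training order.
check_predict_X <- function(object, X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    vi_stop("newdata must be a numeric matrix or data.frame", "viselect_schema_error")
  }
  missing <- setdiff(object$features, colnames(X))
  extra <- setdiff(colnames(X), object$features)
  if (length(missing) || length(extra)) {
    vi_stop(sprintf("feature mismatch; missing: [%s], extra: [%s]",
                    paste(missing, collapse = ", "),
                    paste(extra, collapse = ", ")),
            "viselect_schema_error")
  }
  X[, object$features, drop = FALSE]
}

#' Feature importance of a fitted base model
#'
#' For the rule tree this is attribute usage frequency: the percentage of
#' rules in which a feature appears in a split condition or with a non-zero
#' coefficient in a region regression. For the recurrent network it is
#' permutation importance: the mean increase in RMSE over `k` seeded
#' permutations of each feature, floored at zero.
#'
#' @param model A fitted `vi_model`.
#' @param X,y Evaluation data (used by permutation importance).
#' @param seed Seed for the permutations.
#' @param k Number of permutations per feature (rnn only).
#' @return A `vi_ranking` with non-negative scores.
#' @export
model_importance <- function(model, X, y, seed = 1, k = 5) {
  UseMethod("model_importance")
}

permutation_importance <- function(model, X, y, seed, k) {
  X <- check_predict_X(model, X)
  y <- as.numeric(y)
  base <- sqrt(mean((predict(model, X) - y)^2))
  score <- vapply(seq_len(ncol(X)), function(j) {
    errs <- vapply(seq_len(k), function(r) {
      Xp <- X
      Xp[, j] <- with_seed(mix_seed(seed, j * 131L + r), sample(Xp[, j]))
      sqrt(mean((predict(model, Xp) - y)^2))
    }, numeric(1))
    max(0, mean(errs) - base)
  }, numeric(1))
  new_ranking(colnames(X), score, method = paste0(model$family, "-permutation"))
}

# ---- serialization ---------------------------------------------------------

#' Save a fitted model as JSON
#'
#' All numeric payloads are written as 17-significant-digit decimal strings
#' so a reloaded model reproduces predictions bit-exactly.
#'
#' @param model A fitted `vi_model`.
#' @param path Output path (JSON).
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  payload <- switch(model$family,
                    cubist = serialize_cubist(model),
                    rnn = serialize_rnn(model))
  obj <- list(package = "viselect",
              version = as.character(utils::packageVersion("viselect")),
              family = model$family,
              features = model$features,
              seed = model$seed,
              payload = payload)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a fitted model saved by [write_model()]
#'
#' @param path JSON path.
#' @return A fitted `vi_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  switch(obj$family,
         cubist = deserialize_cubist(obj),
         rnn = deserialize_rnn(obj),
         vi_stop(sprintf("unknown model family '%s'", obj$family), "viselect_schema_error"))
}
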