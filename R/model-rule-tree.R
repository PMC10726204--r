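# Rule-based model tree (Cubist/M5 family): recursive partitioning by
# standard-deviation reduction, an OLS model per node restricted to the
# attributes tested in its subtree, pruning by complexity-corrected error
# and optional smoothing of predictions along the root-to-leaf path.
# A dataset that admits no split reduces exactly to a single global OLS
# regression on all features.

#' Control parameters for the rule-based model tree
#'
#' @param min_split Minimum rows required to attempt a split (default 4).
#' @param min_leaf Minimum rows per child (default 2).
#' @param sd_frac Nodes whose response standard deviation falls below this
#'   fraction of the root standard deviation become leaves (default 0.05).
#' @param max_depth Depth cap (default 30).
#' @param prune Prune subtrees whose complexity-corrected error is no better
#'   than the node's own regression (default TRUE).
#' @param smooth Smooth predictions along the path with the classic
#'   `(n p_child + k p_node) / (n + k)` blend (default TRUE).
#' @param smooth_k Smoothing constant k (default 15).
#' @return A list of class `cubist_control`.
#' @export
cubist_control <- function(min_split = 4, min_leaf = 2, sd_frac = 0.05,
                           max_depth = 30, prune = TRUE, smooth = TRUE,
                           smooth_k = 15) {
  structure(list(min_split = min_split, min_leaf = min_leaf, sd_frac = sd_frac,
                 max_depth = max_depth, prune = prune, smooth = smooth,
                 smooth_k = smooth_k),
            class = "cubist_control")
}

# Population sd of a vector (denominator n): stable for tiny nodes.
pop_sd <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  sqrt(max(0, sum((x - mean(x))^2) / n))
}

# Best split of a node: maximize standard-deviation reduction. Ties resolve
# to the earliest feature (column order) and smallest threshold.
best_split <- function(X, y, idx, min_leaf) {
  n <- length(idx)
  yy <- y[idx]
  sd_node <- pop_sd(yy)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xs <- X[idx, j]
    ord <- order(xs)
    xo <- xs[ord]; yo <- yy[ord]
    # candidate cut after position i (left gets 1..i)
    cs1 <- cumsum(yo); cs2 <- cumsum(yo^2)
    tot1 <- cs1[n]; tot2 <- cs2[n]
    i <- seq_len(n - 1)
    valid <- i >= min_leaf & (n - i) >= min_leaf & xo[i] < xo[i + 1]
    if (!any(valid)) next
    i <- i[valid]
    nl <- i; nr <- n - i
    sdl <- sqrt(pmax(0, cs2[i] / nl - (cs1[i] / nl)^2))
    sdr <- sqrt(pmax(0, (tot2 - cs2[i]) / nr - ((tot1 - cs1[i]) / nr)^2))
    sdr_gain <- sd_node - (nl / n) * sdl - (nr / n) * sdr
    m <- which.max(sdr_gain)
    if (is.null(best) || sdr_gain[m] > best$gain + 1e-15) {
      best <- list(feature = j, threshold = (xo[i[m]] + xo[i[m] + 1]) / 2,
                   gain = sdr_gain[m])
    }
  }
  if (!is.null(best) && best$gain <= 1e-12) best <- NULL
  best
}

# OLS on selected columns with rank-deficiency handling; falls back to the
# node mean (with a warning) if the fit fails outright.
fit_node_ols <- function(X, y, idx, attrs) {
  yy <- y[idx]
  mean_model <- function() list(features = character(), coef = numeric(), intercept = mean(yy))
  if (length(attrs) == 0L || pop_sd(yy) == 0) return(mean_model())
  Xa <- X[idx, attrs, drop = FALSE]
  fit <- tryCatch(stats::lm.fit(cbind(`(Intercept)` = 1, Xa), yy),
                  error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$coefficients[!is.na(fit$coefficients)]))) {
    warning("rank-deficient region regression; falling back to the region mean",
            call. = FALSE)
    return(mean_model())
  }
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0  # aliased (collinear) terms contribute nothing
  list(features = attrs[cf[-1] != 0], coef = cf[-1][cf[-1] != 0],
       intercept = cf[[1]])
}

predict_node_model <- function(model, X, rows) {
  out <- rep(model$intercept, length(rows))
  for (i in seq_along(model$features)) {
    out <- out + model$coef[[i]] * X[rows, model$features[[i]]]
  }
  out
}

# Complexity-corrected mean absolute error, M5 style.
corrected_mae <- function(model, X, y, idx) {
  n <- length(idx)
  v <- length(model$coef) + 1L
  mae <- mean(abs(y[idx] - predict_node_model(model, X, idx)))
  if (n <= v) return(Inf)
  mae * (n + v) / (n - v)
}

fit_cubist <- function(X, y, spec) {
  d <- check_train_xy(X, y, min_n = 5L)
  X <- d$X; y <- d$y
  ctrl <- spec$control
  root_sd <- pop_sd(y)
  feat_names <- colnames(X)

  grow <- function(idx, depth) {
    n <- length(idx)
    can_split <- n >= ctrl$min_split && depth < ctrl$max_depth &&
      pop_sd(y[idx]) >= ctrl$sd_frac * root_sd
    sp <- if (can_split) best_split(X, y, idx, ctrl$min_leaf) else NULL
    if (is.null(sp)) {
      return(list(type = "leaf", n = n, idx = idx, attrs = character()))
    }
    fname <- feat_names[sp$feature]
    left_rows <- idx[X[idx, sp$feature] <= sp$threshold]
    right_rows <- setdiff(idx, left_rows)
    left <- grow(left_rows, depth + 1)
    right <- grow(right_rows, depth + 1)
    list(type = "split", n = n, idx = idx, feature = fname,
         threshold = sp$threshold,
         attrs = union(fname, union(left$attrs, right$attrs)),
         left = left, right = right)
  }
  root <- grow(seq_along(y), 0L)

  # node regressions: attributes tested in the subtree; an unsplit root gets
  # the full global regression
  attach_models <- function(node, is_root = FALSE) {
    attrs <- node$attrs
    if (is_root && node$type == "leaf") attrs <- feat_names
    node$model <- fit_node_ols(X, y, node$idx, attrs)
    if (node$type == "split") {
      node$left <- attach_models(node$left)
      node$right <- attach_models(node$right)
    }
    node
  }
  root <- attach_models(root, is_root = TRUE)

  prune <- function(node) {
    node_err <- corrected_mae(node$model, X, y, node$idx)
    if (node$type == "leaf") return(list(node = node, err = node_err))
    l <- prune(node$left); r <- prune(node$right)
    node$left <- l$node; node$right <- r$node
    sub_err <- (l$node$n * l$err + r$node$n * r$err) / node$n
    if (node_err <= sub_err) {
      leaf <- list(type = "leaf", n = node$n, idx = node$idx,
                   attrs = node$attrs, model = node$model)
      return(list(node = leaf, err = node_err))
    }
    list(node = node, err = sub_err)
  }
  if (ctrl$prune) root <- prune(root)$node

  strip <- function(node) {
    node$idx <- NULL
    if (node$type == "split") {
      node$left <- strip(node$left)
      node$right <- strip(node$right)
    }
    node
  }
  structure(list(family = "cubist", features = feat_names,
                 tree = strip(root), control = ctrl, seed = spec$seed),
            class = c("vi_cubist", "vi_model"))
}

#' @export
predict.vi_cubist <- function(object, newdata, ...) {
  X <- check_predict_X(object, newdata)
  k <- object$control$smooth_k
  smooth <- isTRUE(object$control$smooth)
  out <- numeric(nrow(X))
  descend <- function(node, rows) {
    if (!length(rows)) return()
    if (node$type == "leaf") {
      out[rows] <<- predict_node_model(node$model, X, rows)
      return()
    }
    left_rows <- rows[X[rows, node$feature] <= node$threshold]
    right_rows <- setdiff(rows, left_rows)
    for (side in list(list(child = node$left, rows = left_rows),
                      list(child = node$right, rows = right_rows))) {
      if (!length(side$rows)) next
      descend(side$child, side$rows)
      if (smooth) {
        pn <- predict_node_model(node$model, X, side$rows)
        out[side$rows] <<- (side$child$n * out[side$rows] + k * pn) / (side$child$n + k)
      }
    }
  }
  descend(object$tree, seq_len(nrow(X)))
  unname(out)
}

# Enumerate rules: one per leaf, with the path conditions and region model.
cubist_rules <- function(object) {
  rules <- list()
  walk <- function(node, conds) {
    if (node$type == "leaf") {
      rules[[length(rules) + 1]] <<- list(conditions = conds, model = node$model, n = node$n)
      return()
    }
    walk(node$left, c(conds, sprintf("%s <= %.6g", node$feature, node$threshold)))
    walk(node$right, c(conds, sprintf("%s > %.6g", node$feature, node$threshold)))
  }
  walk(object$tree, character())
  rules
}

#' @export
print.vi_cubist <- function(x, ...) {
  rules <- cubist_rules(x)
  cat(sprintf("Rule-based model tree: %d rule(s) over %d feature(s)\n",
              length(rules), length(x$features)))
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    cond <- if (length(r$conditions)) paste(r$conditions, collapse = " & ") else "TRUE"
    terms <- if (length(r$model$features)) {
      paste(sprintf("%+.4g*%s", r$model$coef, r$model$features), collapse = " ")
    } else ""
    cat(sprintf("  Rule %d [n=%d]: if %s then y = %.4g %s\n",
                i, r$n, cond, r$model$intercept, terms))
  }
  invisible(x)
}

#' @export
coef.vi_cubist <- function(object, ...) {
  rules <- cubist_rules(object)
  if (length(rules) == 1L) {
    m <- rules[[1]]$model
    return(c(`(Intercept)` = m$intercept, stats::setNames(as.numeric(m$coef), m$features)))
  }
  lapply(rules, function(r) c(`(Intercept)` = r$model$intercept,
                              stats::setNames(as.numeric(r$model$coef), r$model$features)))
}

#' @export
model_importance.vi_cubist <- function(model, X, y, seed = 1, k = 5) {
  rules <- cubist_rules(model)
  n_rules <- length(rules)
  usage_cond <- usage_model <- stats::setNames(numeric(length(model$features)), model$features)
  for (r in rules) {
    cond_feats <- unique(sub(" .*$", "", r$conditions))
    usage_cond[cond_feats] <- usage_cond[cond_feats] + 1
    usage_model[r$model$features] <- usage_model[r$model$features] + 1
  }
  score <- 100 * (usage_cond + usage_model) / (2 * n_rules)
  new_ranking(model$features, unname(score), method = "cubist-usage")
}

serialize_cubist <- function(model) {
  enc_node <- function(node) {
    out <- list(type = node$type, n = node$n,
                model = list(features = I(node$model$features),
                             coef = I(num_to_chr(node$model$coef)),
                             intercept = num_to_chr(node$model$intercept)))
    if (node$type == "split") {
      out$feature <- node$feature
      out$threshold <- num_to_chr(node$threshold)
      out$left <- enc_node(node$left)
      out$right <- enc_node(node$right)
    }
    out
  }
  list(control = model$control[c("min_split", "min_leaf", "sd_frac", "max_depth",
                                 "prune", "smooth", "smooth_k")],
       tree = enc_node(model$tree))
}

deserialize_cubist <- function(obj) {
  dec_node <- function(node) {
    out <- list(type = node$type, n = node$n,
                model = list(features = as.character(unlist(node$model$features)),
                             coef = chr_to_num(unlist(node$model$coef)) %||% numeric(),
                             intercept = chr_to_num(node$model$intercept)))
    if (length(out$model$coef) == 0) out$model$coef <- numeric()
    if (identical(node$type, "split")) {
      out$feature <- node$feature
      out$threshold <- chr_to_num(node$threshold)
      out$left <- dec_node(node$left)
      out$right <- dec_node(node$right)
    }
    out
  }
  ctrl <- do.call(cubist_control, obj$payload$control)
  structure(list(family = "cubist", features = as.character(obj$features),
                 tree = dec_node(obj$payload$tree), control = ctrl,
                 seed = obj$seed),
            class = c("vi_cubist", "vi_model"))
}
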