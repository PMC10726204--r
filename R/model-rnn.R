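# Recurrent-network regressor for tabular features: the d-dimensional
# feature vector is presented as a length-d sequence of scalars to a single
# tanh recurrent layer; the final hidden state feeds a linear output unit.
# Trained full-batch by backpropagation through time with Adam, gradient
# clipping and early stopping on a held-out split. Inputs and response are
# z-scored internally from the training data.

#' Control parameters for the recurrent-network regressor
#'
#' @param hidden Hidden-state size (default 32).
#' @param epochs Maximum training epochs (default 500).
#' @param lr Adam learning rate (default 0.01).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement (default 25).
#' @param val_frac Fraction of training rows held out for early stopping
#'   (default 0.15, at least one row).
#' @param clip Global gradient-norm clip (default 5).
#' @return A list of class `rnn_control`.
#' @export
rnn_control <- function(hidden = 32, epochs = 500, lr = 0.01, patience = 25,
                        val_frac = 0.15, clip = 5) {
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 lr = lr, patience = as.integer(patience),
                 val_frac = val_frac, clip = clip),
            class = "rnn_control")
}

rnn_forward <- function(par, Xs, keep_states = FALSE) {
  n <- nrow(Xs); d <- ncol(Xs); H <- length(par$b)
  h <- matrix(0, H, n)
  states <- if (keep_states) vector("list", d)
  for (t in seq_len(d)) {
    h <- tanh(par$whh %*% h + par$win %*% matrix(Xs[, t], nrow = 1) + as.vector(par$b))
    if (keep_states) states[[t]] <- h
  }
  yhat <- drop(crossprod(par$wout, h)) + par$bo
  list(yhat = yhat, states = states)
}

rnn_backward <- function(par, Xs, y, fw) {
  n <- nrow(Xs); d <- ncol(Xs); H <- length(par$b)
  g <- matrix(2 * (fw$yhat - y) / n, nrow = 1)
  hd <- fw$states[[d]]
  grads <- list(win = matrix(0, H, 1), whh = matrix(0, H, H),
                b = matrix(0, H, 1), wout = hd %*% t(g), bo = sum(g))
  dh <- par$wout %*% g
  for (t in rev(seq_len(d))) {
    A <- fw$states[[t]]
    dA <- dh * (1 - A * A)
    grads$win <- grads$win + dA %*% Xs[, t]
    grads$b <- grads$b + rowSums(dA)
    hprev <- if (t > 1) fw$states[[t - 1]] else matrix(0, H, n)
    grads$whh <- grads$whh + dA %*% t(hprev)
    dh <- crossprod(par$whh, dA)
  }
  grads
}

fit_rnn <- function(X, y, spec) {
  d0 <- check_train_xy(X, y, min_n = 10L)
  X <- d0$X; y <- d0$y
  ctrl <- spec$control
  n <- nrow(X); d <- ncol(X); H <- ctrl$hidden

  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, `/`)
  ymu <- mean(y)
  ysd <- stats::sd(y); if (ysd == 0 || !is.finite(ysd)) ysd <- 1
  ys <- (y - ymu) / ysd

  state <- with_seed(spec$seed, {
    n_val <- max(1L, round(ctrl$val_frac * n))
    val <- sample(n, n_val)
    par <- list(
      win = matrix(stats::rnorm(H, 0, 0.3), H, 1),
      whh = diag(0.9, H) + matrix(stats::rnorm(H * H, 0, 0.01), H, H),
      b = matrix(0, H, 1),
      wout = matrix(stats::rnorm(H, 0, 0.3 / sqrt(H)), H, 1),
      bo = 0
    )
    list(val = val, par = par)
  })
  val <- state$val
  par <- state$par
  tr <- setdiff(seq_len(n), val)
  Xtr <- Xs[tr, , drop = FALSE]; ytr <- ys[tr]
  Xva <- Xs[val, , drop = FALSE]; yva <- ys[val]

  m <- v <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(par = par, val_rmse = Inf, epoch = 0L)
  checkpoints <- numeric()
  wait <- 0L
  for (epoch in seq_len(ctrl$epochs)) {
    fw <- rnn_forward(par, Xtr, keep_states = TRUE)
    loss <- mean((fw$yhat - ytr)^2)
    if (!is.finite(loss)) {
      vi_stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
              "viselect_train_error")
    }
    grads <- rnn_backward(par, Xtr, ytr, fw)
    gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
    if (is.finite(gn) && gn > ctrl$clip) grads <- lapply(grads, function(g) g * ctrl$clip / gn)
    for (nm in names(par)) {
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * grads[[nm]]
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * grads[[nm]]^2
      mhat <- m[[nm]] / (1 - b1^epoch)
      vhat <- v[[nm]] / (1 - b2^epoch)
      par[[nm]] <- par[[nm]] - ctrl$lr * mhat / (sqrt(vhat) + eps)
    }
    val_rmse <- sqrt(mean((rnn_forward(par, Xva)$yhat - yva)^2))
    if (val_rmse < best$val_rmse - 1e-12) {
      best <- list(par = par, val_rmse = val_rmse, epoch = epoch)
      checkpoints <- c(checkpoints, val_rmse)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= ctrl$patience) break
    }
  }
  structure(list(family = "rnn", features = colnames(X), par = best$par,
                 center = center, scale = scale_, ymu = ymu, ysd = ysd,
                 control = ctrl, seed = spec$seed,
                 history = list(best_epoch = best$epoch,
                                val_rmse = best$val_rmse,
                                checkpoints = checkpoints,
                                epochs_run = epoch)),
            class = c("vi_rnn", "vi_model"))
}

#' @export
predict.vi_rnn <- function(object, newdata, ...) {
  X <- check_predict_X(object, newdata)
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  unname(rnn_forward(object$par, Xs)$yhat * object$ysd + object$ymu)
}

#' @export
print.vi_rnn <- function(x, ...) {
  cat(sprintf(paste0("Recurrent-network regressor: %d features as a length-%d",
                     " scalar sequence, hidden size %d\n"),
              length(x$features), length(x$features), x$control$hidden))
  cat(sprintf("  best epoch %d/%d, validation RMSE (standardized) %.4f\n",
              x$history$best_epoch, x$history$epochs_run, x$history$val_rmse))
  invisible(x)
}

#' @export
model_importance.vi_rnn <- function(model, X, y, seed = 1, k = 5) {
  permutation_importance(model, X, y, seed = seed, k = k)
}

serialize_rnn <- function(model) {
  list(control = unclass(model$control),
       hidden = model$control$hidden,
       par = lapply(model$par, function(p) list(dim = dim(p) %||% integer(),
                                                data = I(num_to_chr(as.numeric(p))))),
       center = I(num_to_chr(model$center)),
       scale = I(num_to_chr(model$scale)),
       ymu = num_to_chr(model$ymu),
       ysd = num_to_chr(model$ysd))
}

deserialize_rnn <- function(obj) {
  p <- obj$payload
  par <- lapply(p$par, function(w) {
    x <- chr_to_num(unlist(w$data))
    dm <- unlist(w$dim)
    if (length(dm) == 2) matrix(x, dm[1], dm[2]) else x
  })
  feats <- as.character(obj$features)
  ctrl <- do.call(rnn_control, p$control[c("hidden", "epochs", "lr", "patience",
                                           "val_frac", "clip")])
  structure(list(family = "rnn", features = feats, par = par,
                 center = stats::setNames(chr_to_num(unlist(p$center)), feats),
                 scale = stats::setNames(chr_to_num(unlist(p$scale)), feats),
                 ymu = chr_to_num(p$ymu), ysd = chr_to_num(p$ysd),
                 control = ctrl, seed = obj$seed,
                 history = list()),
            class = c("vi_rnn", "vi_model"))
}
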