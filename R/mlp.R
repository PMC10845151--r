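## Multitask feed-forward network: shared two-hidden-layer trunk (tanh) and
## one linear head per target, trained with full-batch Adam on a summed MSE
## with equal loss weights, early stopping on a validation split. Pure R
## matrix arithmetic, so training is deterministic for a given seed.

.mlpInit <- function(d, h, n_out, seed) {
  .withSeed(seed, {
    g <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0,
                                                 sqrt(2 / (nin + nout))),
                                    nin, nout)
    list(W1 = g(d, h), b1 = numeric(h),
         W2 = g(h, h), b2 = numeric(h),
         W3 = g(h, n_out), b3 = numeric(n_out))
  })
}

.mlpForward <- function(p, X) {
  A1 <- tanh(sweep(X %*% p$W1, 2, p$b1, "+"))
  A2 <- tanh(sweep(A1 %*% p$W2, 2, p$b2, "+"))
  Y <- sweep(A2 %*% p$W3, 2, p$b3, "+")
  list(A1 = A1, A2 = A2, Y = Y)
}

.mlpGrad <- function(p, X, Y) {
  fw <- .mlpForward(p, X)
  n <- nrow(X)
  dY <- 2 * (fw$Y - Y) / (n * ncol(Y))          # d(mean sq err)/dY
  dW3 <- crossprod(fw$A2, dY); db3 <- colSums(dY)
  dA2 <- tcrossprod(dY, p$W3) * (1 - fw$A2^2)
  dW2 <- crossprod(fw$A1, dA2); db2 <- colSums(dA2)
  dA1 <- (dA2 %*% t(p$W2)) * (1 - fw$A1^2)
  dW1 <- crossprod(X, dA1); db1 <- colSums(dA1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3,
       loss = mean((fw$Y - Y)^2))
}

#' Fit the multitask MLP
#'
#' @param X training matrix; `y` numeric vector or matrix (one column per
#'   task; the barrier-height correction must be column 1).
#' @param hidden trunk width (default 128).
#' @param epochs maximum Adam steps (full batch).
#' @param lr Adam learning rate.
#' @param val_frac fraction of rows held out internally for early stopping
#'   when no validation set is supplied.
#' @param Xval,yval optional explicit validation data.
#' @param patience early-stopping patience in epochs.
#' @param seed RNG seed for initialization and the internal split.
#' @return Fitted state list.
#' @keywords internal
mlpFit <- function(X, y, hidden = 128L, epochs = 2000L, lr = 5e-3,
                   val_frac = 0.1, Xval = NULL, yval = NULL,
                   patience = 100L, seed = 1L) {
  X <- as.matrix(X)
  Y <- as.matrix(y)
  mu_x <- colMeans(X); sd_x <- apply(X, 2, stats::sd); sd_x[sd_x == 0] <- 1
  mu_y <- colMeans(Y); sd_y <- apply(Y, 2, stats::sd)
  if (any(!is.finite(sd_y)) || any(sd_y == 0))
    stop("degenerate target: zero variance", call. = FALSE)
  Xs <- sweep(sweep(X, 2, mu_x), 2, sd_x, "/")
  Ys <- sweep(sweep(Y, 2, mu_y), 2, sd_y, "/")

  if (is.null(Xval)) {
    n <- nrow(Xs)
    vi <- .withSeed(.childSeed(seed, 7L),
                    sample.int(n, max(1L, round(val_frac * n))))
    Xv <- Xs[vi, , drop = FALSE]; Yv <- Ys[vi, , drop = FALSE]
    Xt <- Xs[-vi, , drop = FALSE]; Yt <- Ys[-vi, , drop = FALSE]
  } else {
    Xv <- sweep(sweep(as.matrix(Xval), 2, mu_x), 2, sd_x, "/")
    Yv <- sweep(sweep(as.matrix(yval), 2, mu_y), 2, sd_y, "/")
    Xt <- Xs; Yt <- Ys
  }

  p <- .mlpInit(ncol(Xs), hidden, ncol(Ys), seed)
  m <- lapply(p, function(w) w * 0)
  v <- lapply(p, function(w) w * 0)
  b1c <- 0.9; b2c <- 0.999; epsa <- 1e-8
  best <- Inf; best_p <- p; wait <- 0L
  for (t in seq_len(epochs)) {
    gr <- .mlpGrad(p, Xt, Yt)
    for (nm in names(p)) {
      m[[nm]] <- b1c * m[[nm]] + (1 - b1c) * gr[[nm]]
      v[[nm]] <- b2c * v[[nm]] + (1 - b2c) * gr[[nm]]^2
      mhat <- m[[nm]] / (1 - b1c^t)
      vhat <- v[[nm]] / (1 - b2c^t)
      p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + epsa)
    }
    if (t %% 10L == 0L) {
      vloss <- mean((.mlpForward(p, Xv)$Y - Yv)^2)
      if (vloss < best - 1e-7) { best <- vloss; best_p <- p; wait <- 0L }
      else { wait <- wait + 10L; if (wait >= patience) break }
    }
  }
  list(params = best_p, mu_x = mu_x, sd_x = sd_x, mu_y = mu_y, sd_y = sd_y,
       n_out = ncol(Ys), val_loss = best)
}

#' Predict the primary task from a fitted MLP
#' @keywords internal
mlpPredict <- function(fit, Xnew, task = 1L) {
  Xs <- sweep(sweep(as.matrix(Xnew), 2, fit$mu_x), 2, fit$sd_x, "/")
  Ys <- .mlpForward(fit$params, Xs)$Y
  Ys[, task] * fit$sd_y[task] + fit$mu_y[task]
}
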