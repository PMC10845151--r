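## Exact Gaussian-process regression with a Matern-5/2 kernel and a noise
## term. Inputs are standardized and the target centered/scaled internally;
## hyperparameters (signal variance, a single shared lengthscale, noise
## variance) are set by L-BFGS-B maximization of the log marginal likelihood.
## For large training sets the hyperparameters are optimized on a seeded
## subsample (exact GP cost is cubic) and the final posterior uses all points.

.matern52 <- function(D, ell, sf2) {
  r <- sqrt(5) * D / ell
  sf2 * (1 + r + r^2 / 3) * exp(-r)
}

## Pairwise Euclidean distances between rows of A and B.
.crossDist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

.gpNegLogLik <- function(logtheta, D, y) {
  sf2 <- exp(logtheta[1]); ell <- exp(logtheta[2]); sn2 <- exp(logtheta[3])
  n <- length(y)
  K <- .matern52(D, ell, sf2) + diag(sn2 + 1e-10, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  as.numeric(0.5 * crossprod(y, alpha) + sum(log(diag(ch))) +
               0.5 * n * log(2 * pi))
}

#' Fit an exact Gaussian process regressor
#'
#' @param X numeric training matrix (rows = cases).
#' @param y numeric target vector, kcal/mol.
#' @param hyper_subsample maximum number of points used during
#'   marginal-likelihood optimization (default 400); the final posterior uses
#'   all rows of `X`.
#' @param seed integer seed for the subsample draw.
#' @return A list with the fitted state (standardization, hyperparameters,
#'   Cholesky factor, weights).
#' @keywords internal
gpFit <- function(X, y, hyper_subsample = 400L, seed = 1L) {
  X <- as.matrix(X)
  mu_x <- colMeans(X)
  sd_x <- apply(X, 2, stats::sd)
  sd_x[sd_x == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu_x), 2, sd_x, "/")
  mu_y <- mean(y); sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0)
    stop("degenerate target: zero variance", call. = FALSE)
  ys <- (y - mu_y) / sd_y

  n <- nrow(Xs)
  idx <- if (n > hyper_subsample) {
    .withSeed(seed, sort(sample.int(n, hyper_subsample)))
  } else seq_len(n)
  Dsub <- .crossDist(Xs[idx, , drop = FALSE], Xs[idx, , drop = FALSE])
  med <- stats::median(Dsub[upper.tri(Dsub)])
  if (!is.finite(med) || med <= 0) med <- 1
  start <- log(c(1, med, 0.1))
  opt <- stats::optim(start, .gpNegLogLik, D = Dsub, y = ys[idx],
                      method = "L-BFGS-B",
                      lower = log(c(1e-3, med * 1e-2, 1e-6)),
                      upper = log(c(1e3, med * 1e2, 1e2)),
                      control = list(maxit = 80))
  sf2 <- exp(opt$par[1]); ell <- exp(opt$par[2]); sn2 <- exp(opt$par[3])

  D <- .crossDist(Xs, Xs)
  K <- .matern52(D, ell, sf2) + diag(sn2 + 1e-10, n)
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  list(mu_x = mu_x, sd_x = sd_x, mu_y = mu_y, sd_y = sd_y,
       sf2 = sf2, ell = ell, sn2 = sn2, Xs = Xs, chol = ch, alpha = alpha,
       nll = opt$value)
}

#' Predict from a fitted GP
#'
#' @param fit result of \code{gpFit}.
#' @param Xnew numeric matrix of query points.
#' @return A list with `mean` and `sd` (predictive standard deviation of a
#'   new observation, i.e. including the noise term), both on the original
#'   target scale.
#' @keywords internal
gpPredict <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  Xs <- sweep(sweep(Xnew, 2, fit$mu_x), 2, fit$sd_x, "/")
  Kx <- .matern52(.crossDist(Xs, fit$Xs), fit$ell, fit$sf2)
  mean_s <- as.numeric(Kx %*% fit$alpha)
  V <- forwardsolve(t(fit$chol), t(Kx))
  var_s <- pmax(fit$sf2 - colSums(V^2), 0) + fit$sn2
  list(mean = mean_s * fit$sd_y + fit$mu_y,
       sd = sqrt(var_s) * fit$sd_y)
}
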