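## The three correction-model heads, data splitting, evaluation, learning
## curves and SHAP attributions.

#' Seeded train/validation/test split
#'
#' Disjoint and exhaustive index sets with sizes within one unit of
#' `fractions * n`. The default fractions are 85/5/10.
#'
#' @param n number of cases (>= 20).
#' @param fractions numeric(3) summing to 1: train, validation, test.
#' @param seed integer RNG seed.
#' @return List with integer vectors `train`, `val`, `test`.
#' @export
splitData <- function(n, fractions = c(0.85, 0.05, 0.10), seed = 1L) {
  stopifnot(n >= 20L, length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-8)
  perm <- .withSeed(seed, sample.int(n))
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  if (n_train + n_val >= n) n_train <- n - n_val - 1L
  list(train = perm[seq_len(n_train)],
       val = perm[n_train + seq_len(n_val)],
       test = perm[(n_train + n_val + 1L):n])
}

.xgbGrid <- function() expand.grid(eta = c(0.05, 0.1), max_depth = c(4L, 6L),
                                   KEEP.OUT.ATTRS = FALSE)

.trainXGB <- function(X, y, Xval, yval, hpo_budget, cv_folds, seed, nrounds_max) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  grid <- .xgbGrid()
  if (hpo_budget > 0L && nrow(grid) > 1L) {
    grid <- grid[seq_len(min(nrow(grid), hpo_budget)), , drop = FALSE]
    folds <- .withSeed(.childSeed(seed, 3L), {
      idx <- sample.int(nrow(X))
      split(idx, rep_len(seq_len(cv_folds), nrow(X)))
    })
    scores <- vapply(seq_len(nrow(grid)), function(g) {
      cv <- xgboost::xgb.cv(
        params = list(objective = "reg:squarederror", eta = grid$eta[g],
                      max_depth = grid$max_depth[g], nthread = 1,
                      eval_metric = "mae", seed = seed),
        data = dtrain, nrounds = nrounds_max, folds = folds,
        early_stopping_rounds = 40L, verbose = 0)
      min(cv$evaluation_log$test_mae_mean)
    }, numeric(1))
    best <- which.min(scores)
  } else best <- nrow(grid)  # eta 0.1, depth 6 default
  params <- list(objective = "reg:squarederror", eta = grid$eta[best],
                 max_depth = grid$max_depth[best], nthread = 1,
                 eval_metric = "mae", seed = seed)
  if (!is.null(Xval)) {
    dval <- xgboost::xgb.DMatrix(as.matrix(Xval), label = yval, nthread = 1)
    booster <- xgboost::xgb.train(params, dtrain, nrounds = nrounds_max,
                                  evals = list(val = dval),
                                  early_stopping_rounds = 60L, verbose = 0)
  } else {
    booster <- xgboost::xgb.train(params, dtrain, nrounds = nrounds_max,
                                  verbose = 0)
  }
  list(booster = booster, params = params)
}

#' Train a barrier-height correction model
#'
#' Fits one of the three heads to predict Delta = BH_DFT - BH_PM7 (kcal/mol):
#' \describe{
#'   \item{xgb}{gradient-boosted trees; a small eta x depth grid is scored by
#'     k-fold cross-validated MAE (capped at `hpo_budget` configurations),
#'     boosting rounds chosen by early stopping.}
#'   \item{gp}{exact Gaussian process, Matern-5/2 kernel plus noise,
#'     standardized inputs, hyperparameters by marginal-likelihood
#'     maximization; also yields a predictive standard deviation.}
#'   \item{multitask_nn}{shared two-hidden-layer trunk with two linear heads
#'     (the correction and the reaction energy), equal loss weights, Adam,
#'     early stopping on the validation split.}
#' }
#'
#' @param kind "xgb", "gp" or "multitask_nn".
#' @param X numeric feature matrix with column names.
#' @param y target vector (kcal/mol); for "multitask_nn" a two-column matrix
#'   `(Delta BH, Delta E_r)`.
#' @param Xval,yval optional validation data for early stopping.
#' @param hpo_budget maximum hyperparameter configurations tried (xgb).
#' @param cv_folds folds for the xgb grid search (default 5).
#' @param seed integer seed; given the seed, xgb and gp fits are bit-stable.
#' @param nrounds_max maximum boosting rounds (xgb).
#' @param hidden trunk width of the neural network head.
#' @return A \linkS4class{CorrectionModel}.
#' @export
trainModel <- function(kind = c("xgb", "gp", "multitask_nn"), X, y,
                       Xval = NULL, yval = NULL, hpo_budget = 4L,
                       cv_folds = 5L, seed = 1L, nrounds_max = 2000L,
                       hidden = 128L) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have column names", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(as.matrix(y))))
    stop("non-finite values in X or y", call. = FALSE)
  y1 <- if (is.matrix(y)) y[, 1] else y
  if (stats::sd(y1) == 0) stop("degenerate target: zero variance", call. = FALSE)
  fit <- switch(kind,
    xgb = .trainXGB(X, y1, Xval, if (is.null(yval)) NULL else
                    (if (is.matrix(yval)) yval[, 1] else yval),
                    hpo_budget, cv_folds, seed, nrounds_max),
    gp = gpFit(X, y1, seed = seed),
    multitask_nn = {
      Y <- if (is.matrix(y)) y else cbind(y)
      mlpFit(X, Y, hidden = hidden, Xval = Xval,
             yval = if (is.null(yval)) NULL else
               (if (is.matrix(yval)) yval else cbind(yval)),
             seed = seed)
    })
  new("CorrectionModel", kind = kind, featureNames = colnames(X), fit = fit)
}

.checkFeatures <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) ||
      !identical(colnames(X), model@featureNames))
    stop("feature-name mismatch: prediction requires exactly the training ",
         "features, in order", call. = FALSE)
  X
}

#' Predict the correction Delta for new reactions
#'
#' @param model a fitted \linkS4class{CorrectionModel}.
#' @param X feature matrix with exactly the training columns, in order.
#' @param se also return the predictive standard deviation (gp only).
#' @return Numeric vector of predicted corrections (kcal/mol), or a list
#'   `(mean, sd)` when `se = TRUE`.
#' @export
predictCorrection <- function(model, X, se = FALSE) {
  X <- .checkFeatures(model, X)
  if (se && modelKind(model) != "gp")
    stop("predictive standard deviations are available for the gp head only",
         call. = FALSE)
  switch(modelKind(model),
    xgb = {
      p <- stats::predict(model@fit$booster,
                          xgboost::xgb.DMatrix(X, nthread = 1))
      as.numeric(p)
    },
    gp = {
      pr <- gpPredict(model@fit, X)
      if (se) pr else pr$mean
    },
    multitask_nn = as.numeric(mlpPredict(model@fit, X)))
}

#' Corrected barrier heights
#'
#' `BH_PM7 + predicted Delta`: the low-level barrier promoted toward the
#' reference level.
#'
#' @param model a fitted \linkS4class{CorrectionModel}.
#' @param X feature matrix (training columns, in order).
#' @param bh_pm7 vector of low-level barrier heights, kcal/mol; length must
#'   equal `nrow(X)`.
#' @return Numeric vector, kcal/mol.
#' @export
correctedBH <- function(model, X, bh_pm7) {
  X <- .checkFeatures(model, X)
  if (length(bh_pm7) != nrow(X))
    stop("bh_pm7 length must equal nrow(X)", call. = FALSE)
  bh_pm7 + predictCorrection(model, X)
}

#' Evaluate a model on a test set
#'
#' @param model fitted \linkS4class{CorrectionModel}.
#' @param X test features; `y` true corrections (kcal/mol).
#' @param breaks histogram break count for the signed-error summary.
#' @return List with `mae` (kcal/mol), `errors` (signed, predicted - true),
#'   `histogram` (counts summing to the test size) and `predictions`.
#' @export
evaluateModel <- function(model, X, y, breaks = 20L) {
  pred <- predictCorrection(model, X)
  err <- pred - y
  h <- graphics::hist(err, breaks = breaks, plot = FALSE)
  list(mae = mean(abs(err)), errors = err,
       histogram = list(breaks = h$breaks, counts = h$counts),
       predictions = pred)
}

#' Learning curve
#'
#' For each training-pool subsample size, draws `reps` seeded subsamples,
#' retrains, and evaluates MAE on the fixed test set.
#'
#' @param kind model kind passed to \code{\link{trainModel}}.
#' @param X,y training pool.
#' @param Xtest,ytest fixed test set.
#' @param sizes training sizes (each <= nrow(X)).
#' @param reps repeats per size.
#' @param seed master seed.
#' @param ... further arguments to \code{\link{trainModel}}.
#' @return data.frame with `n_train`, `mae_mean`, `mae_sd`.
#' @export
learningCurve <- function(kind, X, y, Xtest, ytest,
                          sizes = c(100L, 400L, 1600L), reps = 3L, seed = 1L,
                          ...) {
  stopifnot(all(sizes <= nrow(X)))
  rows <- lapply(seq_along(sizes), function(si) {
    maes <- vapply(seq_len(reps), function(r) {
      s <- .childSeed(seed, si * 100L + r)
      idx <- .withSeed(s, sample.int(nrow(X), sizes[si]))
      m <- trainModel(kind, X[idx, , drop = FALSE],
                      if (is.matrix(y)) y[idx, , drop = FALSE] else y[idx],
                      seed = s, ...)
      evaluateModel(m, Xtest, ytest)$mae
    }, numeric(1))
    data.frame(n_train = sizes[si], mae_mean = mean(maes),
               mae_sd = if (reps > 1L) stats::sd(maes) else 0)
  })
  do.call(rbind, rows)
}

#' SHAP attributions
#'
#' For the tree head, exact path-dependent TreeSHAP values: per-record
#' attributions plus a bias column that together sum to the prediction, so
#' attribution sums equal prediction minus expected model output. For the
#' other heads, a sampling-based Shapley approximation (Monte-Carlo
#' permutation estimator) is used.
#'
#' @param model fitted \linkS4class{CorrectionModel}.
#' @param X feature matrix to explain.
#' @param nsim Monte-Carlo samples per feature for the non-tree fallback.
#' @param seed seed for the fallback sampler.
#' @return List with `attributions` (n x p matrix), `expected_value`
#'   (model base value) and `ranking` (features by decreasing mean absolute
#'   attribution).
#' @export
explainModel <- function(model, X, nsim = 50L, seed = 1L) {
  X <- .checkFeatures(model, X)
  if (modelKind(model) == "xgb") {
    contrib <- stats::predict(model@fit$booster,
                              xgboost::xgb.DMatrix(X, nthread = 1),
                              predcontrib = TRUE)
    bias_col <- ncol(contrib)   # named "(Intercept)": the expected output
    attributions <- contrib[, -bias_col, drop = FALSE]
    expected <- unname(contrib[1, bias_col])
  } else {
    expected <- mean(predictCorrection(model, X))
    attributions <- .samplingShap(model, X, nsim, seed)
  }
  ranking <- names(sort(colMeans(abs(attributions)), decreasing = TRUE))
  list(attributions = attributions, expected_value = expected,
       ranking = ranking)
}

## Monte-Carlo permutation Shapley estimator with the explained matrix as the
## background distribution.
.samplingShap <- function(model, X, nsim, seed) {
  n <- nrow(X); p <- ncol(X)
  phi <- matrix(0, n, p, dimnames = list(NULL, colnames(X)))
  .withSeed(seed, {
    for (s in seq_len(nsim)) {
      perm <- sample.int(p)
      bg <- X[sample.int(n, n, replace = TRUE), , drop = FALSE]
      cur <- bg
      prev_pred <- predictCorrection(model, .named(cur, colnames(X)))
      for (j in perm) {
        cur[, j] <- X[, j]
        new_pred <- predictCorrection(model, .named(cur, colnames(X)))
        phi[, j] <- phi[, j] + (new_pred - prev_pred)
        prev_pred <- new_pred
      }
    }
  })
  phi / nsim
}

.named <- function(m, nms) { colnames(m) <- nms; m }
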