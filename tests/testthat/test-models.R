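linearToy <- function(n, p = 6, sd_noise = 0, seed = 101) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("pm7.x", 1:p)))
  y <- 2 * X[, 1] - 1.5 * X[, 2] + 0.8 * X[, 3] + rnorm(n, 0, sd_noise)
  list(X = X, y = y)
}

test_that("splitData is seeded, disjoint and exhaustive with 85/5/10 sizes", {
  s <- splitData(1000L, seed = 5L)
  expect_equal(lengths(s), c(train = 850L, val = 50L, test = 100L))
  all_idx <- sort(c(s$train, s$val, s$test))
  expect_equal(all_idx, 1:1000)
  s2 <- splitData(1000L, seed = 5L)
  expect_identical(s, s2)
  expect_false(identical(splitData(1000L, seed = 6L)$train, s$train))
  # near-integer boundaries stay exhaustive
  s3 <- splitData(23L, seed = 1L)
  expect_equal(sort(unlist(s3)), 1:23, ignore_attr = TRUE)
})

test_that("all heads learn an exact linear signal", {
  toy <- linearToy(500)
  tr <- 1:400; te <- 401:500
  m_gp <- trainModel("gp", toy$X[tr, ], toy$y[tr], seed = 2L)
  expect_lt(evaluateModel(m_gp, toy$X[te, ], toy$y[te])$mae, 0.1)

  m_nn <- trainModel("multitask_nn", toy$X[tr, ],
                     cbind(toy$y[tr], 0.5 * toy$y[tr] + 1), seed = 2L)
  expect_lt(evaluateModel(m_nn, toy$X[te, ], toy$y[te])$mae, 0.1)

  # trees approximate smooth linear maps more slowly; bounded, not exact
  m_xgb <- trainModel("xgb", toy$X[tr, ], toy$y[tr], hpo_budget = 0L,
                      seed = 2L, nrounds_max = 1500L)
  expect_lt(evaluateModel(m_xgb, toy$X[te, ], toy$y[te])$mae, 0.5)
})

test_that("pure-noise targets floor at sigma * sqrt(2/pi)", {
  set.seed(55)
  n <- 600; sigma <- 1
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("pm7.n", 1:5)))
  y <- rnorm(n, 0, sigma)
  tr <- 1:500; te <- 501:600
  floor_mae <- sigma * sqrt(2 / pi)
  for (kind in c("xgb", "gp")) {
    m <- trainModel(kind, X[tr, ], y[tr], hpo_budget = 0L, seed = 3L,
                    nrounds_max = 200L)
    mae <- evaluateModel(m, X[te, ], y[te])$mae
    expect_lt(abs(mae - floor_mae) / floor_mae, 0.15)
  }
})

test_that("degenerate and malformed inputs are rejected", {
  toy <- linearToy(50)
  expect_error(trainModel("gp", toy$X, rep(1, 50)), "degenerate")
  expect_error(trainModel("xgb", unname(toy$X), toy$y), "column names")
  Xb <- toy$X; Xb[1, 1] <- NA
  expect_error(trainModel("gp", Xb, toy$y), "non-finite")
})

test_that("prediction enforces the training feature contract", {
  toy <- linearToy(100)
  m <- trainModel("gp", toy$X, toy$y, seed = 1L)
  Xw <- toy$X[, c(2, 1, 3:6)]
  expect_error(predictCorrection(m, Xw), "feature-name mismatch")
  expect_error(correctedBH(m, toy$X, rep(0, 5)), "length")
  # corrected BH = bh_pm7 + predicted delta
  bh <- runif(100, 10, 50)
  expect_equal(correctedBH(m, toy$X, bh),
               bh + predictCorrection(m, toy$X))
})

test_that("GP predictive uncertainty grows away from the training data", {
  toy <- linearToy(300, p = 3)
  m <- trainModel("gp", toy$X, toy$y, seed = 9L)
  pr_train <- predictCorrection(m, toy$X[1:50, ], se = TRUE)
  far <- matrix(8, 50, 3, dimnames = list(NULL, colnames(toy$X)))
  pr_far <- predictCorrection(m, far, se = TRUE)
  expect_lt(mean(pr_train$sd), mean(pr_far$sd) / 3)
})

test_that("GP agrees with an independent GP implementation on a smooth task", {
  skip_if_not_installed("kernlab")
  set.seed(77)
  X <- matrix(runif(120, -2, 2), ncol = 2,
              dimnames = list(NULL, c("pm7.a", "pm7.b")))
  y <- sin(X[, 1]) + 0.5 * cos(2 * X[, 2]) + rnorm(60, 0, 0.05)
  Xte <- matrix(runif(60, -2, 2), ncol = 2,
                dimnames = list(NULL, c("pm7.a", "pm7.b")))
  m <- trainModel("gp", X, y, seed = 1L)
  ours <- predictCorrection(m, Xte)
  ref <- kernlab::gausspr(x = X, y = y, kernel = "rbfdot", variance.model = FALSE)
  theirs <- as.numeric(kernlab::predict(ref, Xte))
  # two different kernels/optimizers on an easy smooth function: close fits
  expect_lt(mean(abs(ours - theirs)), 0.25)
})

test_that("learning curves are deterministic and decrease with signal", {
  toy <- linearToy(1100, sd_noise = 0.3)
  tr <- 1:1000; te <- 1001:1100
  tab <- learningCurve("xgb", toy$X[tr, ], toy$y[tr], toy$X[te, ],
                       toy$y[te], sizes = c(60L, 250L, 1000L), reps = 2L,
                       seed = 11L, hpo_budget = 0L, nrounds_max = 300L)
  expect_equal(tab$n_train, c(60, 250, 1000))
  expect_true(all(diff(tab$mae_mean) <= tab$mae_sd[-nrow(tab)] + 1e-12))
  tab2 <- learningCurve("xgb", toy$X[tr, ], toy$y[tr], toy$X[te, ],
                        toy$y[te], sizes = c(60L, 250L, 1000L), reps = 2L,
                        seed = 11L, hpo_budget = 0L, nrounds_max = 300L)
  expect_identical(tab, tab2)
})

test_that("tree SHAP attributions are exactly additive and find the driver", {
  set.seed(23)
  n <- 400
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("pm7.s", 1:6)))
  # target of O(1) scale: TreeSHAP accumulates in single precision, so the
  # absolute additivity bound is exercised where it is meaningful
  y <- 0.5 * X[, 3] + 0.03 * X[, 1] + rnorm(n, 0, 0.01)
  m <- trainModel("xgb", X, y, hpo_budget = 0L, seed = 5L,
                  nrounds_max = 80L)
  ex <- explainModel(m, X)
  pred <- predictCorrection(m, X)
  sums <- rowSums(ex$attributions) + ex$expected_value
  expect_lt(max(abs(sums - pred)), 1e-6)
  expect_equal(ex$ranking[1], "pm7.s3")
  # a feature the model never saw as signal attributes ~ nothing
  expect_lt(mean(abs(ex$attributions[, "pm7.s6"])),
            0.05 * mean(abs(ex$attributions[, "pm7.s3"])))
})

test_that("sampling attributions recover a linear single-feature model", {
  set.seed(31)
  n <- 150
  X <- cbind("pm7.z" = rnorm(n))
  y <- 3 * X[, 1]
  m <- trainModel("gp", X, y, seed = 2L)
  ex <- explainModel(m, X, nsim = 80L, seed = 3L)
  # closed form for a linear model: phi = slope * (x - E[x]); the sampling
  # estimator converges at sqrt(nsim), so the check is statistical
  expected <- 3 * (X[, 1] - mean(X[, 1]))
  expect_gt(cor(ex$attributions[, 1], expected), 0.95)
  expect_lt(mean(abs(ex$attributions[, 1] - expected)),
            0.2 * stats::sd(expected))
})
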