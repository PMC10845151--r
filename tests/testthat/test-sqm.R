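mkSpecies <- function(energy, zpe, freqs = c(1000, 2000), homo = -10,
                      lumo = -1, B = diag(2), pol = 1,
                      geom = Geometry(c("C", "O"),
                                      rbind(c(0, 0, 0), c(0, 0, 1.2)))) {
  SQMSpecies(energy, zpe, freqs, homo, lumo, B, pol, geom)
}

test_that("barrierHeight follows the ZPE-inclusive definition", {
  r <- mkSpecies(0, 10)
  ts <- mkSpecies(30, 8, freqs = c(-500, 1500))
  expect_equal(barrierHeight(r, ts), 28.0)
  expect_equal(barrierHeight(r, r), 0)
  ts_low <- mkSpecies(-5, 8, freqs = c(-500, 1500))
  expect_warning(bh <- barrierHeight(r, ts_low), "negative")
  expect_lt(bh, 0)
})

test_that("rateProxy is the bare exponential, overflow-safe and monotone", {
  expect_equal(rateProxy(0), 1.0)
  expect_equal(rateProxy(1), exp(-1))
  expect_equal(rateProxy(1), 0.367879, tolerance = 1e-5)
  bhs <- seq(-100, 80, length.out = 50)
  expect_true(all(diff(rateProxy(bhs)) <= 0))
  expect_true(is.finite(rateProxy(-1000)))
})

test_that("koopmans reproduces direct substitution", {
  expect_equal(koopmans(-9, 1), c(eta = 5, alpha = 4))
  expect_equal(unname(koopmans(-3, 3)["alpha"]), 0)
  expect_equal(koopmans(-10.5, -0.5), c(eta = 5.0, alpha = 5.5))
  set.seed(31)
  for (rep in 1:100) {
    h <- rnorm(1, -10, 3); l <- h + abs(rnorm(1, 4, 2))
    k <- koopmans(h, l)
    expect_identical(unname(k["eta"]), (l - h) / 2)
    expect_identical(unname(k["alpha"]), -(l + h) / 2)
  }
})

test_that("bondOrderEigenvalues pads, sorts and matches a dense solver", {
  expect_equal(bondOrderEigenvalues(diag(c(1, 1)), k = 3), c(1, 1, 0))
  set.seed(13)
  M <- matrix(rnorm(25), 5, 5); M <- (M + t(M)) / 2
  perm <- sample(5)
  expect_equal(bondOrderEigenvalues(M[perm, perm], k = 5),
               bondOrderEigenvalues(M, k = 5), tolerance = 1e-10)
  expect_equal(bondOrderEigenvalues(M, k = 5),
               sort(eigen(M, symmetric = TRUE)$values, decreasing = TRUE),
               tolerance = 1e-12)
  expect_equal(length(bondOrderEigenvalues(M, k = 8)), 8)
  expect_error(bondOrderEigenvalues(matrix(1:4, 2, 2)), "symmetric")
})

test_that("sqmFeatures assembles hand-computable values and rejects bad TSs", {
  geom <- h2coGeometry()
  r <- SQMSpecies(0, 10, c(1000, 2000), -10, -2, diag(4), 2.0, geom)
  ts <- SQMSpecies(30, 8, c(-750, 1500), -9, -1, diag(4) * 0.5, 2.5, geom)
  p <- SQMSpecies(-4, 9, c(1100, 2100), -10.5, -1.5, diag(4), 1.8, geom)
  rec <- ReactionRecord("x", r, ts, p, bhDft = 33, "C=O", "[H][H].[C-]#[O+]")

  f <- sqmFeatures(rec, k_bond_eigs = 5)
  expect_equal(unname(f["pm7.bh_pm7"]), 28)
  expect_equal(unname(f["pm7.rate_proxy"]), exp(-28))
  expect_equal(unname(f["pm7.nu1_ts"]), 750)
  expect_equal(unname(f["pm7.dzpe_ts_r"]), -2)
  expect_equal(unname(f["pm7.dzpe_p_r"]), -1)
  expect_equal(unname(f["pm7.dzpe_ts_p"]), -1)
  expect_equal(unname(f["pm7.eta_ts"]), 4)
  expect_equal(unname(f["pm7.alpha_ts"]), 5)
  expect_equal(unname(f["pm7.dpol"]), 0.2, tolerance = 1e-12)
  expect_equal(unname(f["pm7.de_r"]), -4)
  expect_equal(unname(f["pm7.bo_eig1"]), 0.5)

  # target identity: target + bh_pm7 = bh_dft to machine precision
  expect_equal(reactionTarget(rec) + 28, 33, tolerance = 1e-14)

  # zero or multiple imaginary frequencies rejected (construction + assembly)
  expect_error(ReactionRecord("y", r, p, p, 33, "C", "C"), "imaginary")
  ts2 <- SQMSpecies(30, 8, c(-750, -100, 1500), -9, -1, diag(4), 2.5, geom)
  expect_error(ReactionRecord("z", r, ts2, p, 33, "C", "C"), "imaginary")
})

test_that("sqm features are invariant under atom reindexing of the species", {
  set.seed(17)
  geom <- methaneGeometry()
  B <- matrix(rnorm(25), 5, 5); B <- (B + t(B)) / 2
  perm <- sample(5)
  geom_p <- Geometry(atomSymbols(geom)[perm], atomCoords(geom)[perm, ])
  r <- SQMSpecies(0, 10, c(1000, 2000), -10, -2, B, 2.0, geom)
  ts <- SQMSpecies(20, 9, c(-300, 1500), -9, -1, B, 2.1, geom)
  ts_p <- SQMSpecies(20, 9, c(-300, 1500), -9, -1, B[perm, perm], 2.1, geom_p)
  p <- SQMSpecies(5, 10, c(900, 1900), -10, -2, B, 2.0, geom)
  rec1 <- ReactionRecord("a", r, ts, p, 25, "C", "C")
  rec2 <- ReactionRecord("b", r, ts_p, p, 25, "C", "C")
  expect_equal(unname(sqmFeatures(rec1)), unname(sqmFeatures(rec2)),
               tolerance = 1e-10)
})

test_that("record JSON files round-trip", {
  cfg <- generatorConfig(n_reactions = 3L, seed = 5L)
  ds <- genDataset(cfg)
  path <- tempfile(fileext = ".json")
  writeRecords(ds$records, path)
  back <- readRecords(path)
  expect_equal(length(back), 3)
  for (i in 1:3) {
    expect_equal(back[[i]]@bhDft, ds$records[[i]]@bhDft)
    expect_equal(back[[i]]@ts@frequencies, ds$records[[i]]@ts@frequencies)
    expect_equal(atomCoords(back[[i]]@reactant@geometry),
                 atomCoords(ds$records[[i]]@reactant@geometry))
    expect_equal(reactionTarget(back[[i]]), reactionTarget(ds$records[[i]]))
  }
})
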