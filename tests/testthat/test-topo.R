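completeGraph <- function(n, z = rep(6L, n)) {
  A <- matrix(1, n, n); diag(A) <- 0
  new("MolecularGraph", adjacency = A, atomicNumbers = z)
}
pathGraph <- function(n, z = rep(6L, n)) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) { A[i, i + 1] <- 1; A[i + 1, i] <- 1 }
  new("MolecularGraph", adjacency = A, atomicNumbers = z)
}
edgeless <- function(n) new("MolecularGraph", adjacency = matrix(0, n, n),
                            atomicNumbers = rep(6L, n))

test_that("topological indices reproduce closed forms", {
  expect_equal(randicIndex(completeGraph(4)), 2.0)
  expect_equal(randicIndex(pathGraph(3)), sqrt(2))
  expect_equal(randicIndex(edgeless(5)), 0)
  for (n in 2:6) expect_equal(randicIndex(completeGraph(n)), n / 2)

  expect_equal(spectralGap(completeGraph(4)), 4.0)
  expect_equal(spectralGap(completeGraph(2)), 2.0)

  expect_equal(estradaIndex(edgeless(7)), 7)
  expect_equal(estradaIndex(completeGraph(2)), exp(1) + exp(-1))
  expect_equal(estradaIndex(pathGraph(3)), exp(sqrt(2)) + 1 + exp(-sqrt(2)))

  expect_equal(zagrebIndex(pathGraph(3)), 6)
  expect_equal(zagrebIndex(completeGraph(4)), 36)
  expect_equal(zagrebIndex(edgeless(4)), 0)
  expect_equal(zagrebIndex(pathGraph(3), second = TRUE), 4)  # 2 edges x 1*2
})

test_that("spectral gap scales linearly with weights and is 0 when disconnected", {
  set.seed(5)
  g <- randomTestGraph(6, p_edge = 0.6)
  wg <- new("WeightedGraph",
            weights = g@adjacency * matrix(0.8, 6, 6),
            atomicNumbers = atomicNumbers(g))
  wg2 <- new("WeightedGraph", weights = wg@weights * 3,
             atomicNumbers = atomicNumbers(g))
  expect_equal(spectralGap(wg2), 3 * spectralGap(wg), tolerance = 1e-10)

  two_comp <- new("MolecularGraph",
                  adjacency = rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                                    c(0, 0, 0, 1), c(0, 0, 1, 0)),
                  atomicNumbers = rep(6L, 4))
  expect_equal(spectralGap(two_comp), 0)
})

test_that("indices match brute-force implementations on random graphs", {
  set.seed(42)
  worst <- c(randic = 0, estrada = 0, zagreb = 0, gap = 0)
  for (rep in 1:50) {
    g <- randomTestGraph(sample(2:8, 1))
    A <- adjacency(g)
    d <- rowSums(A)
    # brute-force loops over edges / dense solve on the Laplacian
    r_bf <- 0; z2 <- 0
    n <- nrow(A)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i < j && A[i, j] == 1)
      r_bf <- r_bf + 1 / sqrt(d[i] * d[j])
    e_bf <- sum(exp(eigen(A)$values))
    z_bf <- sum(d * d)
    L <- diag(d) - A
    evl <- sort(Re(eigen(L)$values))
    gap_bf <- if (sum(evl <= 1e-9) > 1) 0 else evl[evl > 1e-9][1]
    if (length(gap_bf) == 0 || is.na(gap_bf)) gap_bf <- 0
    worst["randic"] <- max(worst["randic"], abs(r_bf - randicIndex(g)))
    worst["estrada"] <- max(worst["estrada"], abs(e_bf - estradaIndex(g)))
    worst["zagreb"] <- max(worst["zagreb"], abs(z_bf - zagrebIndex(g)))
    worst["gap"] <- max(worst["gap"], abs(gap_bf - spectralGap(g)))
  }
  expect_true(all(worst < 1e-8))
})

test_that("indices are invariant under node permutation and Zagreb is edge-monotone", {
  set.seed(9)
  for (rep in 1:10) {
    g <- randomTestGraph(sample(3:8, 1))
    gp <- permuteGraph(g)
    expect_equal(randicIndex(gp), randicIndex(g), tolerance = 1e-12)
    expect_equal(estradaIndex(gp), estradaIndex(g), tolerance = 1e-10)
    expect_equal(zagrebIndex(gp), zagrebIndex(g))
    expect_equal(spectralGap(gp), spectralGap(g), tolerance = 1e-10)

    # adding an edge never decreases the Zagreb index
    A <- adjacency(g)
    holes <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
    if (nrow(holes) > 0) {
      k <- sample(nrow(holes), 1)
      A[holes[k, 1], holes[k, 2]] <- A[holes[k, 2], holes[k, 1]] <- 1
      g_plus <- new("MolecularGraph", adjacency = A,
                    atomicNumbers = atomicNumbers(g))
      expect_gte(zagrebIndex(g_plus), zagrebIndex(g))
    }
  }
})

test_that("topoFeatures evaluates the registry with stable naming", {
  v <- topoFeatures(h2coGeometry())
  expect_named(v, paste0("topol.", topoDescriptorNames()))
  expect_true(all(is.finite(v)))
  expect_equal(unname(v["topol.n_edges"]), 3)
})
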