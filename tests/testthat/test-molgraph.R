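test_that("buildGraph recovers expected bonding from standard geometries", {
  g <- buildGraph(methaneGeometry())
  A <- adjacency(g)
  expect_equal(sum(A) / 2, 4)              # 4 C-H bonds
  expect_true(all(A[1, 2:5] == 1))         # all to the carbon
  expect_true(all(A[2:5, 2:5] == 0))       # no H-H bonds

  g1 <- buildGraph(Geometry("O", matrix(c(0, 0, 0), 1)))
  expect_equal(nAtoms(g1), 1)
  expect_equal(sum(adjacency(g1)), 0)

  # formaldehyde: brute-force all-pairs distance vs threshold
  geom <- h2coGeometry()
  g2 <- buildGraph(geom)
  r <- supportedElements()$r_cov
  names(r) <- supportedElements()$symbol
  n <- nAtoms(geom)
  expected <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((atomCoords(geom)[i, ] - atomCoords(geom)[j, ])^2))
    if (d <= 1.2 * (r[atomSymbols(geom)[i]] + r[atomSymbols(geom)[j]]))
      expected[i, j] <- expected[j, i] <- 1
  }
  expect_equal(unname(adjacency(g2)), expected)
  # edges are exactly {C-O, C-H, C-H}
  expect_equal(sum(adjacency(g2)) / 2, 3)
  expect_equal(unname(adjacency(g2)[1, ]), c(0, 1, 1, 1))
})

test_that("buildGraph rejects bad inputs", {
  expect_error(Geometry("Xe", matrix(0, 1, 3)), "unsupported")
  overlapping <- Geometry(c("C", "C"), rbind(c(0, 0, 0), c(0.2, 0, 0)))
  expect_error(buildGraph(overlapping), "overlapping")
  expect_error(buildGraph(methaneGeometry(), scale = 2), "scale")
})

test_that("spectrumFingerprint matches the 2x2 closed form and is permutation invariant", {
  g <- new("MolecularGraph", adjacency = matrix(c(0, 1, 1, 0), 2, 2),
           atomicNumbers = c(6L, 1L))
  # eigenvalues of [[6,1],[1,1]]: (7 +/- sqrt(29)) / 2
  expect_equal(spectrumFingerprint(g),
               sort((7 + c(-1, 1) * sqrt(29)) / 2), tolerance = 1e-12)

  # edgeless graph: fingerprint = sorted atomic numbers
  ge <- new("MolecularGraph", adjacency = matrix(0, 3, 3),
            atomicNumbers = c(8L, 1L, 6L))
  expect_equal(spectrumFingerprint(ge), c(1, 6, 8))

  set.seed(11)
  for (rep in 1:20) {
    g <- randomTestGraph(sample(3:8, 1))
    expect_equal(spectrumFingerprint(permuteGraph(g)),
                 spectrumFingerprint(g), tolerance = 1e-10)
  }
})

test_that("fingerprints agree with an independent Jacobi eigensolver", {
  set.seed(7)
  worst <- 0
  for (rep in 1:50) {
    g <- randomTestGraph(sample(2:8, 1))
    M <- adjacency(g); diag(M) <- atomicNumbers(g)
    worst <- max(worst, max(abs(jacobiEigenvalues(M) -
                                  spectrumFingerprint(g))))
  }
  expect_lt(worst, 1e-8)
})

test_that("weighted fingerprints separate conformations but not rotations", {
  geom <- h2coGeometry()
  expect_equal(weightedFingerprint(geom), weightedFingerprint(geom))

  # stretched bond: same connectivity, different weighted spectrum
  stretched <- geom
  coords <- atomCoords(geom)
  coords[2, ] <- coords[2, ] * 1.2    # stretch C=O by 20%
  stretched <- Geometry(atomSymbols(geom), coords)
  expect_true(sameConnectivity(buildGraph(geom), buildGraph(stretched)))
  expect_gt(max(abs(weightedFingerprint(geom) -
                      weightedFingerprint(stretched))), 1e-3)

  # rigid rotation + permutation: identical within 1e-8
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  perm <- c(3, 1, 4, 2)
  rotated <- Geometry(atomSymbols(geom)[perm],
                      (atomCoords(geom) %*% t(R))[perm, ])
  expect_lt(max(abs(weightedFingerprint(geom) -
                      weightedFingerprint(rotated))), 1e-8)
})

test_that("sameConnectivity distinguishes isomers and size mismatches", {
  expect_true(sameConnectivity(hcnGraph(), hcnGraph()))
  expect_false(sameConnectivity(hcnGraph(), hncGraph()))
  g2 <- randomTestGraph(4)
  g3 <- randomTestGraph(5)
  expect_false(sameConnectivity(g2, g3))
})

test_that("sameConformation separates rotamers but not mirror images", {
  anti <- chainGeometry(180)
  gauche <- chainGeometry(60)
  expect_true(sameConformation(anti, anti))
  expect_true(sameConnectivity(buildGraph(anti), buildGraph(gauche)))
  expect_false(sameConformation(anti, gauche))

  mirror <- Geometry(atomSymbols(gauche),
                     atomCoords(gauche) %*% diag(c(1, 1, -1)))
  expect_true(sameConformation(gauche, mirror))  # documented limitation
})

test_that("distinct small CHNO graphs have distinguishable fingerprints", {
  # six structurally distinct 4-node graphs over fixed CHNO atoms
  zs <- c(6L, 7L, 8L, 1L)
  adj <- function(edges) {
    A <- matrix(0, 4, 4)
    for (e in edges) { A[e[1], e[2]] <- 1; A[e[2], e[1]] <- 1 }
    A
  }
  graphs <- list(
    adj(list(c(1, 2), c(2, 3), c(3, 4))),                 # path C-N-O-H
    adj(list(c(1, 2), c(1, 3), c(1, 4))),                 # star on C
    adj(list(c(2, 1), c(2, 3), c(2, 4))),                 # star on N
    adj(list(c(1, 2), c(2, 3), c(3, 1))),                 # triangle + lone H
    adj(list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))),        # 4-cycle
    adj(list(c(1, 2), c(3, 4)))                           # two dimers
  )
  fps <- lapply(graphs, function(A)
    spectrumFingerprint(new("MolecularGraph", adjacency = A,
                            atomicNumbers = zs)))
  for (i in 1:5) for (j in (i + 1):6)
    expect_gt(max(abs(fps[[i]] - fps[[j]])), 1e-4)
})

test_that("XYZ files round-trip geometries", {
  path <- tempfile(fileext = ".xyz")
  geoms <- list(methane = methaneGeometry(), h2co = h2coGeometry())
  writeXYZ(geoms, path)
  back <- readXYZ(path)
  expect_equal(length(back), 2)
  expect_equal(atomSymbols(back[[1]]), atomSymbols(geoms[[1]]))
  expect_equal(atomCoords(back[[2]]), atomCoords(geoms[[2]]),
               tolerance = 1e-7)
})
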