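# Shared fixtures, built in code.

# methane: C at origin, 4 H tetrahedral at 1.09 A
methaneGeometry <- function() {
  a <- 1.09 / sqrt(3)
  Geometry(c("C", "H", "H", "H", "H"),
           rbind(c(0, 0, 0), c(a, a, a), c(a, -a, -a), c(-a, a, -a),
                 c(-a, -a, a)))
}

# formaldehyde H2CO at a standard gas-phase geometry
h2coGeometry <- function() {
  Geometry(c("C", "O", "H", "H"),
           rbind(c(0, 0, 0), c(0, 0, 1.205),
                 c(0.943, 0, -0.587), c(-0.943, 0, -0.587)))
}

# HCN / HNC graphs (same atoms, different bonding), built directly
hcnGraph <- function() {
  new("MolecularGraph",
      adjacency = matrix(c(0, 1, 1, 1, 0, 0, 1, 0, 0), 3, 3),
      atomicNumbers = c(6L, 7L, 1L))  # C bonded to N and H
}
hncGraph <- function() {
  new("MolecularGraph",
      adjacency = matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3),
      atomicNumbers = c(6L, 7L, 1L))  # H bonded to N, N bonded to C
}

# n-butane-like heavy-atom chain with a settable C-C-C-C dihedral (degrees);
# hydrogens omitted -- the weighted fingerprint only needs the chain.
chainGeometry <- function(dihedral_deg) {
  d <- 1.53; ang <- 111 * pi / 180; phi <- dihedral_deg * pi / 180
  p1 <- c(0, 0, 0)
  p2 <- c(d, 0, 0)
  p3 <- p2 + d * c(-cos(ang), sin(ang), 0)
  # place p4 via the standard internal-coordinate construction
  b1 <- p2 - p1; b2 <- p3 - p2
  b2n <- b2 / sqrt(sum(b2^2))
  n1 <- pracma::cross(b1, b2); n1 <- n1 / sqrt(sum(n1^2))
  m1 <- pracma::cross(n1, b2n)
  dvec <- -b2n * cos(ang) + (m1 * cos(phi) + n1 * sin(phi)) * sin(ang)
  p4 <- p3 + d * dvec
  Geometry(c("C", "C", "C", "C"), rbind(p1, p2, p3, p4))
}

# random valence-free graph on n nodes with CHNO atomic numbers
randomTestGraph <- function(n, p_edge = 0.4) {
  A <- matrix(0, n, n)
  if (n > 1) {
    up <- which(upper.tri(A))
    A[up] <- as.numeric(stats::runif(length(up)) < p_edge)
    A <- A + t(A)
  }
  new("MolecularGraph", adjacency = A,
      atomicNumbers = sample(c(1L, 6L, 7L, 8L), n, replace = TRUE))
}

# apply a random node permutation to a graph
permuteGraph <- function(g, perm = sample(nAtoms(g))) {
  new("MolecularGraph", adjacency = g@adjacency[perm, perm],
      atomicNumbers = g@atomicNumbers[perm])
}

# independent symmetric eigensolver: classical Jacobi rotation sweeps,
# no LAPACK involved -- the oracle for all spectral fingerprints
jacobiEigenvalues <- function(M, tol = 1e-13, max_sweeps = 100) {
  A <- unname(as.matrix(M))
  n <- nrow(A)
  if (n == 1) return(as.numeric(A))
  for (sweep in seq_len(max_sweeps)) {
    off <- sqrt(sum(A[upper.tri(A)]^2))
    if (off < tol) break
    for (p in 1:(n - 1)) for (q in (p + 1):n) {
      if (abs(A[p, q]) < 1e-300) next
      theta <- (A[q, q] - A[p, p]) / (2 * A[p, q])
      t <- sign(theta) / (abs(theta) + sqrt(theta^2 + 1))
      if (theta == 0) t <- 1
      cs <- 1 / sqrt(t^2 + 1); sn <- t * cs
      J <- diag(n); J[p, p] <- cs; J[q, q] <- cs
      J[p, q] <- sn; J[q, p] <- -sn
      A <- t(J) %*% A %*% J
    }
  }
  sort(diag(A))
}

# cache expensive shared datasets across test files
.fixtureEnv <- new.env(parent = emptyenv())
cachedDataset <- function(key, maker) {
  if (is.null(.fixtureEnv[[key]])) .fixtureEnv[[key]] <- maker()
  .fixtureEnv[[key]]
}

# assembled features + target for a generated dataset
featurizeDataset <- function(ds, threshold = 0.9, split_seed = 3L) {
  fm <- suppressMessages(assembleFeatures(ds$records))
  y <- vapply(ds$records, reactionTarget, numeric(1))
  sp <- splitData(length(ds$records), seed = split_seed)
  fm <- correlationFilter(fm, threshold, rows = sp$train)
  list(X = featureValues(fm), y = y, sp = sp, fm = fm,
       bh_pm7 = vapply(ds$records, function(r)
         suppressWarnings(barrierHeight(r@reactant, r@ts)), numeric(1)),
       bh_dft = vapply(ds$records, function(r) r@bhDft, numeric(1)))
}
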