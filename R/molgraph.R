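## Molecular graphs from 3D geometries and eigenvalue fingerprints.
##
## Two structures are judged to have the same connectivity when the
## eigenvalues of their adjacency matrices (atomic numbers on the diagonal)
## agree; the same conformation when the eigenvalues of a weighted adjacency
## matrix agree. Eigenvalues are invariant under atom permutation, which makes
## the comparison ordering-free, at the cost of not distinguishing cospectral
## graphs or enantiomers (distances are reflection-invariant).

#' Build a molecular graph from a geometry
#'
#' Atoms i and j are bonded iff their distance does not exceed
#' `scale * (r_cov(i) + r_cov(j))`, using the package covalent-radius table
#' (see \code{\link{supportedElements}}).
#'
#' @param geom a \linkS4class{Geometry}.
#' @param scale bond-detection scale factor in [1.0, 1.5]; default 1.2.
#' @return A \linkS4class{MolecularGraph}.
#' @export
#' @examples
#' g <- Geometry(c("C", "O", "H", "H"),
#'               rbind(c(0, 0, 0), c(0, 0, 1.21),
#'                     c(0.94, 0, -0.54), c(-0.94, 0, -0.54)))
#' buildGraph(g)
buildGraph <- function(geom, scale = 1.2) {
  stopifnot(is(geom, "Geometry"))
  if (!is.numeric(scale) || length(scale) != 1L || scale < 1.0 || scale > 1.5)
    stop("scale must be a single value in [1.0, 1.5]", call. = FALSE)
  n <- nAtoms(geom)
  z <- .atomicNumbers(geom@symbols)
  r <- .covalentRadii(geom@symbols)
  A <- matrix(0, n, n)
  if (n > 1L) {
    D <- .distanceMatrix(geom)
    if (any(D[upper.tri(D)] < 0.5))
      stop("overlapping atoms: interatomic distance below 0.5 Angstrom",
           call. = FALSE)
    thr <- outer(r, r, "+") * scale
    A[D <= thr] <- 1
    diag(A) <- 0
  }
  new("MolecularGraph", adjacency = A, atomicNumbers = as.integer(z))
}

#' Spectral fingerprint of a molecular graph
#'
#' Eigenvalues of the adjacency matrix with atomic numbers on the diagonal,
#' sorted ascending. Identical fingerprints (to tolerance) identify identical
#' connectivity for structures with the same element multiset.
#'
#' @param g a \linkS4class{MolecularGraph}.
#' @return Sorted numeric vector of eigenvalues.
#' @export
spectrumFingerprint <- function(g) {
  stopifnot(is(g, "MolecularGraph"))
  M <- g@adjacency
  diag(M) <- g@atomicNumbers
  sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
}

#' Weighted graph from a geometry
#'
#' Atom pairs carry the weight `w_ij = (r_cov(i) + r_cov(j)) / d_ij`:
#' dimensionless, close to 1 at equilibrium bond lengths, small for distant
#' pairs, monotone in compression. Two forms serve two purposes:
#' \describe{
#'   \item{`pairs = "bonded"`}{weights only where the molecular graph has a
#'     bond (zero elsewhere). This preserves graph structure, so the weighted
#'     Laplacian keeps one zero eigenvalue per fragment and the spectral gap
#'     retains its tightness/disconnection semantics. Default.}
#'   \item{`pairs = "all"`}{weights on every pair. This makes the spectrum
#'     sensitive to torsions and packing, so conformers that share every bond
#'     length still separate; used by \code{\link{weightedFingerprint}}.}
#' }
#'
#' @param geom a \linkS4class{Geometry}.
#' @param graph the \linkS4class{MolecularGraph} built from `geom`; built on
#'   the fly when omitted.
#' @param scale bond scale used when `graph` is missing.
#' @param pairs "bonded" (default) or "all".
#' @return A \linkS4class{WeightedGraph}.
#' @export
weightedGraph <- function(geom, graph = NULL, scale = 1.2,
                          pairs = c("bonded", "all")) {
  pairs <- match.arg(pairs)
  if (is.null(graph)) graph <- buildGraph(geom, scale)
  stopifnot(nAtoms(graph) == nAtoms(geom))
  n <- nAtoms(geom)
  W <- matrix(0, n, n)
  if (n > 1L) {
    D <- .distanceMatrix(geom)
    r <- .covalentRadii(geom@symbols)
    rsum <- outer(r, r, "+")
    sel <- if (pairs == "all") row(W) != col(W) else graph@adjacency == 1
    W[sel] <- rsum[sel] / D[sel]
  }
  new("WeightedGraph", weights = W, atomicNumbers = graph@atomicNumbers)
}

#' Weighted spectral fingerprint
#'
#' Eigenvalues of the all-pairs weighted matrix (atomic numbers on the
#' diagonal), sorted ascending. Sensitive to the full 3D structure, so it
#' separates conformers (e.g. rotamers) that share connectivity and bond
#' lengths.
#'
#' @param geom a \linkS4class{Geometry}.
#' @param graph optional pre-built \linkS4class{MolecularGraph} for `geom`.
#' @param scale bond scale used if `graph` is missing.
#' @return Sorted numeric vector of eigenvalues.
#' @export
weightedFingerprint <- function(geom, graph = NULL, scale = 1.2) {
  wg <- weightedGraph(geom, graph, scale, pairs = "all")
  M <- wg@weights
  diag(M) <- wg@atomicNumbers
  sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
}

#' Do two graphs share the same connectivity?
#'
#' TRUE iff the graphs have equal atom counts, equal sorted atomic-number
#' multisets, and spectral fingerprints equal element-wise within `tol`.
#'
#' @param a,b \linkS4class{MolecularGraph} objects.
#' @param tol element-wise eigenvalue tolerance (default 1e-4).
#' @return logical(1).
#' @export
sameConnectivity <- function(a, b, tol = 1e-4) {
  stopifnot(is(a, "MolecularGraph"), is(b, "MolecularGraph"))
  if (nAtoms(a) != nAtoms(b)) return(FALSE)
  if (!identical(sort(a@atomicNumbers), sort(b@atomicNumbers))) return(FALSE)
  max(abs(spectrumFingerprint(a) - spectrumFingerprint(b))) <= tol
}

#' Do two geometries present the same conformation?
#'
#' Assumes \code{\link{sameConnectivity}} already holds for their graphs;
#' compares weighted fingerprints within `tol`. The default tolerance is
#' looser than the connectivity one because the geometries being compared
#' typically come from different optimizers. Mirror images are not
#' distinguished (interatomic distances are reflection-invariant).
#'
#' @param geomA,geomB \linkS4class{Geometry} objects.
#' @param tol element-wise eigenvalue tolerance (default 1e-3).
#' @param scale bond scale for graph construction.
#' @return logical(1).
#' @export
sameConformation <- function(geomA, geomB, tol = 1e-3, scale = 1.2) {
  fa <- weightedFingerprint(geomA, scale = scale)
  fb <- weightedFingerprint(geomB, scale = scale)
  if (length(fa) != length(fb)) return(FALSE)
  max(abs(fa - fb)) <= tol
}
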