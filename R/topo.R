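## Topological descriptors of the transition-state graph (X_topol family).
##
## Randic, Estrada and Zagreb indices are computed on the plain 0/1 adjacency;
## only the Laplacian spectral gap uses the weighted matrix, which is what ties
## the descriptor to the 3D tightness of the TS structure.

#' Randic connectivity index
#'
#' Sum over edges (i, j) of (d_i d_j)^(-1/2), d = vertex degree; 0 for an
#' edgeless graph. Equals n/2 for the complete graph K_n.
#'
#' @param g a \linkS4class{MolecularGraph}.
#' @return numeric(1), non-negative.
#' @export
randicIndex <- function(g) {
  stopifnot(is(g, "MolecularGraph"))
  A <- g@adjacency
  d <- rowSums(A)
  e <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  if (nrow(e) == 0L) return(0)
  sum(1 / sqrt(d[e[, 1]] * d[e[, 2]]))
}

#' Laplacian spectral gap
#'
#' Smallest eigenvalue of the Laplacian D - A strictly above numerical zero
#' (threshold 1e-9). For a weighted graph, D holds the weighted degrees (row
#' sums) and A the weights; atomic numbers are never added to the Laplacian.
#' Returns 0 when the graph splits into more than one component and the
#' second-smallest eigenvalue is itself below threshold.
#'
#' @param g a \linkS4class{WeightedGraph} or \linkS4class{MolecularGraph}
#'   (the latter treated as unit weights).
#' @param zero_tol threshold separating numerical zeros (default 1e-9).
#' @return numeric(1), non-negative.
#' @export
spectralGap <- function(g, zero_tol = 1e-9) {
  W <- if (is(g, "WeightedGraph")) g@weights
       else if (is(g, "MolecularGraph")) g@adjacency
       else stop("g must be a WeightedGraph or MolecularGraph", call. = FALSE)
  L <- diag(rowSums(W), nrow(W)) - W
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  # one numerical zero per connected component: a second zero means the
  # graph is disconnected and the gap is reported as 0
  if (sum(ev <= zero_tol) > 1L) return(0)
  pos <- ev[ev > zero_tol]
  if (length(pos) == 0L) return(0)
  pos[1]
}

#' Estrada index
#'
#' Sum of exp(mu_i) over the eigenvalues mu of the plain 0/1 adjacency matrix
#' (no atomic-number diagonal). Equals n for an edgeless n-node graph.
#'
#' @param g a \linkS4class{MolecularGraph}.
#' @return numeric(1), positive.
#' @export
estradaIndex <- function(g) {
  stopifnot(is(g, "MolecularGraph"))
  mu <- eigen(g@adjacency, symmetric = TRUE, only.values = TRUE)$values
  sum(exp(mu))
}

#' Zagreb index
#'
#' First Zagreb index: sum of squared vertex degrees on the unweighted graph
#' (the common unqualified usage). The second Zagreb index (sum over edges of
#' d_i d_j) is available with `second = TRUE`.
#'
#' @param g a \linkS4class{MolecularGraph}.
#' @param second compute the second Zagreb index instead.
#' @return numeric(1), non-negative.
#' @export
zagrebIndex <- function(g, second = FALSE) {
  stopifnot(is(g, "MolecularGraph"))
  A <- g@adjacency
  d <- rowSums(A)
  if (!second) return(sum(d^2))
  e <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  if (nrow(e) == 0L) return(0)
  sum(d[e[, 1]] * d[e[, 2]])
}

## Registry of topological descriptors: name -> function(graph, wgraph).
## Keeping the registry as a single object makes the column set and its order
## reproducible and extensible.
.topoRegistry <- list(
  randic     = function(g, wg) randicIndex(g),
  lambda1    = function(g, wg) spectralGap(wg),
  estrada    = function(g, wg) estradaIndex(g),
  zagreb     = function(g, wg) zagrebIndex(g),
  mean_degree = function(g, wg) mean(rowSums(g@adjacency)),
  max_degree = function(g, wg) max(rowSums(g@adjacency)),
  n_edges    = function(g, wg) sum(g@adjacency) / 2
)

#' Topological descriptor names
#' @return Character vector of registry names, in column order.
#' @export
topoDescriptorNames <- function() names(.topoRegistry)

#' Compute all topological descriptors for one structure
#'
#' Evaluates the descriptor registry (Randic, weighted-Laplacian spectral gap
#' lambda1, Estrada, first Zagreb, plus degree statistics) on a geometry's
#' graph.
#'
#' @param geom a \linkS4class{Geometry} (typically the transition state).
#' @param scale bond scale for graph construction.
#' @return Named numeric vector, names `topol.<descriptor>`.
#' @export
topoFeatures <- function(geom, scale = 1.2) {
  g <- buildGraph(geom, scale)
  wg <- weightedGraph(geom, g)
  vals <- vapply(.topoRegistry, function(f) f(g, wg), numeric(1))
  names(vals) <- paste0("topol.", names(.topoRegistry))
  vals
}
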