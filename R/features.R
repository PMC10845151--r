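## Feature-matrix assembly, Pearson-correlation pruning, and the reduced
## importance-ranked subset fed to the Gaussian process.

#' Construct a FeatureMatrix
#'
#' @param matrix numeric matrix with unique column names.
#' @param family per-column family tags; inferred from the `family.` name
#'   prefix when omitted.
#' @return A \linkS4class{FeatureMatrix}.
#' @export
FeatureMatrix <- function(matrix, family = NULL) {
  if (is.null(family)) family <- sub("\\..*$", "", colnames(matrix))
  new("FeatureMatrix", matrix = matrix, family = family)
}

#' Assemble the stacked descriptor matrix for curated records
#'
#' Column-wise concatenation, in fixed order, of the four descriptor
#' families: `rdkit.` delta-descriptors from the reactant/product SMILES,
#' `topol.` indices of the transition-state graph, `bonds.` formed/broken
#' bond counts, and `pm7.` semiempirical descriptors. Zero-variance columns
#' are dropped with a message.
#'
#' @param records list of \linkS4class{ReactionRecord} objects.
#' @param scale bond-detection scale for graph construction.
#' @param k_bond_eigs bond-order eigenvalues kept per record.
#' @param drop_constant drop zero-variance columns (default TRUE).
#' @return A \linkS4class{FeatureMatrix} with rownames = record ids.
#' @export
assembleFeatures <- function(records, scale = 1.2, k_bond_eigs = 10L,
                             drop_constant = TRUE) {
  stopifnot(length(records) > 0L)
  ids <- vapply(records, function(r) r@id, "")
  rd <- deltaDescriptors(vapply(records, function(r) r@smilesReactant, ""),
                         vapply(records, function(r) r@smilesProduct, ""))
  topo <- t(vapply(records, function(r) topoFeatures(r@ts@geometry, scale),
                   numeric(length(topoDescriptorNames()))))
  bonds <- t(vapply(records, function(r)
    bondChanges(buildGraph(r@reactant@geometry, scale),
                buildGraph(r@product@geometry, scale)), numeric(20L)))
  pm7 <- t(vapply(records, function(r) sqmFeatures(r, k_bond_eigs),
                  numeric(10L + k_bond_eigs)))
  m <- cbind(rd, topo, bonds, pm7)
  rownames(m) <- ids
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite feature value: record ", ids[bad[1, 1]], ", column ",
         colnames(m)[bad[1, 2]], call. = FALSE)
  if (drop_constant) {
    const <- apply(m, 2, function(x) max(x) - min(x) == 0)
    if (any(const)) {
      message("dropping ", sum(const), " zero-variance column(s): ",
              paste(colnames(m)[const], collapse = ", "))
      m <- m[, !const, drop = FALSE]
    }
  }
  FeatureMatrix(m)
}

#' Prune highly correlated descriptors
#'
#' Greedy scan in column order: a column is dropped iff its absolute Pearson
#' correlation with any already-retained column exceeds `threshold`. The
#' first column of a correlated group is therefore kept (reproducible
#' keep-first tie-breaking). To avoid leakage, compute the filter on training
#' rows via `rows` and apply the retained set everywhere.
#'
#' @param m a \linkS4class{FeatureMatrix} (or plain named matrix).
#' @param threshold absolute Pearson correlation above which a column is
#'   dropped; default 0.9.
#' @param rows optional row indices on which correlations are computed
#'   (e.g. the training split); all rows by default.
#' @return A \linkS4class{FeatureMatrix} with the retained columns, original
#'   order preserved; attribute `dropped` lists removed names.
#' @export
correlationFilter <- function(m, threshold = 0.9, rows = NULL) {
  fm <- if (is(m, "FeatureMatrix")) m else FeatureMatrix(m)
  X <- fm@matrix
  if (is.null(rows)) rows <- seq_len(nrow(X))
  stopifnot(length(rows) >= 3L)
  cm <- abs(suppressWarnings(stats::cor(X[rows, , drop = FALSE])))
  cm[is.na(cm)] <- 0  # zero-variance columns correlate with nothing
  keep <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    keep[j] <- !any(cm[j, keep] > threshold)
  }
  out <- FeatureMatrix(X[, keep, drop = FALSE], fm@family[keep])
  attr(out, "dropped") <- colnames(X)[!keep]
  out
}

#' Reduced feature subset by tree-ensemble importance
#'
#' Ranks features by the gain importance of a fitted gradient-boosted-tree
#' model and returns the top `k` (default 49), ties broken by column order.
#' This is the succinct descriptor set X' fed to the Gaussian process.
#'
#' @param model a \linkS4class{CorrectionModel} of kind "xgb".
#' @param m the \linkS4class{FeatureMatrix} the model was trained on.
#' @param k subset size (capped at the number of features, with a warning).
#' @return A list with `selected` (ordered names, most important first) and
#'   `importances` (named numeric gain scores for all features; zero for
#'   features the trees never used).
#' @export
importanceSubset <- function(model, m, k = 49L) {
  stopifnot(is(model, "CorrectionModel"), modelKind(model) == "xgb")
  nms <- if (is(m, "FeatureMatrix")) featureNames(m) else colnames(m)
  if (k > length(nms)) {
    warning("k exceeds the number of features; capped at ", length(nms),
            call. = FALSE)
    k <- length(nms)
  }
  imp_tab <- xgboost::xgb.importance(model = model@fit$booster)
  gain <- stats::setNames(numeric(length(nms)), nms)
  gain[imp_tab$Feature] <- imp_tab$Gain
  ord <- order(-gain, seq_along(gain))  # descending gain, column-order ties
  selected <- nms[ord][seq_len(k)]
  list(selected = selected, importances = gain)
}
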