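## S4 classes for the core data containers.

setOldClass("data.frame")

#' Geometry: one molecular structure
#'
#' Element symbols plus n x 3 Cartesian coordinates in Angstrom.
#'
#' @slot symbols character vector of element symbols (H, C, N, O).
#' @slot coords numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @export
setClass("Geometry",
  representation(symbols = "character", coords = "matrix"),
  validity = function(object) {
    n <- length(object@symbols)
    if (n < 1L) return("geometry must contain at least one atom")
    bad <- setdiff(unique(object@symbols), .ELEMENTS$symbol)
    if (length(bad) > 0L)
      return(paste0("unsupported element(s): ", paste(bad, collapse = ", ")))
    if (!is.numeric(object@coords) || ncol(object@coords) != 3L ||
        nrow(object@coords) != n)
      return("coords must be a numeric n x 3 matrix matching symbols")
    if (!all(is.finite(object@coords))) return("coordinates must be finite")
    TRUE
  })

#' Molecular graph with atomic numbers
#'
#' Symmetric 0/1 adjacency with zero diagonal; atomic numbers stored
#' separately and placed on the diagonal only when the spectral fingerprint
#' is computed.
#'
#' @slot adjacency numeric n x n symmetric 0/1 matrix with zero diagonal.
#' @slot atomicNumbers integer vector of length n.
#' @export
setClass("MolecularGraph",
  representation(adjacency = "matrix", atomicNumbers = "integer"),
  validity = function(object) {
    A <- object@adjacency
    n <- length(object@atomicNumbers)
    if (nrow(A) != n || ncol(A) != n)
      return("adjacency dimensions must match atomicNumbers length")
    if (!isSymmetric(unname(A))) return("adjacency must be symmetric")
    if (any(diag(A) != 0)) return("adjacency diagonal must be zero")
    if (!all(A %in% c(0, 1))) return("adjacency entries must be 0 or 1")
    TRUE
  })

#' Weighted molecular graph
#'
#' Symmetric non-negative weight matrix (zero diagonal, inverse-distance
#' weights off it) with atomic numbers; used for conformer-sensitive
#' fingerprints and the weighted Laplacian spectral gap.
#'
#' @slot weights numeric n x n symmetric non-negative matrix.
#' @slot atomicNumbers integer vector of length n.
#' @export
setClass("WeightedGraph",
  representation(weights = "matrix", atomicNumbers = "integer"),
  validity = function(object) {
    W <- object@weights
    n <- length(object@atomicNumbers)
    if (nrow(W) != n || ncol(W) != n)
      return("weights dimensions must match atomicNumbers length")
    if (!isSymmetric(unname(W))) return("weights must be symmetric")
    if (!all(is.finite(W))) return("weights must be finite")
    if (any(W < 0)) return("weights must be non-negative")
    TRUE
  })

#' Low-level (semiempirical) results for one stationary point
#'
#' Scalar results of a PM7-style calculation for a single species: electronic
#' energy and ZPE (kcal/mol), harmonic wavenumbers (cm^-1, a transition state
#' carries exactly one negative entry), frontier-orbital energies (eV), the
#' symmetric bond-order matrix and the summed self-polarizability.
#'
#' @slot energy numeric(1), kcal/mol.
#' @slot zpe numeric(1), kcal/mol, non-negative.
#' @slot frequencies numeric, cm^-1 (signed; imaginary modes negative).
#' @slot homo,lumo numeric(1), eV.
#' @slot bondOrders numeric symmetric matrix.
#' @slot selfPolarizability numeric(1).
#' @slot geometry the associated \linkS4class{Geometry}.
#' @export
setClass("SQMSpecies",
  representation(energy = "numeric", zpe = "numeric", frequencies = "numeric",
                 homo = "numeric", lumo = "numeric", bondOrders = "matrix",
                 selfPolarizability = "numeric", geometry = "Geometry"),
  validity = function(object) {
    if (length(object@energy) != 1L || !is.finite(object@energy))
      return("energy must be a single finite number")
    if (length(object@zpe) != 1L || !is.finite(object@zpe) || object@zpe < 0)
      return("zpe must be a single non-negative number")
    if (!isSymmetric(unname(object@bondOrders)))
      return("bondOrders must be symmetric")
    if (length(object@homo) != 1L || length(object@lumo) != 1L ||
        !is.finite(object@homo) || !is.finite(object@lumo))
      return("homo/lumo must be single finite numbers")
    TRUE
  })

#' One curated reaction: reactant, transition state, product
#'
#' Holds the three stationary points at the low level, the reference
#' (DFT-level) barrier height, and reactant/product SMILES. The low-level
#' barrier height and the regression target Delta = BH_DFT - BH_PM7 are
#' derived with \code{\link{barrierHeight}} and \code{\link{reactionTarget}}.
#'
#' @slot id character identifier.
#' @slot reactant,ts,product \linkS4class{SQMSpecies} objects.
#' @slot bhDft numeric(1), reference barrier height in kcal/mol.
#' @slot smilesReactant,smilesProduct character SMILES (multi-fragment species
#'   dot-separated).
#' @export
setClass("ReactionRecord",
  representation(id = "character", reactant = "SQMSpecies", ts = "SQMSpecies",
                 product = "SQMSpecies", bhDft = "numeric",
                 smilesReactant = "character", smilesProduct = "character"),
  validity = function(object) {
    if (length(object@bhDft) != 1L || !is.finite(object@bhDft))
      return("bhDft must be a single finite number")
    n_imag <- sum(object@ts@frequencies < 0)
    if (n_imag != 1L)
      return(sprintf("transition state must carry exactly one imaginary frequency (found %d)",
                     n_imag))
    TRUE
  })

#' Raw (pre-curation) record for the screening flow
#'
#' Inputs to the curation decision logic: the dataset reactant/product
#' geometries, the success flag of the low-level TS optimization, the two IRC
#' endpoint geometries, and the four low-level optimized structures used for
#' the conformation comparison. Geometry optimization and IRC integration are
#' upstream quantum-chemistry steps; this class only carries their outputs.
#'
#' @slot id character identifier.
#' @slot dftReactant,dftProduct dataset geometries.
#' @slot tsOptOk logical(1): did the low-level TS optimization succeed.
#' @slot ircFwd,ircRev IRC endpoint geometries.
#' @slot optEndpointFwd,optEndpointRev,optDatasetReactant,optDatasetProduct
#'   low-level optimized geometries for the conformation comparison.
#' @export
setClass("RawRecord",
  representation(id = "character",
                 dftReactant = "Geometry", dftProduct = "Geometry",
                 tsOptOk = "logical",
                 ircFwd = "Geometry", ircRev = "Geometry",
                 optEndpointFwd = "Geometry", optEndpointRev = "Geometry",
                 optDatasetReactant = "Geometry",
                 optDatasetProduct = "Geometry"),
  validity = function(object) {
    if (length(object@tsOptOk) != 1L || is.na(object@tsOptOk))
      return("tsOptOk must be TRUE or FALSE")
    ms <- sort(object@dftReactant@symbols)
    geoms <- list(object@dftProduct, object@ircFwd, object@ircRev,
                  object@optEndpointFwd, object@optEndpointRev,
                  object@optDatasetReactant, object@optDatasetProduct)
    for (g in geoms)
      if (!identical(sort(g@symbols), ms))
        return("all geometries in a record must share the element multiset")
    TRUE
  })

#' Stacked descriptor matrix with family tags
#'
#' An n_reactions x n_features numeric matrix with unique column names
#' prefixed by family (rdkit., topol., bonds., pm7.) and a per-column family
#' tag.
#'
#' @slot matrix numeric matrix, no NaN/Inf.
#' @slot family character vector, one tag per column.
#' @export
setClass("FeatureMatrix",
  representation(matrix = "matrix", family = "character"),
  validity = function(object) {
    m <- object@matrix
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
      return("feature columns must have unique names")
    if (length(object@family) != ncol(m))
      return("family must tag every column")
    if (!all(is.finite(m))) return("feature matrix must be finite")
    TRUE
  })

#' A fitted barrier-height correction model
#'
#' One of the three regression heads (gradient-boosted trees, Gaussian
#' process, multitask neural network) fitted to predict the correction
#' Delta = BH_DFT - BH_PM7 in kcal/mol from a named feature matrix.
#'
#' @slot kind "xgb", "gp" or "multitask_nn".
#' @slot featureNames ordered training feature names; prediction requires
#'   exactly these columns in this order.
#' @slot fit opaque fitted state.
#' @export
setClass("CorrectionModel",
  representation(kind = "character", featureNames = "character", fit = "list"),
  validity = function(object) {
    if (!object@kind %in% c("xgb", "gp", "multitask_nn"))
      return("kind must be one of xgb, gp, multitask_nn")
    TRUE
  })
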