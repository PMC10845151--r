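## Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for deltaBH classes
#' @description Slot accessors: \code{atomSymbols}, \code{atomCoords},
#'   \code{nAtoms}, \code{adjacency}, \code{atomicNumbers}, \code{weights},
#'   \code{featureNames}, \code{featureFamilies}, \code{featureValues},
#'   \code{modelKind}.
#' @param x an object.
#' @return The slot contents.
NULL

#' @rdname accessors
#' @export
setGeneric("atomSymbols", function(x) standardGeneric("atomSymbols"))
#' @rdname accessors
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("atomicNumbers", function(x) standardGeneric("atomicNumbers"))
#' @rdname accessors
#' @export
setGeneric("graphWeights", function(x) standardGeneric("graphWeights"))
#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
#' @rdname accessors
#' @export
setGeneric("featureFamilies", function(x) standardGeneric("featureFamilies"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("modelKind", function(x) standardGeneric("modelKind"))

#' @rdname accessors
#' @export
setMethod("atomSymbols", "Geometry", function(x) x@symbols)
#' @rdname accessors
#' @export
setMethod("atomCoords", "Geometry", function(x) x@coords)
#' @rdname accessors
#' @export
setMethod("nAtoms", "Geometry", function(x) length(x@symbols))
#' @rdname accessors
#' @export
setMethod("nAtoms", "MolecularGraph", function(x) length(x@atomicNumbers))
#' @rdname accessors
#' @export
setMethod("nAtoms", "WeightedGraph", function(x) length(x@atomicNumbers))
#' @rdname accessors
#' @export
setMethod("adjacency", "MolecularGraph", function(x) x@adjacency)
#' @rdname accessors
#' @export
setMethod("atomicNumbers", "MolecularGraph", function(x) x@atomicNumbers)
#' @rdname accessors
#' @export
setMethod("atomicNumbers", "WeightedGraph", function(x) x@atomicNumbers)
#' @rdname accessors
#' @export
setMethod("graphWeights", "WeightedGraph", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("featureNames", "FeatureMatrix", function(x) colnames(x@matrix))
#' @rdname accessors
#' @export
setMethod("featureFamilies", "FeatureMatrix", function(x) x@family)
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@matrix)
#' @rdname accessors
#' @export
setMethod("featureNames", "CorrectionModel", function(x) x@featureNames)
#' @rdname accessors
#' @export
setMethod("modelKind", "CorrectionModel", function(x) x@kind)

setMethod("show", "Geometry", function(object) {
  cat(sprintf("Geometry: %d atoms (%s)\n", nAtoms(object),
              paste0(names(table(object@symbols)), table(object@symbols),
                     collapse = " ")))
})

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph: %d atoms, %d bonds\n", nAtoms(object),
              sum(object@adjacency) / 2))
})

setMethod("show", "WeightedGraph", function(object) {
  cat(sprintf("WeightedGraph: %d atoms, %d weighted edges\n", nAtoms(object),
              sum(object@weights > 0) / 2))
})

setMethod("show", "SQMSpecies", function(object) {
  n_imag <- sum(object@frequencies < 0)
  cat(sprintf("SQMSpecies: %d atoms, E = %.3f kcal/mol, ZPE = %.3f, %d modes (%d imaginary)\n",
              nAtoms(object@geometry), object@energy, object@zpe,
              length(object@frequencies), n_imag))
})

setMethod("show", "ReactionRecord", function(object) {
  cat(sprintf("ReactionRecord %s: %s -> %s\n", object@id,
              object@smilesReactant, object@smilesProduct))
  cat(sprintf("  BH_PM7 = %.3f, BH_DFT = %.3f, target = %.3f kcal/mol\n",
              barrierHeight(object@reactant, object@ts), object@bhDft,
              reactionTarget(object)))
})

setMethod("show", "FeatureMatrix", function(object) {
  fam <- table(object@family)
  cat(sprintf("FeatureMatrix: %d reactions x %d features (%s)\n",
              nrow(object@matrix), ncol(object@matrix),
              paste(names(fam), fam, sep = ":", collapse = ", ")))
})

setMethod("show", "CorrectionModel", function(object) {
  cat(sprintf("CorrectionModel <%s>: %d features\n", object@kind,
              length(object@featureNames)))
})
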