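## Standard cheminformatics delta-descriptors (X_RDKit-style family).
##
## Descriptors are computed from SMILES with the ChemmineR/ChemmineOB
## (OpenBabel) backend: the propOB property set plus formula/graph counts.
## For each descriptor the reaction-level value is the signed difference
## product - reactant, except for descriptors on a fixed declared invariant
## list (conserved quantities such as molecular weight and atom counts), for
## which the raw reactant value is used. The invariant list is declared, not
## detected at runtime, so column semantics never change per-reaction.

.CHEM_INVARIANT <- c("MW", "n_atoms", "n_heavy", "nH", "nC", "nN", "nO")

.CHEM_NUMERIC_PROPS <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "TPSA")

## Count one element in a Hill-style formula string, e.g. "C2H4O" -> H: 4.
.formulaCount <- function(formula, element) {
  m <- regmatches(formula,
                  regexec(paste0(element, "(?![a-z])([0-9]*)"), formula,
                          perl = TRUE))[[1]]
  if (length(m) == 0L) return(0L)
  if (m[2] == "") 1L else as.integer(m[2])
}

## Per-species descriptor matrix for a vector of SMILES (one row per entry).
.speciesDescriptors <- function(smiles) {
  stopifnot(length(smiles) >= 1L)
  sdf <- tryCatch(
    ChemmineR::smiles2sdf(stats::setNames(smiles, seq_along(smiles))),
    error = function(e) {
      ok <- vapply(smiles, function(s)
        !inherits(try(suppressWarnings(ChemmineR::smiles2sdf(s)),
                      silent = TRUE), "try-error"), logical(1))
      stop("input error: unparseable SMILES: ",
           paste(unique(smiles[!ok]), collapse = ", "), call. = FALSE)
    })
  if (length(sdf) != length(smiles)) {
    ok <- as.integer(ChemmineR::sdfid(sdf))
    bad <- smiles[setdiff(seq_along(smiles), ok)]
    stop("input error: unparseable SMILES: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  props <- ChemmineR::propOB(sdf)
  ringc <- tryCatch(as.numeric(ChemmineR::rings(sdf, type = "count")[, 1]),
                    error = function(e) rep(NA_real_, length(smiles)))
  per_mol <- function(k) {
    mol <- sdf[[k]]
    ab <- ChemmineR::atomblock(mol)
    bb <- tryCatch(ChemmineR::bondblock(mol), error = function(e) NULL)
    sym <- gsub("_.*$", "", rownames(ab))
    orders <- if (is.null(bb) || nrow(bb) == 0L) integer(0) else as.integer(bb[, 3])
    formula <- props$formula[k]
    nH <- .formulaCount(formula, "H")
    n_heavy <- length(sym)
    c(n_heavy   = n_heavy,
      n_atoms   = n_heavy + nH,
      nH        = nH,
      nC        = sum(sym == "C"),
      nN        = sum(sym == "N"),
      nO        = sum(sym == "O"),
      n_bonds   = length(orders),
      n_single  = sum(orders == 1L),
      n_double  = sum(orders == 2L),
      n_triple  = sum(orders == 3L),
      n_rings   = if (is.na(ringc[k])) max(0, length(orders) - n_heavy +
                                             1) else ringc[k])
  }
  counts <- t(vapply(seq_along(smiles), per_mol, numeric(11L)))
  out <- cbind(as.matrix(props[, .CHEM_NUMERIC_PROPS, drop = FALSE]), counts)
  rownames(out) <- NULL
  storage.mode(out) <- "double"
  out
}

#' Names of the cheminformatics descriptor registry
#'
#' @return Character vector of per-species descriptor names (without the
#'   `rdkit.` column prefix used in feature matrices).
#' @export
chemDescriptorNames <- function() {
  c(.CHEM_NUMERIC_PROPS,
    c("n_heavy", "n_atoms", "nH", "nC", "nN", "nO", "n_bonds", "n_single",
      "n_double", "n_triple", "n_rings"))
}

#' Delta-descriptors for one or more reactions
#'
#' For each registered descriptor, computes the reaction-level value
#' `X_i(product) - X_i(reactant)` (mode "difference", the default) or the
#' mean of the two (mode "average", kept as an auditable alternative).
#' Descriptors on the declared invariant list (molecular weight and atom
#' counts, conserved in any atom-balanced reaction) report the raw reactant
#' value instead. Multi-fragment species are written dot-separated and
#' evaluated as the composite structure.
#'
#' @param smiles_reactant,smiles_product character vectors of equal length.
#' @param mode "difference" or "average".
#' @return A numeric matrix with one row per reaction and columns
#'   `rdkit.<name>`; attribute `invariant` holds the logical invariant mask.
#' @export
#' @examples
#' \donttest{
#' d <- deltaDescriptors("CC=O", "C1CO1")  # acetaldehyde -> oxirane
#' d[, "rdkit.n_rings"]                    # +1
#' }
deltaDescriptors <- function(smiles_reactant, smiles_product,
                             mode = c("difference", "average")) {
  mode <- match.arg(mode)
  stopifnot(length(smiles_reactant) == length(smiles_product))
  smiles <- c(smiles_reactant, smiles_product)
  uniq <- unique(smiles)
  tab <- .speciesDescriptors(uniq)
  iR <- match(smiles_reactant, uniq)
  iP <- match(smiles_product, uniq)
  XR <- tab[iR, , drop = FALSE]
  XP <- tab[iP, , drop = FALSE]
  out <- if (mode == "difference") XP - XR else (XP + XR) / 2
  inv <- colnames(tab) %in% .CHEM_INVARIANT
  out[, inv] <- XR[, inv]
  colnames(out) <- paste0("rdkit.", colnames(tab))
  attr(out, "invariant") <- stats::setNames(inv, colnames(out))
  out
}
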