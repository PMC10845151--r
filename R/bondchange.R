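## Formed/broken bond counts per element pair (X_bonds family).

.BOND_PAIRS <- c("HH", "CH", "CN", "CO", "HN", "HO", "CC", "NN", "NO", "OO")

## Canonical pair label for two atomic numbers, matching .BOND_PAIRS naming.
.pairLabel <- function(z1, z2) {
  s <- .symbolsFromNumbers(c(z1, z2))
  cands <- c(paste0(s[1], s[2]), paste0(s[2], s[1]))
  cands[cands %in% .BOND_PAIRS][1]
}

#' Bond-change feature names
#'
#' The fixed 20-column naming: `bonds.+HH`, `bonds.+CH`, ... for formed bonds
#' and `bonds.-HH`, ... for broken bonds, over all unordered pairings of
#' H, C, N, O.
#'
#' @return Character vector of 20 names in stable order.
#' @export
bondChangeNames <- function() {
  c(paste0("bonds.+", .BOND_PAIRS), paste0("bonds.-", .BOND_PAIRS))
}

#' Count formed and broken bonds between reactant and product
#'
#' Atom mapping is positional: atom i of the reactant is atom i of the
#' product, as holds for IRC-connected structures. Formed bonds are edges
#' present in the product but not the reactant; broken bonds the reverse.
#' Counts are tallied per unordered element pair.
#'
#' @param reactant,product \linkS4class{MolecularGraph} objects with identical
#'   atomic-number vectors in the same index order.
#' @return Named numeric vector of 20 counts (see
#'   \code{\link{bondChangeNames}}).
#' @export
#' @examples
#' # formaldehyde decomposition H2CO -> H2 + CO: two C-H broken, one H-H formed
bondChanges <- function(reactant, product) {
  stopifnot(is(reactant, "MolecularGraph"), is(product, "MolecularGraph"))
  if (nAtoms(reactant) != nAtoms(product) ||
      !identical(reactant@atomicNumbers, product@atomicNumbers))
    stop("atom mapping error: reactant and product must list the same atoms ",
         "in the same order", call. = FALSE)
  z <- reactant@atomicNumbers
  diffm <- product@adjacency - reactant@adjacency
  counts <- stats::setNames(numeric(20L), bondChangeNames())
  idx <- which(upper.tri(diffm) & diffm != 0, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      sign_chr <- if (diffm[i, j] > 0) "+" else "-"
      nm <- paste0("bonds.", sign_chr, .pairLabel(z[i], z[j]))
      counts[nm] <- counts[nm] + 1
    }
  }
  counts
}
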