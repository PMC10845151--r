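## Semiempirical (PM7-style) descriptors and the regression target.

#' Create an SQMSpecies
#'
#' @param energy electronic energy / heat of formation, kcal/mol (one
#'   consistent scale within a dataset).
#' @param zpe zero-point vibrational energy, kcal/mol.
#' @param frequencies signed harmonic wavenumbers, cm^-1 (a transition state
#'   carries exactly one negative entry).
#' @param homo,lumo frontier orbital energies, eV.
#' @param bondOrders symmetric bond-order matrix.
#' @param selfPolarizability summed atomic self-polarizability.
#' @param geometry the species \linkS4class{Geometry}.
#' @return An \linkS4class{SQMSpecies}.
#' @export
SQMSpecies <- function(energy, zpe, frequencies, homo, lumo, bondOrders,
                       selfPolarizability, geometry) {
  if (is.finite(homo) && is.finite(lumo) && lumo < homo)
    warning("lumo below homo; check orbital energies", call. = FALSE)
  new("SQMSpecies", energy = as.numeric(energy), zpe = as.numeric(zpe),
      frequencies = as.numeric(frequencies), homo = as.numeric(homo),
      lumo = as.numeric(lumo), bondOrders = unname(as.matrix(bondOrders)),
      selfPolarizability = as.numeric(selfPolarizability),
      geometry = geometry)
}

#' Create a ReactionRecord
#'
#' @param id record identifier.
#' @param reactant,ts,product \linkS4class{SQMSpecies} objects.
#' @param bhDft reference barrier height, kcal/mol.
#' @param smilesReactant,smilesProduct SMILES strings (dot-separated for
#'   multi-fragment species).
#' @return A \linkS4class{ReactionRecord}.
#' @export
ReactionRecord <- function(id, reactant, ts, product, bhDft,
                           smilesReactant, smilesProduct) {
  new("ReactionRecord", id = as.character(id), reactant = reactant, ts = ts,
      product = product, bhDft = as.numeric(bhDft),
      smilesReactant = as.character(smilesReactant),
      smilesProduct = as.character(smilesProduct))
}

#' Barrier height from reactant and transition state
#'
#' `(E_TS + ZPE_TS) - (E_R + ZPE_R)` in kcal/mol: the 0 K activation energy
#' including zero-point energies. Negative values are allowed (submerged
#' barriers on the low-level surface) but flagged with a warning.
#'
#' @param reactant,ts \linkS4class{SQMSpecies} objects.
#' @return numeric(1), kcal/mol.
#' @export
barrierHeight <- function(reactant, ts) {
  bh <- (ts@energy + ts@zpe) - (reactant@energy + reactant@zpe)
  if (bh < 0) warning("negative barrier height (", format(bh), " kcal/mol)",
                      call. = FALSE)
  bh
}

#' Regression target of a record
#'
#' Delta = BH_DFT - BH_PM7, the correction the models learn.
#'
#' @param record a \linkS4class{ReactionRecord}.
#' @return numeric(1), kcal/mol.
#' @export
reactionTarget <- function(record) {
  record@bhDft - barrierHeight(record@reactant, record@ts)
}

#' Rate-constant proxy e^(-BH)
#'
#' The bare exponential of the (numerical, kcal/mol) barrier height, a rough
#' monotone proxy for the rate constant. No kT scaling is applied: the
#' exponent is taken on the raw kcal/mol value, so the proxy is unit-bearing
#' by construction. Barriers below -50 are clamped to avoid overflow.
#'
#' @param bh barrier height(s), kcal/mol.
#' @return exp(-bh); in (0, 1] for non-negative barriers.
#' @export
rateProxy <- function(bh) {
  exp(-pmax(bh, -50))
}

#' Koopmans hardness and electronegativity
#'
#' From frontier-orbital energies: hardness eta = (e_LUMO - e_HOMO) / 2 and
#' Mulliken electronegativity alpha = -(e_LUMO + e_HOMO) / 2.
#'
#' @param homo,lumo orbital energies, eV.
#' @return Named numeric vector `c(eta = ..., alpha = ...)`, eV.
#' @export
#' @examples
#' koopmans(homo = -9, lumo = 1)  # eta 5, alpha 4
koopmans <- function(homo, lumo) {
  stopifnot(is.finite(homo), is.finite(lumo))
  c(eta = (lumo - homo) / 2, alpha = -(lumo + homo) / 2)
}

#' Fixed-width bond-order eigenvalue vector
#'
#' Eigenvalues of the symmetric bond-order matrix, sorted descending, then
#' truncated or zero-padded to length `k` so feature vectors have constant
#' width across molecule sizes (absent atoms contribute zero bond order).
#'
#' @param bond_orders symmetric numeric matrix.
#' @param k output length (default 10).
#' @return numeric(k).
#' @export
bondOrderEigenvalues <- function(bond_orders, k = 10L) {
  bond_orders <- unname(as.matrix(bond_orders))
  if (!isSymmetric(bond_orders))
    stop("bond-order matrix must be symmetric", call. = FALSE)
  ev <- sort(eigen(bond_orders, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  out <- numeric(k)
  m <- min(k, length(ev))
  out[seq_len(m)] <- ev[seq_len(m)]
  out
}

#' Semiempirical descriptor vector for one reaction (X_PM7 family)
#'
#' Assembles, from the low-level results of a curated record: the barrier
#' height and its rate proxy e^(-BH); the absolute imaginary TS wavenumber;
#' the three pairwise ZPE differences among reactant, TS and product; the
#' Koopmans hardness and electronegativity at the TS; the reactant-product
#' self-polarizability difference; the low-level reaction energy
#' `Delta E_r = E_P - E_R`; and `k` eigenvalues of the TS bond-order matrix.
#'
#' @param record a \linkS4class{ReactionRecord}.
#' @param k_bond_eigs number of bond-order eigenvalues kept (default 10).
#' @return Named numeric vector, names `pm7.<descriptor>`.
#' @export
sqmFeatures <- function(record, k_bond_eigs = 10L) {
  stopifnot(is(record, "ReactionRecord"))
  ts <- record@ts; r <- record@reactant; p <- record@product
  imag <- ts@frequencies[ts@frequencies < 0]
  if (length(imag) != 1L)
    stop("record error: transition state must carry exactly one imaginary ",
         "frequency (found ", length(imag), ")", call. = FALSE)
  bh <- suppressWarnings(barrierHeight(r, ts))
  ka <- koopmans(ts@homo, ts@lumo)
  boe <- bondOrderEigenvalues(ts@bondOrders, k_bond_eigs)
  vals <- c(
    bh_pm7     = bh,
    rate_proxy = rateProxy(bh),
    nu1_ts     = abs(imag),
    dzpe_ts_r  = ts@zpe - r@zpe,
    dzpe_p_r   = p@zpe - r@zpe,
    dzpe_ts_p  = ts@zpe - p@zpe,
    eta_ts     = unname(ka["eta"]),
    alpha_ts   = unname(ka["alpha"]),
    dpol       = r@selfPolarizability - p@selfPolarizability,
    de_r       = p@energy - r@energy,
    stats::setNames(boe, paste0("bo_eig", seq_along(boe)))
  )
  names(vals) <- paste0("pm7.", names(vals))
  vals
}
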