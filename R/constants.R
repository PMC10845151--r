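## Element tables and pinned physical constants.
##
## Covalent radii (Angstrom) are the Cordero et al. single-bond values for the
## CHNO chemistry this package targets; atomic masses are the standard atomic
## weights. Physical constants are CODATA-2018 exact/recommended values,
## hard-coded so thermochemistry results are bit-reproducible across machines.

.ELEMENTS <- data.frame(
  symbol = c("H", "C", "N", "O"),
  number = c(1L, 6L, 7L, 8L),
  r_cov  = c(0.31, 0.76, 0.71, 0.66),   # Angstrom
  mass   = c(1.008, 12.011, 14.007, 15.999),  # amu
  # maximum standard valence, used by the synthetic generator
  valence = c(1L, 4L, 3L, 2L),
  stringsAsFactors = FALSE
)
rownames(.ELEMENTS) <- .ELEMENTS$symbol

.CONST <- list(
  h      = 6.62607015e-34,    # J s (exact)
  kB     = 1.380649e-23,      # J / K (exact)
  c_cm   = 2.99792458e10,     # cm / s (exact)
  NA_    = 6.02214076e23,     # 1 / mol (exact)
  amu    = 1.66053906660e-27, # kg
  atm    = 101325,            # Pa (exact)
  R_kcal = 1.987204258640832e-3, # kcal / (mol K) = 8.31446261815324 / 4184
  # pinned wavenumber -> kcal/mol conversion used for ZPE
  cm1_to_kcal = 2.85914e-3
)

#' Supported elements
#'
#' Returns the element table used throughout the package: symbol, atomic
#' number, covalent radius (Angstrom), atomic mass (amu) and standard valence.
#' The package targets gas-phase CHNO chemistry, so the table covers H, C, N
#' and O.
#'
#' @return A data.frame with one row per supported element.
#' @export
#' @examples
#' supportedElements()
supportedElements <- function() .ELEMENTS

.checkSymbols <- function(symbols) {
  bad <- setdiff(unique(symbols), .ELEMENTS$symbol)
  if (length(bad) > 0L)
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(.ELEMENTS$symbol, collapse = ", "), ")",
         call. = FALSE)
  invisible(TRUE)
}

.atomicNumbers <- function(symbols) {
  .checkSymbols(symbols)
  .ELEMENTS[symbols, "number"]
}

.covalentRadii <- function(symbols) {
  .checkSymbols(symbols)
  .ELEMENTS[symbols, "r_cov"]
}

.atomicMasses <- function(symbols) {
  .checkSymbols(symbols)
  .ELEMENTS[symbols, "mass"]
}

.symbolsFromNumbers <- function(z) {
  idx <- match(z, .ELEMENTS$number)
  if (anyNA(idx)) stop("unsupported atomic number(s): ",
                       paste(z[is.na(idx)], collapse = ", "), call. = FALSE)
  .ELEMENTS$symbol[idx]
}
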