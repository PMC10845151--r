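## Rigid-rotor / harmonic-oscillator ideal-gas thermochemistry.
##
## Standard closed forms: translational partition function from the molecular
## mass at the 1 atm standard state, rigid-rotor rotational term from the
## principal moments of inertia (linear and monatomic species handled),
## harmonic-oscillator vibrational term over the positive wavenumbers, and a
## spin-degeneracy electronic term. Physical constants are pinned (CODATA) so
## results are bit-reproducible.

#' Scale harmonic frequencies
#'
#' Element-wise multiplication by a published scaling factor (e.g. 0.9914 for
#' wB97X-D-style frequencies). Imaginary (negative) entries are scaled too but
#' are never used in thermal sums.
#'
#' @param freqs signed wavenumbers, cm^-1.
#' @param factor scaling factor in (0.8, 1.1).
#' @return Scaled wavenumbers.
#' @export
scaleFrequencies <- function(freqs, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0.8 ||
      factor >= 1.1)
    stop("scaling factor must lie in (0.8, 1.1)", call. = FALSE)
  freqs * factor
}

#' Zero-point vibrational energy
#'
#' `sum(h c nu_i / 2)` over positive wavenumbers, using the pinned conversion
#' 1 cm^-1 = 2.85914e-3 kcal/mol. The caller must exclude the imaginary mode
#' of a transition state first: negative input is an error.
#'
#' @param freqs wavenumbers, cm^-1; all > 0 (empty vector gives 0).
#' @return numeric(1), kcal/mol.
#' @export
#' @examples
#' zpe(1000)  # 1.42957 kcal/mol
zpe <- function(freqs) {
  if (length(freqs) == 0L) return(0)
  if (any(freqs <= 0))
    stop("zpe requires positive frequencies; exclude imaginary modes first",
         call. = FALSE)
  sum(freqs) / 2 * .CONST$cm1_to_kcal
}

#' Thermochemistry input for one species
#'
#' @param geometry a \linkS4class{Geometry}.
#' @param frequencies signed wavenumbers, cm^-1 (imaginary modes are excluded
#'   from all thermal sums and from the ZPE).
#' @param electronic_energy kcal/mol.
#' @param multiplicity spin multiplicity (default 1).
#' @param symmetry_number rotational symmetry number (default 1).
#' @return A list of class `thermoInput`.
#' @export
thermoInput <- function(geometry, frequencies, electronic_energy,
                        multiplicity = 1L, symmetry_number = 1L) {
  stopifnot(is(geometry, "Geometry"), multiplicity >= 1L,
            symmetry_number >= 1L)
  structure(list(geometry = geometry, frequencies = as.numeric(frequencies),
                 electronic_energy = as.numeric(electronic_energy),
                 multiplicity = as.integer(multiplicity),
                 symmetry_number = as.integer(symmetry_number)),
            class = "thermoInput")
}

## Principal moments of inertia in kg m^2.
.momentsOfInertia <- function(geom) {
  m <- .atomicMasses(geom@symbols) * .CONST$amu       # kg
  x <- geom@coords * 1e-10                            # m
  com <- colSums(x * m) / sum(m)
  x <- sweep(x, 2, com)
  Ixx <- sum(m * (x[, 2]^2 + x[, 3]^2))
  Iyy <- sum(m * (x[, 1]^2 + x[, 3]^2))
  Izz <- sum(m * (x[, 1]^2 + x[, 2]^2))
  Ixy <- -sum(m * x[, 1] * x[, 2])
  Ixz <- -sum(m * x[, 1] * x[, 3])
  Iyz <- -sum(m * x[, 2] * x[, 3])
  I <- matrix(c(Ixx, Ixy, Ixz, Ixy, Iyy, Iyz, Ixz, Iyz, Izz), 3, 3)
  sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
}

#' RRHO Gibbs energy at temperature T
#'
#' Returns the Gibbs energy `g = electronic_energy + zpe + h_corr - T s_total`
#' (units reconciled: entropies in cal/(mol K)), along with the pieces.
#' `h_corr` is the thermal enthalpy correction above the ZPE (translation
#' 3/2 RT + PV, rotation, vibration); `s_total` sums translational
#' (Sackur-Tetrode), rotational, vibrational and electronic entropies. A
#' single atom has translational and electronic terms only.
#'
#' @param inp a \code{\link{thermoInput}}.
#' @param T_K temperature in K (> 0).
#' @param P_atm pressure in atm (default 1, the standard state).
#' @return List with `T`, `zpe` and `h_corr` (kcal/mol), `s_total`
#'   (cal/(mol K)) and `g` (kcal/mol).
#' @export
gibbs <- function(inp, T_K, P_atm = 1) {
  stopifnot(inherits(inp, "thermoInput"), T_K > 0)
  k <- .CONST
  R <- k$R_kcal                      # kcal / (mol K)
  geom <- inp$geometry
  n <- nAtoms(geom)
  mass_kg <- sum(.atomicMasses(geom@symbols)) * k$amu
  P <- P_atm * k$atm

  # translation: Sackur-Tetrode, V = kB T / P per molecule
  q_trans <- (2 * pi * mass_kg * k$kB * T_K / k$h^2)^1.5 * (k$kB * T_K / P)
  s_trans <- R * (log(q_trans) + 2.5)
  h_trans <- 2.5 * R * T_K           # 3/2 RT + PV

  # rotation
  if (n == 1L) {
    s_rot <- 0; h_rot <- 0
  } else {
    I <- .momentsOfInertia(geom)
    linear <- I[1] / I[3] < 1e-8
    if (linear) {
      q_rot <- 8 * pi^2 * I[3] * k$kB * T_K / (inp$symmetry_number * k$h^2)
      s_rot <- R * (log(q_rot) + 1)
      h_rot <- R * T_K
    } else {
      q_rot <- sqrt(pi * prod(I)) / inp$symmetry_number *
        (8 * pi^2 * k$kB * T_K / k$h^2)^1.5
      s_rot <- R * (log(q_rot) + 1.5)
      h_rot <- 1.5 * R * T_K
    }
  }

  # vibration (above the ZPE), positive modes only
  nu <- inp$frequencies[inp$frequencies > 0]
  if (length(nu) > 0L) {
    theta <- k$h * k$c_cm * nu / k$kB          # vibrational temperatures, K
    x <- theta / T_K
    h_vib <- R * sum(theta / (exp(x) - 1))
    s_vib <- R * sum(x / (exp(x) - 1) - log1p(-exp(-x)))
  } else { h_vib <- 0; s_vib <- 0 }

  s_elec <- R * log(inp$multiplicity)

  zpe_val <- zpe(nu)
  h_corr <- h_trans + h_rot + h_vib
  s_total <- (s_trans + s_rot + s_vib + s_elec) * 1000  # cal / (mol K)
  g <- inp$electronic_energy + zpe_val + h_corr - T_K * s_total / 1000
  list(T = T_K, zpe = zpe_val, h_corr = h_corr, s_total = s_total, g = g)
}

#' Gibbs energy of activation
#'
#' `G(TS, T) - G(reactant, T)` in kcal/mol. The transition-state input must
#' already have its imaginary mode excluded (negative frequencies are ignored
#' by \code{\link{gibbs}} in all thermal sums).
#'
#' @param reactant,ts \code{\link{thermoInput}} objects.
#' @param T_K one or more temperatures in K (default the 300/500/1000 batch).
#' @param P_atm standard-state pressure, atm.
#' @return Named numeric vector of Delta-G-of-activation values, one per
#'   temperature.
#' @export
deltaGActivation <- function(reactant, ts, T_K = c(300, 500, 1000),
                             P_atm = 1) {
  vals <- vapply(T_K, function(tt)
    gibbs(ts, tt, P_atm)$g - gibbs(reactant, tt, P_atm)$g, numeric(1))
  stats::setNames(vals, paste0("T", T_K))
}
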