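#' @title Units and physical constants
#' @description
#' All quantities in the package use a fixed unit system: lengths in
#' Angstrom (Å), time in femtoseconds (fs), masses in unified atomic mass
#' units (amu), energies in kJ/mol and temperatures in Kelvin.
#'
#' With these units the "internal" energy unit amu·Å²/fs² equals exactly
#' 1e4 kJ/mol (because 1 amu = 1 g/mol / N_A), so accelerations follow from
#' forces as `a = F * .F2A / m` with `.F2A = 1e-4`.
#' @name units
#' @keywords internal
NULL

## Boltzmann constant, kJ/mol/K
.kB <- 0.0083144621

## kJ/mol -> amu Angstrom^2 / fs^2 (exact)
.F2A <- 1e-4

## amu Angstrom^2/fs^2 -> kJ/mol (exact)
.E2KJ <- 1e4

## Coulomb constant, kJ/mol * Angstrom / e^2
.KE <- 138.935458

## standard atomic weights (amu) for the elements the coarse model uses
.ATOMIC_MASS <- c(
  H  = 1.008,
  C  = 12.011,
  N  = 14.007,
  O  = 15.999,
  Na = 22.98976928,
  P  = 30.973761998,
  Cl = 35.45,
  Hg = 200.592
)

#' Standard atomic mass lookup
#'
#' @param element character vector of element symbols (e.g. `"Hg"`).
#' @return numeric vector of masses in amu.
#' @examples
#' atomic_mass(c("N", "H"))
#' @export
atomic_mass <- function(element) {
  m <- .ATOMIC_MASS[element]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Reduced mass of an atom pair
#'
#' `mu_ij = m_i * m_j / (m_i + m_j)`, the mass that weights each pair inside
#' the dynamic-distance collective variable.
#'
#' @param m1,m2 masses in amu (vectorized).
#' @return reduced masses in amu.
#' @examples
#' reduced_mass(atomic_mass("N"), atomic_mass("H"))  # 0.94033...
#' @export
reduced_mass <- function(m1, m2) {
  stopifnot(all(m1 > 0), all(m2 > 0))
  m1 * m2 / (m1 + m2)
}
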