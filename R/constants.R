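#' @name torsconf-constants
#' @title Physical constants and element data
#'
#' @description
#' All physical constants used by the package are CODATA-2018 exact or
#' recommended values, centralized here so that every unit conversion is
#' traceable to a single definition.  Working units at all interfaces are
#' kcal/mol (energy), Angstrom (length), amu (mass), cm^-1 (wavenumber),
#' Kelvin (temperature) and degrees (angles).
#'
#' @keywords internal
NULL

# CODATA-2018
.const <- list(
  h      = 6.62607015e-34,     # Planck, J s (exact)
  hbar   = 6.62607015e-34 / (2 * pi),
  kB     = 1.380649e-23,       # Boltzmann, J/K (exact)
  c      = 2.99792458e8,       # speed of light, m/s (exact)
  NA_    = 6.02214076e23,      # Avogadro, 1/mol (exact)
  amu    = 1.66053906660e-27,  # atomic mass constant, kg
  cal    = 4.184               # thermochemical calorie, J (exact)
)

# gas constant in kcal/(mol K)
.const$R_kcal <- .const$kB * .const$NA_ / (.const$cal * 1000)

# 1 kcal/mol expressed in cm^-1 (about 349.755)
.const$kcal_per_mol_in_wavenumber <-
  (.const$cal * 1000 / .const$NA_) / (.const$h * .const$c * 100)

# sqrt(eigenvalue in kcal/mol/A^2/amu) -> wavenumber cm^-1 (about 108.59)
.const$freq_factor <-
  sqrt(.const$cal * 1000 / (.const$NA_ * .const$amu * 1e-20)) /
  (2 * pi * .const$c * 100)

# Cordero (2008) single-bond covalent radii, Angstrom (sp3 value for C)
.covalent_radii <- c(
  H = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05,
  Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Br = 1.20, I = 1.39
)

# standard atomic weights, amu (IUPAC 2021 abridged)
.atomic_masses <- c(
  H = 1.008, He = 4.0026,
  Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305, Al = 26.982,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95, K = 39.098,
  Ca = 40.078, Br = 79.904, I = 126.90
)

element_radius <- function(elements) {
  r <- .covalent_radii[elements]
  if (anyNA(r)) {
    bad <- unique(elements[is.na(r)])
    stop("no covalent radius for element(s): ", paste(bad, collapse = ", "))
  }
  unname(r)
}

element_mass <- function(elements) {
  m <- .atomic_masses[elements]
  if (anyNA(m)) {
    bad <- unique(elements[is.na(m)])
    stop("no atomic mass for element(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}
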