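#' Physical constants and unit conversions
#'
#' Fixed constants used throughout the package. Internal mechanical units are
#' kcal/mol, Angstrom and elementary charge; observable-facing units are bar,
#' nm, ps, K, g/L, kJ/mol and mN/m, with conversions applied at the interfaces.
#'
#' @format A list with elements:
#' \describe{
#'   \item{R_J}{Gas constant, 8.314462618 J/(mol K).}
#'   \item{kB_J}{Boltzmann constant, 1.380649e-23 J/K.}
#'   \item{P_standard_Pa}{Standard-state pressure, 1 atm = 101325 Pa.}
#'   \item{coulomb_kcal}{Coulomb prefactor, 332.0637 kcal A/(mol e^2).}
#'   \item{molar_mass_cyclohexene}{82.143 g/mol.}
#'   \item{bar_nm_to_mN_m}{1 bar nm = 0.1 mN/m.}
#'   \item{A2_ps_to_cm2_s}{1 A^2/ps = 1e-4 cm^2/s.}
#' }
#' @export
physical_constants <- list(
  R_J            = 8.314462618,
  kB_J           = 1.380649e-23,
  P_standard_Pa  = 101325,
  coulomb_kcal   = 332.0637,
  molar_mass_cyclohexene = 82.143,
  bar_nm_to_mN_m = 0.1,
  A2_ps_to_cm2_s = 1e-4,
  avogadro       = 6.02214076e23
)

# atomic masses (g/mol) for center-of-mass work; extend as elements appear
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  M = 0.0   # massless virtual site used by simple solvent surrogates
)

atomic_mass <- function(element) {
  m <- .atomic_masses[element]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
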