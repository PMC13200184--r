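#' Vaporization free energy from coexistence densities
#'
#' \deqn{\Delta G_{vap} = -RT \ln(\rho_g/\rho_l)}
#' the free-energy difference between gas and liquid at coexistence,
#' assuming ideal vapor.
#'
#' @param rho_g,rho_l vapor and liquid densities (g/L), positive.
#' @param temperature temperature (K).
#' @return Delta G_vap (kJ/mol).
#' @examples
#' dgvap_from_densities(0.394, 811, 298.15)  # ~18.9 kJ/mol
#' @export
dgvap_from_densities <- function(rho_g, rho_l, temperature) {
  if (any(rho_g <= 0) || any(rho_l <= 0)) stop("densities must be positive")
  -physical_constants$R_J * temperature * log(rho_g / rho_l) / 1000
}

#' Vapor pressure from the vaporization free energy
#'
#' \deqn{\ln(P_g/P^\circ) = \ln\!\left(\frac{RT\rho_l}{P^\circ}\right) -
#'   \frac{\Delta G_{vap}}{RT}}
#' with the liquid density converted to molar density through the molar
#' mass and ideal-gas behaviour assumed for the vapor. Composing this with
#' [dgvap_from_densities()] returns exactly the ideal-gas pressure
#' \eqn{P = \rho_g R T / M}.
#'
#' @param dG_vap vaporization free energy (kJ/mol).
#' @param rho_l liquid density (g/L).
#' @param temperature temperature (K).
#' @param molar_mass molar mass (g/mol).
#' @param P_standard standard-state pressure (Pa); 1 atm by default.
#' @return vapor pressure (bar).
#' @export
vapor_pressure_from_dgvap <- function(dG_vap, rho_l, temperature,
                                      molar_mass =
                                        physical_constants$molar_mass_cyclohexene,
                                      P_standard =
                                        physical_constants$P_standard_Pa) {
  R <- physical_constants$R_J
  # molar density mol/m^3: rho_l g/L -> g/m^3 (x1000) / (g/mol)
  c_l <- rho_l * 1000 / molar_mass
  lnPP0 <- log(R * temperature * c_l / P_standard) -
    dG_vap * 1000 / (R * temperature)
  exp(lnPP0) * P_standard / 1e5
}

#' Boiling point by the free-energy method
#'
#' Converts (T, Delta G_vap, rho_l) points into \eqn{\ln(P_g/P^\circ)} via
#' the ideal-gas route, fits a straight line in 1/T (the Gibbs-Helmholtz
#' correlation), and returns the temperature where the line crosses
#' \eqn{\ln(P/P_b) = 0}, i.e. where the vapor pressure reaches the boiling
#' threshold.
#'
#' @param points data.frame with columns `T` (K), `dG_vap` (kJ/mol),
#'   `rho_l` (g/L); at least 2 distinct temperatures.
#' @param molar_mass molar mass (g/mol).
#' @param P_boil boiling threshold pressure (Pa); 1 atm by default, with
#'   1 bar (1e5) the common alternative convention.
#' @return boiling temperature (K).
#' @export
boiling_point_free_energy <- function(points,
                                      molar_mass =
                                        physical_constants$molar_mass_cyclohexene,
                                      P_boil =
                                        physical_constants$P_standard_Pa) {
  stopifnot(all(c("T", "dG_vap", "rho_l") %in% names(points)))
  if (nrow(points) < 2 || length(unique(points$T)) < 2)
    stop("need at least 2 distinct temperatures (degenerate fit)")
  P_bar <- vapor_pressure_from_dgvap(points$dG_vap, points$rho_l, points$T,
                                     molar_mass = molar_mass)
  y <- log(P_bar * 1e5 / P_boil)
  x <- 1 / points$T
  co <- stats::coef(stats::lm(y ~ x))
  slope <- co[[2]]; intercept <- co[[1]]
  if (abs(slope) < 1e-12) {
    if (abs(intercept) < 1e-12) stop("degenerate fit: line identically zero")
    stop("no-crossing error: zero slope with nonzero intercept")
  }
  x0 <- -intercept / slope
  if (x0 <= 0) stop("no-crossing error: fit crosses at non-physical 1/T")
  1 / x0
}

#' Stokes-Einstein hydrodynamic radius
#'
#' \deqn{r = \frac{k_B T}{6 \pi \eta D}}
#'
#' @param D diffusion constant (cm^2/s).
#' @param eta shear viscosity (mPa s).
#' @param temperature temperature (K).
#' @return hydrodynamic radius (Angstrom).
#' @examples
#' stokes_einstein_radius(1.9e-5, 0.66, 298.15)  # ~1.74 A
#' @export
stokes_einstein_radius <- function(D, eta, temperature) {
  if (any(D <= 0) || any(eta <= 0) || any(temperature <= 0))
    stop("D, eta and temperature must be positive")
  D_SI <- D * 1e-4       # cm^2/s -> m^2/s
  eta_SI <- eta * 1e-3   # mPa s -> Pa s
  r_m <- physical_constants$kB_J * temperature / (6 * pi * eta_SI * D_SI)
  r_m * 1e10
}

#' Solvation free energy by the thermodynamic cycle
#'
#' \deqn{\Delta G_{sol} = \Delta G_{vap} + \Delta G_{hyd}}
#' (liquid -> gas -> hydrated); uncertainties combine in quadrature.
#'
#' @param dG_vap,dG_hyd free energies (kJ/mol).
#' @param se_vap,se_hyd their 1-sigma uncertainties (kJ/mol).
#' @return named numeric `c(dG_sol, se)` (kJ/mol).
#' @examples
#' solvation_free_energy(18.2, 3.8)  # 22.0 kJ/mol
#' @export
solvation_free_energy <- function(dG_vap, dG_hyd, se_vap = 0, se_hyd = 0) {
  c(dG_sol = dG_vap + dG_hyd, se = sqrt(se_vap^2 + se_hyd^2))
}

#' Enthalpy of vaporization from mean potential energies
#'
#' \deqn{\Delta H_{vap} = \langle U\rangle_{gas} - \langle U\rangle_{liq}
#'   + RT}
#' per molecule, with the ideal-gas PV term.
#'
#' @param U_gas,U_liq mean potential energy per molecule (kJ/mol).
#' @param temperature temperature (K).
#' @return Delta H_vap (kJ/mol).
#' @export
enthalpy_of_vaporization <- function(U_gas, U_liq, temperature) {
  U_gas - U_liq + physical_constants$R_J * temperature / 1000
}

#' Isothermal compressibility from volume fluctuations
#'
#' \deqn{\kappa_T = \frac{\langle \delta V^2\rangle}{k_B T
#'   \langle V\rangle}}
#' the equilibrium NPT fluctuation estimator.
#'
#' @param volumes volume time series (nm^3).
#' @param temperature temperature (K).
#' @return kappa_T (1/MPa).
#' @export
isothermal_compressibility <- function(volumes, temperature) {
  if (length(volumes) < 2) stop("need at least 2 volume samples")
  V_mean <- mean(volumes)
  var_nm6 <- stats::var(volumes) * (length(volumes) - 1) / length(volumes)
  kap_Pa <- var_nm6 * 1e-54 /
    (physical_constants$kB_J * temperature * V_mean * 1e-27)
  kap_Pa * 1e6
}

#' Property table
#'
#' Named property estimates with 1-sigma uncertainties, units and model
#' tags, the package's final report object.
#'
#' @param rows data.frame with columns `property`, `estimate`, `se`,
#'   `units`, `model` (tag such as `"N"`, `"H"`, `"M"`).
#' @return An object of class `property_table` (also a data.frame).
#' @export
property_table <- function(rows) {
  need <- c("property", "estimate", "se", "units", "model")
  stopifnot(all(need %in% names(rows)))
  known_units <- c("g/L", "kJ/mol", "mN/m", "K", "bar", "cm^2/s", "mPa s",
                   "1/MPa", "A", "")
  bad <- setdiff(unique(rows$units), known_units)
  if (length(bad)) stop("unknown units: ", paste(bad, collapse = ", "))
  structure(rows[, need], class = c("property_table", "data.frame"))
}

#' @export
print.property_table <- function(x, ...) {
  cat("property_table (", nrow(x), " properties, 1-sigma uncertainties)\n",
      sep = "")
  for (i in seq_len(nrow(x))) {
    se_txt <- if (is.finite(x$se[i]) && x$se[i] > 0)
      sprintf(" +/- %.3g", x$se[i]) else ""
    cat(sprintf("  %-12s (%s) %.6g%s %s\n", x$property[i], x$model[i],
                x$estimate[i], se_txt, x$units[i]))
  }
  invisible(x)
}
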