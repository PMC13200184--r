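#' Pipeline run configuration
#'
#' Validates and completes the configuration of [run_pipeline()]. Unknown
#' keys are rejected; every tunable exposed by the analysis stages has a
#' default here, so a minimal config is just a seed and a stage selection.
#'
#' @param ... configuration keys (or a single named list). Available keys
#'   and defaults:
#' \describe{
#'   \item{seed}{integer master seed (1).}
#'   \item{stages}{character vector of stages to run, in dependency order
#'     from `c("fit_ff", "slab", "critical", "antoine", "boil",
#'     "transport", "solubility")` (all).}
#'   \item{gamma_true, L_Z}{slab-scenario surface tension (mN/m) and box
#'     normal length (nm): 25.4, 12.}
#'   \item{rho_l, rho_g}{slab densities (g/L): 800, 4.}
#'   \item{T_C, rho_C, amplitudes, D_terms}{coexistence-scenario truths:
#'     513 K, 303.9 g/L, the four standard amplitudes, the two diameter
#'     coefficients.}
#'   \item{coex_temperatures}{coexistence sampling temperatures (K):
#'     six from 360 to 460.}
#'   \item{antoine_truth}{Antoine ground truth `c(A, B, C)`, P in bar.}
#'   \item{antoine_window_low, antoine_window_high}{fit windows (K):
#'     c(360, 440) for the boiling point, c(380, 460) for the critical
#'     pressure.}
#'   \item{tb_pressure}{boiling threshold: `"atm"` (default) or `"bar"`.}
#'   \item{fe_temperatures}{free-energy-method temperatures (K):
#'     c(298.15, 344, 364).}
#'   \item{D_true, kappa_T}{transport truths: 0.99e-5 cm^2/s,
#'     1.0366e-3 1/MPa.}
#'   \item{dG_vap, dG_hyd, dG_vap_se, dG_hyd_se}{solubility-cycle inputs
#'     (kJ/mol): 18.2, 3.8, 0.2, 0.3.}
#'   \item{fit_n_configs, fit_n_molecules, fit_sigma}{force-matching
#'     scenario size and noise: 8, 5, 0.}
#'   \item{interface_threshold, core_fraction, vapor_buffer}{slab density
#'     protocol tunables: 0.5, 0.5, 1 nm.}
#'   \item{model_tag}{tag for report rows: `"M"`.}
#' }
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  defaults <- list(
    seed = 1L,
    stages = c("fit_ff", "slab", "critical", "antoine", "boil",
               "transport", "solubility"),
    gamma_true = 25.4, L_Z = 12,
    rho_l = 800, rho_g = 4,
    T_C = 513, rho_C = 303.9,
    amplitudes = c(579.5, 4637.6, -8973.0, 5706.9),
    D_terms = c(0, 1200),
    coex_temperatures = seq(360, 460, by = 20),
    antoine_truth = c(A = 5.7, B = -612.2, C = -236.3),
    antoine_window_low = c(360, 440),
    antoine_window_high = c(380, 460),
    tb_pressure = "atm",
    fe_temperatures = c(298.15, 344, 364),
    D_true = 0.99e-5, kappa_T = 1.0366e-3,
    dG_vap = 18.2, dG_hyd = 3.8, dG_vap_se = 0.2, dG_hyd_se = 0.3,
    fit_n_configs = 8, fit_n_molecules = 5, fit_sigma = 0,
    interface_threshold = 0.5, core_fraction = 0.5, vapor_buffer = 1,
    model_tag = "M"
  )
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  bad <- setdiff(cfg$stages, defaults$stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!cfg$tb_pressure %in% c("atm", "bar"))
    stop("tb_pressure must be 'atm' or 'bar'")
  structure(cfg, class = "run_config")
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Executes the selected stages in dependency order on seeded synthetic
#' scenarios with known ground truth and assembles a property report:
#' force-field fit quality, surface tension and coexistence densities from
#' slab observables, the critical point from Wegner/rectilinear fits, the
#' boiling point by both the Antoine and the free-energy route, transport
#' coefficients, and the solvation free-energy cycle. Rerunning with an
#' identical config reproduces the report bit for bit.
#'
#' @param config a [run_config()] (or arguments for one).
#' @return a [property_table()]; the resolved config, seed and per-stage
#'   log in attributes `"config"`, `"provenance"`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  seed <- config$seed
  rows <- list()
  log <- list()
  add <- function(property, estimate, se, units) {
    rows[[length(rows) + 1L]] <<- data.frame(
      property = property, estimate = unname(estimate), se = unname(se),
      units = units, model = config$model_tag)
  }
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, detail = paste0(...))
  }
  if ("fit_ff" %in% config$stages) {
    recs <- gen_training_set(seed, n_configs = config$fit_n_configs,
                             n_molecules = config$fit_n_molecules,
                             phase = "neat", sigma = config$fit_sigma)
    truth <- attr(recs, "ground_truth")$params
    start <- truth
    start$pairs$A <- start$pairs$A * 1.2
    start$bonds$k <- start$bonds$k * 0.9
    fit <- fit_forcefield(start, recs, default_fit_stages(start),
                          cutoff = 12)
    fm <- fit_metrics(fit, recs)
    add("ff_atomic_rmse", fm$rmse[fm$class == "atomic force"], 0, "")
    add("ff_molforce_rmse", fm$rmse[fm$class == "molecular force"], 0, "")
    add("ff_max_param_err",
        max(abs(c(fit$pairs$A / truth$pairs$A,
                  fit$bonds$k / truth$bonds$k,
                  fit$angles$k / truth$angles$k) - 1)), 0, "")
    note("fit_ff", sprintf("%d training records, max param err %.2g",
                           length(recs), rows[[length(rows)]]$estimate))
  }

  if ("slab" %in% config$stages) {
    ps <- gen_pressure_series(seed, gamma_true = config$gamma_true,
                              L_Z = config$L_Z)
    st <- surface_tension(ps)
    add("gamma", st["gamma"], st["se"], "mN/m")
    prof <- gen_slab_profile(seed, rho_l = config$rho_l,
                             rho_g = config$rho_g, L_Z = config$L_Z)
    cd <- coexistence_densities(prof, config$interface_threshold,
                                config$core_fraction, config$vapor_buffer)
    add("density", cd["rho_l"], 0, "g/L")
    add("rho_g", cd["rho_g"], 0, "g/L")
    note("slab", sprintf("gamma %.2f mN/m, rho_l %.1f g/L",
                         st["gamma"], cd["rho_l"]))
  }

  wfit <- NULL
  if ("critical" %in% config$stages) {
    cc <- gen_coexistence_curve(seed, T_C = config$T_C,
                                amplitudes = config$amplitudes,
                                rho_C = config$rho_C,
                                D_terms = config$D_terms,
                                temperatures = config$coex_temperatures)
    wfit <- fit_wegner(cc)
    rfit <- fit_rectilinear(cc, wfit$T_C)
    add("T_C", wfit$T_C, 0, "K")
    add("rho_C", rfit$rho_C, 0, "g/L")
    vp_hi <- gen_vapor_pressure_curve(
      seed, antoine = config$antoine_truth,
      temperatures = seq(config$antoine_window_high[1],
                         config$antoine_window_high[2], length.out = 6))
    afit_hi <- fit_antoine(vp_hi, config$antoine_window_high)
    P_C <- suppressWarnings(critical_pressure(afit_hi, wfit$T_C))
    add("P_C", P_C, 0, "bar")
    note("critical", sprintf("T_C %.2f K, rho_C %.1f g/L", wfit$T_C,
                             rfit$rho_C))
  }

  afit <- NULL
  if ("antoine" %in% config$stages) {
    vp <- gen_vapor_pressure_curve(
      seed, antoine = config$antoine_truth,
      temperatures = seq(config$antoine_window_low[1],
                         config$antoine_window_low[2], length.out = 6))
    afit <- fit_antoine(vp, config$antoine_window_low)
    P_b <- if (config$tb_pressure == "atm")
      physical_constants$P_standard_Pa / 1e5 else 1
    T_b <- suppressWarnings(antoine_invert(afit, P_b))
    add("T_b_antoine", T_b, 0, "K")
    note("antoine", sprintf("T_b %.2f K at 1 %s", T_b,
                            config$tb_pressure))
  }

  if ("boil" %in% config$stages) {
    # free-energy points consistent with the same Antoine truth: at each T,
    # take P from the truth and back out dG_vap at a fixed liquid density
    tr <- config$antoine_truth
    Tfe <- config$fe_temperatures
    P_bar <- exp(tr[1] + tr[2] / (Tfe + tr[3]))
    rho_l <- config$rho_l
    R <- physical_constants$R_J
    M <- physical_constants$molar_mass_cyclohexene
    rho_g <- P_bar * 1e5 * M / (R * Tfe) / 1000       # g/L, ideal gas
    pts <- data.frame(T = Tfe,
                      dG_vap = dgvap_from_densities(rho_g, rho_l, Tfe),
                      rho_l = rho_l)
    P_boil <- if (config$tb_pressure == "atm")
      physical_constants$P_standard_Pa else 1e5
    T_b_fe <- boiling_point_free_energy(pts, P_boil = P_boil)
    add("T_b_free_energy", T_b_fe, 0, "K")
    note("boil", sprintf("free-energy T_b %.2f K", T_b_fe))
  }

  if ("transport" %in% config$stages) {
    traj <- gen_brownian(seed, D_true = config$D_true)
    msd <- msd_from_trajectory(traj)
    Dfit <- diffusion_from_msd(msd)
    add("D", Dfit["D"], Dfit["se"], "cm^2/s")
    ss <- gen_stress_series(seed)
    eta <- viscosity_green_kubo(ss)
    add("eta", eta["eta"], eta["se"], "mPa s")
    vols <- gen_volume_series(seed, kappa_T = config$kappa_T)
    kap <- isothermal_compressibility(vols,
                                      attr(vols,
                                           "ground_truth")$temperature)
    add("kappa_T", kap, 0, "1/MPa")
    add("r_hydrodynamic",
        stokes_einstein_radius(Dfit[["D"]], eta[["eta"]], 298.15), 0, "A")
    note("transport", sprintf("D %.3g cm^2/s, eta %.3g mPa s",
                              Dfit["D"], eta["eta"]))
  }

  if ("solubility" %in% config$stages) {
    sol <- solvation_free_energy(config$dG_vap, config$dG_hyd,
                                 config$dG_vap_se, config$dG_hyd_se)
    add("dG_sol", sol["dG_sol"], sol["se"], "kJ/mol")
    note("solubility", sprintf("dG_sol %.2f kJ/mol", sol["dG_sol"]))
  }

  out <- if (length(rows)) property_table(do.call(rbind, rows)) else
    property_table(data.frame(property = character(), estimate = numeric(),
                              se = numeric(), units = character(),
                              model = character()))
  attr(out, "config") <- unclass(config)
  attr(out, "provenance") <- list(
    seed = seed,
    stage_log = if (length(log)) do.call(rbind, log) else NULL,
    config_hash = sum(utf8ToInt(paste(deparse(unclass(config)),
                                      collapse = ""))))
  out
}
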