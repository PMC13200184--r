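test_that("Wegner fit recovers the generating critical temperature", {
  cc <- gen_coexistence_curve(1, T_C = 513, noise = 0)
  w <- fit_wegner(cc)
  expect_lt(abs(w$T_C - 513), 0.5)
  expect_rel_equal(w$amplitudes, c(579.5, 4637.6, -8973.0, 5706.9), 1e-3)
  # tau -> 0: fitted difference vanishes at T = T_C
  expect_equal(afmtools:::wegner_eval(0, w$amplitudes), 0)

  # single-term truth: closed-form A0
  cc1 <- gen_coexistence_curve(1, T_C = 513,
                               amplitudes = c(579.5, 0, 0, 0), noise = 0)
  w1 <- fit_wegner(cc1, n_amplitudes = 1)
  tau <- abs(1 - cc1$T / w1$T_C)
  expect_rel_equal(w1$amplitudes[1],
                   mean((cc1$rho_l - cc1$rho_g) / tau^0.325), 1e-3)

  short <- coexistence_curve(T = c(360, 380, 400),
                             rho_l = c(850, 820, 790),
                             rho_g = c(5, 8, 12))
  expect_error(fit_wegner(short), "at least")
})

test_that("rectilinear fit recovers the critical density", {
  cc <- gen_coexistence_curve(2, T_C = 513, rho_C = 303.9,
                              D_terms = c(50, 1300), noise = 0)
  r <- fit_rectilinear(cc, 513)
  expect_equal(r$rho_C, 303.9, tolerance = 1e-6)
  expect_equal(r$D_1ma, 50, tolerance = 1e-4)
  expect_equal(r$D_1, 1300, tolerance = 1e-4)

  # constant diameter: rho_C = c / 2
  cc2 <- coexistence_curve(T = seq(360, 460, 20),
                           rho_l = 500 + seq(300, 200, -20),
                           rho_g = 500 - seq(300, 200, -20))
  r2 <- fit_rectilinear(cc2, 513)
  expect_equal(r2$rho_C, 500, tolerance = 1e-8)
  expect_error(fit_rectilinear(cc, 400), "exceed")
})

test_that("critical temperature is unbiased under 1% noise (leading order)", {
  # the full 4-amplitude expansion is not identifiable from six noisy
  # points (see the methods vignette); the leading-order estimator is
  errs <- sapply(1:50, function(s) {
    cc <- gen_coexistence_curve(s, T_C = 513,
                                amplitudes = c(579.5, 0, 0, 0),
                                noise = 0.01)
    fit_wegner(cc, n_amplitudes = 1)$T_C - 513
  })
  expect_lt(abs(mean(errs)), 2)
})

test_that("Antoine fits recover, evaluate and invert consistently", {
  truth <- c(A = 9.8, B = -2186.0, C = -43.7)
  vp <- gen_vapor_pressure_curve(1, antoine = truth,
                                 temperatures = seq(380, 460, by = 16))
  f <- fit_antoine(vp, c(380, 460))
  expect_rel_equal(c(f$A, f$B, f$C), unname(truth), 1e-4)
  # eval/invert round trip
  T <- seq(385, 455, by = 10)
  expect_equal(antoine_invert(f, antoine_eval(f, T)), T,
               tolerance = 1e-9)

  # closed-form inversion of the printed low-temperature coefficients
  low <- list(A = 5.7, B = -612.2, C = -236.3, T_range = c(360, 440),
              unit = "bar")
  expect_equal(suppressWarnings(antoine_invert(low, 1)),
               -612.2 / -5.7 + 236.3, tolerance = 1e-9)

  # B = 0: constant pressure e^A everywhere
  fb <- list(A = 2, B = 0, C = 10, T_range = c(300, 400), unit = "bar")
  expect_equal(antoine_eval(fb, c(300, 350, 400)), rep(exp(2), 3))

  expect_error(fit_antoine(vapor_pressure_curve(c(380, 400), c(1, 2))),
               "at least 3")
})

test_that("critical pressure evaluates the Antoine fit at T_C", {
  cons <- vapor_pressure_curve(seq(380, 460, 20), rep(3, 5))
  fc <- fit_antoine(cons, c(380, 460))
  expect_equal(critical_pressure(fc, 430), 3, tolerance = 1e-8)

  truth <- c(A = 9.8, B = -2186.0, C = -43.7)
  vp <- gen_vapor_pressure_curve(1, antoine = truth,
                                 temperatures = seq(380, 460, by = 16))
  f <- fit_antoine(vp, c(380, 460))
  expect_warning(pc <- critical_pressure(f, 513), "outside")
  expect_rel_equal(pc, exp(truth[1] + truth[2] / (513 + truth[3])), 1e-3)
})

test_that("vaporization free energy and vapor pressure compose to the ideal-gas law", {
  # worked chain at ambient conditions
  dg <- dgvap_from_densities(0.3944182, 811, 298.15)
  expect_equal(dg, 18.911, tolerance = 1e-3)
  expect_equal(vapor_pressure_from_dgvap(18.911, 811, 298.15), 0.119,
               tolerance = 1e-2)
  expect_equal(dgvap_from_densities(5, 5, 300), 0)

  # property test: Eq-5 composed with Eq-6 is P = rho R T / M exactly
  set.seed(6)
  n <- 1e4
  rho_l <- runif(n, 400, 1200)
  rho_g <- runif(n, 1e-4, 50)
  temp <- runif(n, 200, 600)
  P <- vapor_pressure_from_dgvap(
    dgvap_from_densities(rho_g, rho_l, temp), rho_l, temp)
  M <- physical_constants$molar_mass_cyclohexene
  P_ideal <- rho_g * 1000 / M * physical_constants$R_J * temp / 1e5
  expect_equal(P, P_ideal, tolerance = 1e-12)

  expect_error(dgvap_from_densities(-1, 800, 300), "positive")
})

test_that("free-energy boiling point finds the Clausius-Clapeyron crossing", {
  # construct points on an exact line crossing zero at 1/T = 1/350
  M <- physical_constants$molar_mass_cyclohexene
  R <- physical_constants$R_J
  Ts <- c(300, 330, 360)
  slope <- -4000                       # K
  lnPP0 <- slope * (1 / Ts - 1 / 350)
  P_Pa <- exp(lnPP0) * physical_constants$P_standard_Pa
  rho_l <- 800
  rho_g <- P_Pa * M / (R * Ts) / 1000
  pts <- data.frame(T = Ts,
                    dG_vap = dgvap_from_densities(rho_g, rho_l, Ts),
                    rho_l = rho_l)
  expect_equal(boiling_point_free_energy(pts), 350, tolerance = 1e-6)

  expect_error(boiling_point_free_energy(pts[c(1, 1), ]),
               "distinct temperatures")
})

test_that("free-energy and Antoine boiling points agree on a shared truth", {
  # a Clausius-Clapeyron truth (C = 0) lies in both model families
  ccA <- c(A = 11.553, B = -3970, C = 0)
  vp <- gen_vapor_pressure_curve(5, antoine = ccA,
                                 temperatures = seq(360, 440, by = 16))
  af <- fit_antoine(vp, c(360, 440))
  tb_antoine <- suppressWarnings(
    antoine_invert(af, physical_constants$P_standard_Pa / 1e5))
  Tfe <- c(298.15, 344, 364)
  P_bar <- exp(ccA[1] + ccA[2] / Tfe)
  M <- physical_constants$molar_mass_cyclohexene
  R <- physical_constants$R_J
  rho_g <- P_bar * 1e5 * M / (R * Tfe) / 1000
  pts <- data.frame(T = Tfe,
                    dG_vap = dgvap_from_densities(rho_g, 800, Tfe),
                    rho_l = 800)
  tb_fe <- boiling_point_free_energy(pts)
  expect_lt(abs(tb_antoine - tb_fe), 1)
})

test_that("Stokes-Einstein radii match the worked ambient values", {
  expect_equal(stokes_einstein_radius(1.9e-5, 0.66, 298.15), 1.74,
               tolerance = 5e-3)
  expect_equal(stokes_einstein_radius(2.4e-5, 0.49, 298.15), 1.857,
               tolerance = 0.01)
  r1 <- stokes_einstein_radius(1e-5, 0.5, 300)
  expect_equal(stokes_einstein_radius(1e-5, 1, 300), r1 / 2)
  expect_error(stokes_einstein_radius(-1, 1, 300), "positive")
})

test_that("the solvation cycle is additive with quadrature uncertainties", {
  expect_equal(solvation_free_energy(18.2, 3.8)[["dG_sol"]], 22.0)
  expect_equal(solvation_free_energy(18.911, 1.51)[["dG_sol"]], 20.421)
  expect_equal(unname(solvation_free_energy(0, 0)), c(0, 0))
  s <- solvation_free_energy(10, 5, se_vap = 3, se_hyd = 4)
  expect_equal(s[["se"]], 5)
})

test_that("enthalpy and compressibility estimators follow their definitions", {
  expect_equal(enthalpy_of_vaporization(50, 50, 300),
               physical_constants$R_J * 300 / 1000)
  v <- gen_volume_series(5, kappa_T = 1.0366e-3, n = 1e5)
  expect_rel_equal(
    isothermal_compressibility(v, attr(v, "ground_truth")$temperature),
    1.0366e-3, 0.05)
  expect_equal(isothermal_compressibility(rep(10, 100), 300), 0)
})
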