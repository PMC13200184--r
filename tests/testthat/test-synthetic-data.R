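test_that("identical seeds give bit-identical outputs, with manifests", {
  a <- gen_training_set(42, n_configs = 2, n_molecules = 3)
  b <- gen_training_set(42, n_configs = 2, n_molecules = 3)
  expect_identical(a, b)
  expect_false(identical(
    a[[1]]$config$coords,
    gen_training_set(43, n_configs = 2, n_molecules = 3)[[1]]$config$coords))
  expect_true(!is.null(attr(a, "ground_truth")$params))

  for (gen in list(gen_pressure_series(9), gen_slab_profile(9),
                   gen_coexistence_curve(9), gen_vapor_pressure_curve(9),
                   gen_volume_series(9, n = 100),
                   gen_stress_series(9, n = 200))) {
    expect_false(is.null(attr(gen, "ground_truth")))
  }
})

test_that("reference forces carry exactly the requested noise", {
  sigma <- 1
  recs <- gen_training_set(13, n_configs = 6, n_molecules = 4,
                           sigma = sigma)
  truth <- attr(recs, "ground_truth")$params
  sq <- unlist(lapply(recs, function(rec) {
    ev <- evaluate_energy_forces(rec$config, truth, cutoff = 12)
    as.numeric(rec$ref_forces - ev$forces)
  }))
  rmse <- sqrt(mean(sq^2))
  n <- length(sq)
  expect_lt(abs(rmse - sigma), 3 * sigma * sqrt(2 / n) + 0.02)
})

test_that("a single molecule has zero intermolecular force components", {
  recs <- gen_training_set(14, n_configs = 1, n_molecules = 1, sigma = 0)
  truth <- attr(recs, "ground_truth")$params
  cfg <- recs[[1]]$config
  # evaluate with bonded terms stripped: remaining forces are purely
  # intramolecular nonbonded (1-4 and beyond); intermolecular is absent
  # because there is no second molecule
  p_nb <- forcefield_params(truth$pairs, truth$charges,
                            charges_enabled = truth$charges_enabled)
  cfg_nb <- cfg; cfg_nb$topology <- NULL
  ev_all <- evaluate_energy_forces(cfg, truth, cutoff = 12)
  # net force on the molecule vanishes either way (no external partner)
  expect_lt(max(abs(colSums(ev_all$forces))), 1e-10)
  mt <- molecular_force_torque(ev_all$forces, cfg)
  expect_lt(max(abs(mt[1, c("fx", "fy", "fz")])), 1e-10)
})

test_that("packing fails loudly when molecules cannot be placed", {
  big <- list(xyz = cyclohexene_geometry(), graph = cyclohexene_graph(),
              types = rep("X", 16), elements = cyclohexene_graph()$elements)
  set.seed(1)
  expect_error(
    afmtools:::pack_molecules(rep(list(big), 3), box = 30,
                              max_attempts = 0),
    "packing failure")
})

test_that("pressure-series generator encodes the requested anisotropy", {
  ps0 <- gen_pressure_series(3, gamma_true = 0, sigma = 1, n = 2000)
  expect_lt(abs(mean(ps0$PZ) - (mean(ps0$PX) + mean(ps0$PY)) / 2), 0.2)

  ps <- gen_pressure_series(3, gamma_true = 25.4, L_Z = 12, sigma = 0.01,
                            n = 500)
  aniso <- mean(ps$PZ) - (mean(ps$PX) + mean(ps$PY)) / 2
  expect_equal(aniso, 2 * 25.4 / 0.1 / 12, tolerance = 1e-3)

  # quadrupling the length shrinks the block SE roughly by half
  se1 <- surface_tension(gen_pressure_series(4, n = 2000))[["se"]]
  se4 <- mean(sapply(4:9, function(s)
    surface_tension(gen_pressure_series(s, n = 8000))[["se"]]))
  expect_lt(se4 / se1, 0.75)
})

test_that("coexistence generator honours its closed forms", {
  cc <- gen_coexistence_curve(1, T_C = 513, noise = 0)
  gt <- attr(cc, "ground_truth")
  tau <- abs(1 - cc$T / 513)
  expect_equal(cc$rho_l - cc$rho_g,
               afmtools:::wegner_eval(tau, gt$amplitudes),
               tolerance = 1e-9)
  expect_equal(cc$rho_l + cc$rho_g,
               2 * gt$rho_C + gt$D_terms[1] * tau^0.89 +
                 gt$D_terms[2] * tau,
               tolerance = 1e-9)
  # a row at T = T_C would have both branches at rho_C
  tau0 <- 0
  expect_equal(afmtools:::wegner_eval(tau0, gt$amplitudes), 0)
})

test_that("slab generator with equal phases leaves nothing to find", {
  p <- gen_slab_profile(2, rho_l = 500, rho_g = 500, noise_sd = 0)
  # threshold sits at the (flat) maximum; there is no vapor region
  expect_error(coexistence_densities(p), "vapor region")
})
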