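test_that("density profiles conserve mass and localise point masses", {
  # all atoms in one bin
  co <- matrix(c(5, 5, 2.05, 5, 5, 2.08, 5, 5, 2.02), ncol = 3,
               byrow = TRUE)
  cfg <- md_configuration(co, rep("C", 3), 1:3, rep("P", 3),
                          box = c(10, 10, 40), periodic = TRUE)
  prof <- profile_from_frames(list(cfg), axis = 3, n_bins = 20)
  expect_equal(sum(prof$density > 0), 1)
  # mass conservation: sum(density * bin volume) = total mass
  bin_vol_L <- 10 * 10 * 2 * 1e-27
  total_mass_g <- 3 * atomic_mass("C") / physical_constants$avogadro
  expect_equal(sum(prof$density * bin_vol_L), total_mass_g,
               tolerance = 1e-10)

  # uniform arrangement: all bins equal within discretisation
  set.seed(5)
  n <- 20000
  cu <- md_configuration(cbind(runif(n, 0, 10), runif(n, 0, 10),
                               runif(n, 0, 40)),
                         rep("C", n), seq_len(n), rep("P", n),
                         box = c(10, 10, 40), periodic = TRUE)
  pu <- profile_from_frames(list(cu), axis = 3, n_bins = 10)
  expect_lt(diff(range(pu$density)) / mean(pu$density), 0.2)

  expect_error(profile_from_frames(list()), "zero frames")
})

test_that("generated tanh slab frames reproduce the generating profile", {
  fr <- gen_slab_frames(2, rho_l = 800, rho_g = 4, L_XY = 6,
                        n_frames = 40)
  prof <- profile_from_frames(fr, axis = 3, n_bins = 48)
  expect_rel_equal(liquid_core_density(prof), 800, 0.005)
})

test_that("two-step density reads the plateau and ignores off-core cavities", {
  # ideal step profile: exactly the plateau
  z <- seq(0.05, 11.95, by = 0.1)
  step <- ifelse(z > 3 & z < 9, 800, 4)
  ps <- density_profile(z, step)
  expect_equal(liquid_core_density(ps), 800)
  expect_equal(unname(coexistence_densities(ps)), c(800, 4))

  # analytic tanh: within 0.1% of bulk
  pt <- gen_slab_profile(1, rho_l = 800, rho_g = 4, width = 0.5,
                         noise_sd = 0)
  expect_rel_equal(liquid_core_density(pt), 800, 1e-3)

  # cavity outside the central core does not move the estimate
  pc <- gen_slab_profile(1, cavities = data.frame(z = 3.8, radius = 0.3),
                         noise_sd = 0)
  expect_rel_equal(liquid_core_density(pc), liquid_core_density(pt), 1e-3)

  # ... while the naive max-density shortcut is biased high under noise
  pn <- gen_slab_profile(3, noise_sd = 0.02, n_frames = 1)
  naive <- max(pn$density)
  twostep <- liquid_core_density(pn)
  expect_gt(naive / 800 - 1, 0.02)          # detectably biased
  expect_lt(abs(twostep / 800 - 1), 0.01)   # two-step stays close

  # degenerate inputs
  flat <- density_profile(z, rep(800, length(z)))
  expect_error(coexistence_densities(flat), "vapor region")
})

test_that("surface tension implements the two-interface pressure route", {
  # isotropic pressure: gamma = 0
  iso <- pressure_tensor_series(0:99, rep(5, 100), rep(5, 100),
                                rep(5, 100), L_Z = 12)
  expect_equal(surface_tension(iso)[["gamma"]], 0)

  # L_Z = 12 nm, anisotropy 1 bar -> 6 bar nm = 0.6 mN/m
  an <- pressure_tensor_series(0:99, rep(4, 100), rep(4, 100),
                               rep(5, 100), L_Z = 12)
  expect_equal(surface_tension(an)[["gamma"]], 0.6)

  # recovery of the generator truth within 2 block SE (25 blocks keep the
  # SE estimate itself sharp, so the 2-sigma band has near-nominal coverage)
  ps <- gen_pressure_series(8, gamma_true = 25.4, L_Z = 12)
  st <- surface_tension(ps, n_blocks = 25)
  expect_lt(abs(st[["gamma"]] - 25.4), 2 * st[["se"]])

  # the generator builds the anisotropy 2 gamma / L_Z in bar
  aniso <- mean(ps$PZ) - (mean(ps$PX) + mean(ps$PY)) / 2
  expect_equal(aniso, 2 * 25.4 / 0.1 / 12, tolerance = 0.15)

  expect_error(pressure_tensor_series(1:2, 1:2, 1:2, 1:2, L_Z = -1),
               "L_Z")
})

test_that("normal pressure averages carry block standard errors", {
  const <- pressure_tensor_series(0:9, rep(1, 10), rep(1, 10),
                                  rep(7, 10), 12)
  np <- normal_pressure(const)
  expect_equal(unname(np), c(7, 0))

  alt <- pressure_tensor_series(0:99, rep(1, 100), rep(1, 100),
                                5 + rep(c(1, -1), 50), 12)
  expect_equal(normal_pressure(alt)[["P"]], 5)

  # AR(1) series: block SE within 30% of the closed-form SE of the mean
  ps <- gen_pressure_series(15, gamma_true = 0, mean_PZ = 10,
                            sigma = 20, rho_ar = 0.5, n = 50000)
  np2 <- normal_pressure(ps, n_blocks = 20)
  var0 <- 20^2 / (1 - 0.5^2)
  se_analytic <- sqrt(var0 / 50000 * (1 + 0.5) / (1 - 0.5))
  expect_lt(abs(np2[["se"]] / se_analytic - 1), 0.3)
})
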