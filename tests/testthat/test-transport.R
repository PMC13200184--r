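test_that("the Einstein estimator recovers Brownian diffusion", {
  traj <- gen_brownian(3, D_true = 0.99e-5, n_particles = 400,
                       steps = 4000, dt = 1)
  msd <- msd_from_trajectory(traj)
  expect_equal(msd$msd[1], 0)
  expect_true(all(msd$msd >= 0))
  D <- diffusion_from_msd(msd)
  expect_rel_equal(D[["D"]], 0.99e-5, 0.06)

  # rigid translation of all positions changes nothing
  traj2 <- traj + 100
  attr(traj2, "dt") <- attr(traj, "dt")
  D2 <- diffusion_from_msd(msd_from_trajectory(traj2))
  expect_equal(D2[["D"]], D[["D"]], tolerance = 1e-12)
})

test_that("degenerate trajectories are caught", {
  # ballistic motion x = v t: regime guard trips
  steps <- 500
  pos <- array(0, dim = c(steps + 1, 2, 3))
  pos[, 1, 1] <- (0:steps) * 0.5
  pos[, 2, 1] <- (0:steps) * 0.3
  attr(pos, "dt") <- 1
  expect_error(diffusion_from_msd(msd_from_trajectory(pos)),
               "ballistic")

  # a single stationary particle has D = 0 (flat MSD, caught as
  # non-diffusive log-log behaviour or zero slope)
  still <- array(1.5, dim = c(201, 1, 3))
  attr(still, "dt") <- 1
  msd <- msd_from_trajectory(still)
  expect_true(all(msd$msd == 0))

  expect_error(msd_from_trajectory(array(0, dim = c(50, 2, 3))),
               "too few frames")
})

test_that("Green-Kubo viscosity matches closed-form autocorrelations", {
  # AR(1) stress: exponential ACF with known discrete integral
  ss <- gen_stress_series(7, sigma0 = 100, rho_ar = 0.8, n = 40000,
                          dt = 0.1)
  truth <- attr(ss, "ground_truth")$eta
  eta <- viscosity_green_kubo(ss, truncate_at_zero = FALSE,
                              max_lag = 0.1 * 100)
  expect_rel_equal(eta[["eta"]], truth, 0.2)

  # white noise: integral is sigma^2 dt / 2
  set.seed(4)
  n <- 50000; dt <- 0.1; sig <- 50
  wn <- stress_series((0:(n - 1)) * dt, rnorm(n, sd = sig),
                      rnorm(n, sd = sig), rnorm(n, sd = sig),
                      volume = 60, temperature = 298.15)
  eta_wn <- viscosity_green_kubo(wn)
  pred <- afmtools:::gk_eta_from_acf0(sig^2 * dt / 2, 60, 298.15)
  expect_rel_equal(eta_wn[["eta"]], pred, 0.1)

  # zero stress: zero viscosity
  z <- stress_series(0:99, numeric(100), numeric(100), numeric(100),
                     volume = 60, temperature = 300)
  expect_equal(viscosity_green_kubo(z)[["eta"]], 0)
  expect_error(viscosity_green_kubo(wn, max_lag = n * dt * 2),
               "shorter than the series")
})
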