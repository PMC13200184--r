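test_that("atom typing yields the scheme's label counts on cyclohexene", {
  g <- cyclohexene_graph()
  expect_equal(length(g$elements), 16)
  expect_equal(nrow(g$bonds), 16)

  ln <- assign_atom_types(g, atom_type_scheme("neat"))
  expect_equal(length(unique(ln[g$elements == "C"])), 2)
  expect_equal(length(unique(ln[g$elements == "H"])), 2)

  lh <- assign_atom_types(g, atom_type_scheme("hydrated"))
  expect_equal(length(unique(lh[g$elements == "C"])), 3)
  expect_equal(length(unique(lh[g$elements == "H"])), 3)
})

test_that("a fully symmetric ring collapses to one carbon and one hydrogen type", {
  g <- benzene_like_graph()
  for (s in c("neat", "hydrated")) {
    l <- assign_atom_types(g, atom_type_scheme(s))
    expect_equal(length(unique(l[g$elements == "C"])), 1)
    expect_equal(length(unique(l[g$elements == "H"])), 1)
  }
})

test_that("typing is deterministic and follows atom permutations", {
  g <- cyclohexene_graph()
  scheme <- atom_type_scheme("hydrated")
  l1 <- assign_atom_types(g, scheme)
  expect_identical(l1, assign_atom_types(g, scheme))
  # permute atoms: relabel indices and check labels permute identically
  set.seed(1)
  perm <- sample(16)
  inv <- order(perm)
  gp <- molecular_graph(g$elements[perm],
                        matrix(inv[g$bonds], ncol = 2), g$bond_orders)
  expect_identical(assign_atom_types(gp, scheme), l1[perm])
})

test_that("typing rejects unknown elements and unclassifiable atoms", {
  g <- molecular_graph(c("C", "O"), rbind(c(1, 2)))
  expect_error(assign_atom_types(g, atom_type_scheme("neat")),
               "unknown element")
  # hydrogen bonded to hydrogen cannot be classified
  hh <- molecular_graph(c("H", "H"), rbind(c(1, 2)))
  expect_error(assign_atom_types(hh, atom_type_scheme("neat")),
               "cannot classify")
})

test_that("bond-term counts are 5 (neat) and 7 (hydrated) on cyclohexene", {
  g <- cyclohexene_graph()
  bt_n <- enumerate_bonded_terms(
    g, assign_atom_types(g, atom_type_scheme("neat")))
  expect_equal(bt_n$n_bond_types, 5)
  bt_h <- enumerate_bonded_terms(
    g, assign_atom_types(g, atom_type_scheme("hydrated")))
  expect_equal(bt_h$n_bond_types, 7)

  dia <- molecular_graph(c("H", "H"), rbind(c(1, 2)))
  expect_equal(enumerate_bonded_terms(dia, c("HX", "HX"))$n_bond_types, 1)
  expect_error(enumerate_bonded_terms(g, rep(NA_character_, 16)),
               "labels missing")
})

test_that("pair energy and force match the dispersion closed form", {
  ev <- evaluate_energy_forces(two_atom_config(2), dispersion_only_params(),
                               cutoff = 10)
  expect_equal(ev$energy, -1 / 64)
  expect_equal(sqrt(sum(ev$forces[1, ]^2)), 6 / 128)
  # attraction: force on atom 1 points toward atom 2 (+x)
  expect_gt(ev$forces[1, 1], 0)

  # isolated single atom: nothing to evaluate
  lone <- md_configuration(matrix(0, 1, 3), "C", 1, "X")
  ev1 <- evaluate_energy_forces(lone, dispersion_only_params(), cutoff = 10)
  expect_equal(ev1$energy, 0)
  expect_equal(ev1$forces, matrix(0, 1, 3))
})

test_that("analytic forces equal central-difference gradients", {
  # chain fixture covers bonds, angles, dihedrals and intramolecular pairs
  cf <- chain_fixture()
  expect_lt(max_fd_force_error(cf$config, cf$params, cutoff = 10), 1e-6)

  # multi-molecule cyclohexene configurations cover inter/intra nonbonded,
  # charges, and bonded terms together (random spot-checked components)
  truth <- ground_truth_params("hydrated", with_solvent = TRUE)
  recs <- gen_training_set(31, n_configs = 3, n_molecules = 4,
                           phase = "hydrated", params = truth)
  set.seed(2)
  for (rec in recs) {
    idx <- data.frame(i = sample(nrow(rec$config$coords), 6),
                      ax = sample(3, 6, replace = TRUE))
    expect_lt(max_fd_force_error(rec$config, truth, cutoff = 12,
                                 idx = idx), 1e-6)
  }
})

test_that("total force on any isolated configuration vanishes", {
  recs <- gen_training_set(5, n_configs = 3, n_molecules = 5,
                           phase = "neat")
  truth <- attr(recs, "ground_truth")$params
  for (rec in recs) {
    ev <- evaluate_energy_forces(rec$config, truth, cutoff = 12)
    expect_lt(max(abs(colSums(ev$forces))), 1e-10)
  }
})

test_that("evaluator rejects degenerate geometry and missing parameters", {
  expect_error(evaluate_energy_forces(two_atom_config(0.05),
                                      dispersion_only_params(),
                                      cutoff = 10),
               "degenerate geometry")
  expect_error(evaluate_energy_forces(two_atom_config(2, type = "Y"),
                                      dispersion_only_params(type = "X"),
                                      cutoff = 10),
               "missing pair parameters")
  per <- md_configuration(rbind(c(0, 0, 0), c(2, 0, 0)), c("C", "C"),
                          c(1, 2), c("X", "X"), box = c(10, 10, 10),
                          periodic = TRUE)
  expect_error(evaluate_energy_forces(per, dispersion_only_params(),
                                      cutoff = 8),
               "half the smallest box")
})

test_that("molecular force and torque follow the lever-arm identities", {
  cf <- chain_fixture()
  cfg <- cf$config
  n <- nrow(cfg$coords)
  # uniform force: net = n*f, torque = 0 about the COM
  f <- c(1.5, -0.3, 0.7)
  F <- matrix(f, n, 3, byrow = TRUE)
  mt <- molecular_force_torque(F, cfg)
  expect_equal(unlist(mt[1, c("fx", "fy", "fz")]), n * f,
               ignore_attr = TRUE)
  expect_equal(max(abs(mt[1, c("tx", "ty", "tz")])), 0, tolerance = 1e-10)

  # force couple on two atoms: net zero, torque = |d||f|
  cfg2 <- md_configuration(rbind(c(0, 0, 0), c(2, 0, 0)), c("C", "C"),
                           c(1, 1), c("X", "X"),
                           topology = molecular_graph(c("C", "C"),
                                                      rbind(c(1, 2))))
  Fc <- rbind(c(0, 1, 0), c(0, -1, 0))
  mt2 <- molecular_force_torque(Fc, cfg2)
  expect_equal(max(abs(mt2[1, c("fx", "fy", "fz")])), 0)
  expect_equal(sqrt(sum(mt2[1, c("tx", "ty", "tz")]^2)), 2)

  # zero net force: torque independent of reference point (shift all
  # coordinates and recompute)
  set.seed(3)
  Fr <- matrix(rnorm(3 * n), n, 3)
  Fr <- sweep(Fr, 2, colMeans(Fr))      # zero net force
  t1 <- unlist(molecular_force_torque(Fr, cfg)[1, c("tx", "ty", "tz")])
  cfg_shift <- cfg
  cfg_shift$coords <- sweep(cfg$coords, 2, c(5, -3, 2), `+`)
  t2 <- unlist(molecular_force_torque(Fr, cfg_shift)[1,
                                                     c("tx", "ty", "tz")])
  expect_equal(t1, t2, tolerance = 1e-10)
})

test_that("tabulated potentials round-trip and carry exact derivatives", {
  path <- tempfile(fileext = ".xvg")
  write_tabulated_potential(3.6, seq(1, 8, by = 5e-4), path)
  tab <- read_tabulated_potential(path)
  expect_equal(attr(tab, "b"), 3.6)

  # pure Coulomb column on a coarse grid: f = 1/r
  p2 <- tempfile(fileext = ".xvg")
  t2 <- write_tabulated_potential(1, c(1, 2, 4), p2)
  expect_equal(t2$f, c(1, 0.5, 0.25))

  # derivative columns match centered finite differences
  n <- nrow(tab)
  for (col in c("f", "g", "h")) {
    num <- -(tab[[col]][3:n] - tab[[col]][1:(n - 2)]) / (2 * 5e-4)
    ana <- tab[[paste0("m", col, "p")]][2:(n - 1)]
    expect_lt(max(abs(num - ana) / abs(ana)), 1e-5)
  }

  # round trip: table energies reproduce the evaluator's pair energies
  A <- 250; b <- 3.6; C6 <- 40
  params <- forcefield_params(data.frame(type1 = "X", type2 = "X",
                                         A = A, b = b, C6 = C6))
  u_tab <- tabulated_pair_energy(tab, A = A, C6 = C6)
  u_eval <- vapply(tab$r, function(r)
    evaluate_energy_forces(two_atom_config(r), params, cutoff = 20)$energy,
    numeric(1))
  expect_equal(u_tab, u_eval, tolerance = 1e-12)

  # empty parameters give an all-zero energy
  expect_true(all(tabulated_pair_energy(tab, A = 0, C6 = 0, qprod = 0)
                  == 0))
  expect_error(write_tabulated_potential(3.6, c(1, 1, 2), tempfile()),
               "strictly increasing")
})
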