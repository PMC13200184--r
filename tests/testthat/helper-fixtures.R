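# shared fixtures, all generated in code

# single pair of neutral atoms at distance r with one type
two_atom_config <- function(r = 2, type = "X") {
  md_configuration(rbind(c(0, 0, 0), c(r, 0, 0)), c("C", "C"),
                   c(1, 2), rep(type, 2))
}

dispersion_only_params <- function(C6 = 1, type = "X") {
  forcefield_params(data.frame(type1 = type, type2 = type,
                               A = 0, b = 1, C6 = C6))
}

# four-atom chain with bond/angle/dihedral terms (exercises every bonded
# kind, including the torsion gradient)
chain_fixture <- function(jitter_seed = 9) {
  g <- molecular_graph(c("C", "C", "C", "C"),
                       rbind(c(1, 2), c(2, 3), c(3, 4)))
  set.seed(jitter_seed)
  co <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.3, 0.2),
              c(3.0, 1.8, 1.4)) + matrix(rnorm(12, sd = 0.05), 4, 3)
  cfg <- md_configuration(co, rep("C", 4), rep(1, 4),
                          c("T1", "T2", "T2", "T1"), topology = g)
  p <- forcefield_params(
    pairs = data.frame(type1 = c("T1", "T1", "T2"),
                       type2 = c("T1", "T2", "T2"),
                       A = c(100, 200, 300), b = c(3.6, 3.7, 3.8),
                       C6 = c(10, 20, 30)),
    bonds = data.frame(type1 = c("T1", "T2"), type2 = c("T2", "T2"),
                       r0 = c(1.5, 1.5), k = c(300, 320)),
    angles = data.frame(type1 = "T1", type2 = "T2", type3 = "T2",
                        theta0 = 1.9, k = 50),
    dihedrals = data.frame(type1 = "T1", type2 = "T2", type3 = "T2",
                           type4 = "T1", k1 = 1.2, k2 = 0.8, k3 = 0.4))
  list(config = cfg, params = p, graph = g)
}

# benzene-like fully symmetric ring: six equivalent sp2 carbons + 6 H
benzene_like_graph <- function() {
  ring <- cbind(1:6, c(2:6, 1))
  hb <- cbind(1:6, 7:12)
  molecular_graph(c(rep("C", 6), rep("H", 6)), rbind(ring, hb),
                  c(rep(c(2L, 1L), 3), rep(1L, 6)))
}

# central-difference force check; returns max relative deviation
max_fd_force_error <- function(cfg, params, cutoff, h = 1e-6,
                               idx = NULL) {
  ev <- evaluate_energy_forces(cfg, params, cutoff = cutoff)
  if (is.null(idx)) {
    idx <- expand.grid(i = seq_len(nrow(cfg$coords)), ax = 1:3)
  }
  maxrel <- 0
  for (r in seq_len(nrow(idx))) {
    i <- idx$i[r]; ax <- idx$ax[r]
    cp <- cfg; cm <- cfg
    cp$coords[i, ax] <- cp$coords[i, ax] + h
    cm$coords[i, ax] <- cm$coords[i, ax] - h
    num <- -(evaluate_energy_forces(cp, params, cutoff = cutoff)$energy -
             evaluate_energy_forces(cm, params, cutoff = cutoff)$energy) /
      (2 * h)
    scale <- max(1e-6, abs(ev$forces[i, ax]))
    maxrel <- max(maxrel, abs(num - ev$forces[i, ax]) / scale)
  }
  maxrel
}

# training records for the chain fixture from jittered replicas
chain_records <- function(params, n = 5, sd = 0.1, seed = 10) {
  base <- chain_fixture()$config
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    c2 <- base
    c2$coords <- base$coords + matrix(rnorm(12, sd = sd), 4, 3)
    structure(list(config = c2,
                   ref_forces = evaluate_energy_forces(c2, params,
                                                       cutoff = 10)$forces,
                   phase = "neat", mask = rep(TRUE, 4)),
              class = "training_record")
  })
}

# records of TWO chain molecules at contact: intermolecular pairs present,
# so repulsion parameters are identifiable
chain_pair_records <- function(params, n = 6, seed = 10) {
  cf <- chain_fixture()
  mol <- list(xyz = cf$config$coords, graph = cf$graph,
              types = cf$config$types, elements = rep("C", 4))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cfg <- afmtools:::pack_molecules(list(mol, mol), box = 20,
                                     jitter = 0.08)
    structure(list(config = cfg,
                   ref_forces = evaluate_energy_forces(cfg, params,
                                                       cutoff = 9)$forces,
                   phase = "neat", mask = rep(TRUE, 8)),
              class = "training_record")
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
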