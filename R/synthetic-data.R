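#' Seeded synthetic-data generators
#'
#' Every estimator in the package has a generator here that produces its
#' input with known ground truth, so the whole pipeline closes the loop
#' (generate -> estimate -> compare to truth) at desk scale. One global seed
#' fans out to per-generator substreams, so each scenario is independently
#' reproducible. All generators attach their ground truth as the
#' `"ground_truth"` attribute of the returned object (the manifest).
#'
#' @name synthetic_data
NULL

# deterministic substream: distinct named streams from one global seed
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 1009L) * 1000003L + (h %% 999983L)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(substream_seed(seed, name))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Idealised cyclohexene geometry
#'
#' A puckered six-ring with the [cyclohexene_graph()] atom order (C1..C6,
#' H7..H16): ring carbons on a hexagon of side ~1.46 A with a small
#' out-of-plane pucker on the sp3 carbons, sp2 hydrogens in-plane, sp3
#' hydrogens above/below the ring.
#'
#' @return 16 x 3 coordinate matrix (Angstrom).
#' @export
cyclohexene_geometry <- function() {
  R <- 1.46
  th <- (0:5) * pi / 3
  z <- c(0, 0, 0.25, -0.25, 0.25, -0.25)
  C <- cbind(R * cos(th), R * sin(th), z)
  uout <- cbind(cos(th), sin(th), 0)
  H <- matrix(0, 10, 3)
  # sp2 hydrogens on C1, C2: in-plane, radially outward
  H[1, ] <- C[1, ] + 1.09 * uout[1, ]
  H[2, ] <- C[2, ] + 1.09 * uout[2, ]
  k <- 3L
  for (ci in 3:6) {
    for (sgn in c(1, -1)) {
      d <- 0.55 * uout[ci, ] + c(0, 0, sgn * 0.84)
      d <- d / sqrt(sum(d^2))
      H[k, ] <- C[ci, ] + 1.09 * d
      k <- k + 1L
    }
  }
  rbind(C, H)
}

#' Rigid three-site solvent surrogate
#'
#' A simple bent three-site molecule (types `OW`, `HW`) standing in for the
#' solvent in hydrated training records. It exists to exercise the QM/MM
#' masking logic of the fits, not to model water physics.
#'
#' @return list with `graph` (a [molecular_graph()]), `coords` (3 x 3,
#'   O then two H, Angstrom) and `types`.
#' @export
solvent_surrogate <- function() {
  graph <- molecular_graph(c("O", "H", "H"), rbind(c(1, 2), c(1, 3)))
  d <- 0.96; half <- 104.5 / 2 * pi / 180
  coords <- rbind(c(0, 0, 0),
                  c(d * sin(half),  d * cos(half), 0),
                  c(-d * sin(half), d * cos(half), 0))
  list(graph = graph, coords = coords, types = c("OW", "HW", "HW"))
}

#' Ground-truth force-field parameters for the synthetic scenarios
#'
#' A fixed, physically plausible Buckingham parameter set for the
#' cyclohexene-class molecule under either typing scheme, extended with
#' solvent-surrogate pairs for the hydrated scenario. The neat scheme
#' carries no partial charges (nonpolar convention); the hydrated and mixed
#' schemes use small charges that sum to zero over the molecule.
#'
#' @param scheme `"neat"` or `"hydrated"` (the mixed-phase model shares the
#'   hydrated typing).
#' @param with_solvent include solvent-surrogate types and cross pairs.
#' @return a [forcefield_params()] object.
#' @export
ground_truth_params <- function(scheme = c("neat", "hydrated"),
                                with_solvent = (scheme == "hydrated")) {
  scheme <- match.arg(scheme)
  ctypes <- if (scheme == "neat") c("C2", "C3") else c("C2", "CA", "CH")
  htypes <- if (scheme == "neat") c("H2", "H3") else c("H2", "HA", "HH")
  types <- c(ctypes, htypes)
  if (with_solvent) types <- c(types, "OW", "HW")

  is_heavy <- function(t) t %in% c(ctypes, "OW")
  pr <- expand.grid(type1 = types, type2 = types,
                    stringsAsFactors = FALSE)
  pr <- pr[pr$type1 <= pr$type2, ]
  # deterministic, type-dependent values: distinct per pair so recovery is
  # informative, in realistic magnitude ranges
  hsh <- function(t) sum(utf8ToInt(t)) %% 7
  A <- b <- C6 <- numeric(nrow(pr))
  for (r in seq_len(nrow(pr))) {
    t1 <- pr$type1[r]; t2 <- pr$type2[r]
    nh <- is_heavy(t1) + is_heavy(t2)
    base_A <- c(1800, 8000, 42000)[nh + 1]
    A[r] <- base_A * (1 + 0.05 * ((hsh(t1) + hsh(t2)) %% 5))
    b[r] <- c(4.0, 3.8, 3.6)[nh + 1] + 0.02 * ((hsh(t1) * hsh(t2)) %% 4)
    base_C6 <- c(25, 120, 600)[nh + 1]
    C6[r] <- base_C6 * (1 + 0.04 * ((hsh(t1) + 2 * hsh(t2)) %% 5))
  }
  pairs <- data.frame(type1 = pr$type1, type2 = pr$type2,
                      A = A, b = b, C6 = C6)

  charges <- if (scheme == "neat") {
    stats::setNames(rep(0, length(types)), types)
  } else {
    q <- c(C2 = -0.15, CA = -0.12, CH = -0.06,
           H2 = 0.12, HA = 0.06, HH = 0.045)
    if (with_solvent) q <- c(q, OW = -0.8, HW = 0.4)
    q
  }

  cc <- function(t1, t2, r0, k) data.frame(type1 = t1, type2 = t2,
                                           r0 = r0, k = k)
  if (scheme == "neat") {
    bonds <- rbind(
      cc("C2", "C2", 1.33, 540), cc("C2", "C3", 1.50, 330),
      cc("C3", "C3", 1.53, 310), cc("C2", "H2", 1.08, 360),
      cc("C3", "H3", 1.09, 340))
    angles <- data.frame(
      type1 = c("C2", "C2", "C3", "C2", "C3", "C2", "H3", "C3"),
      type2 = c("C2", "C3", "C3", "C2", "C2", "C3", "C3", "C3"),
      type3 = c("C3", "C3", "C3", "H2", "H2", "H3", "H3", "H3"),
      theta0 = c(2.12, 1.94, 1.94, 2.08, 2.05, 1.91, 1.88, 1.90),
      k = c(70, 63, 60, 40, 42, 44, 36, 39))
    dtypes <- c("C2", "C3")
  } else {
    bonds <- rbind(
      cc("C2", "C2", 1.33, 540), cc("C2", "CA", 1.50, 330),
      cc("CA", "CH", 1.53, 315), cc("CH", "CH", 1.54, 305),
      cc("C2", "H2", 1.08, 360), cc("CA", "HA", 1.09, 345),
      cc("CH", "HH", 1.09, 335))
    angles <- data.frame(
      type1 = c("C2", "C2", "CA", "C2", "CA", "C2", "HA", "CA", "HH",
                "CH", "CH"),
      type2 = c("C2", "CA", "CH", "C2", "C2", "CA", "CA", "CH", "CH",
                "CH", "CA"),
      type3 = c("CA", "CH", "CH", "H2", "H2", "HA", "HA", "HH", "HH",
                "HH", "HA"),
      theta0 = c(2.12, 1.94, 1.93, 2.08, 2.05, 1.91, 1.88, 1.90, 1.87,
                 1.92, 1.89),
      k = c(70, 63, 60, 40, 42, 44, 36, 39, 35, 38, 41))
    dtypes <- c("C2", "CA", "CH")
  }
  if (with_solvent) {
    bonds <- rbind(bonds, cc("OW", "HW", 0.96, 450))
    angles <- rbind(angles, data.frame(type1 = "HW", type2 = "OW",
                                       type3 = "HW", theta0 = 1.824,
                                       k = 55))
  }
  forcefield_params(pairs, charges = charges, bonds = bonds,
                    angles = angles, dihedrals = NULL,
                    charges_enabled = scheme != "neat",
                    dispersion_frozen = TRUE)
}

#' Generate a force-matching training set
#'
#' Replaces the MD sampling and electronic-structure reference steps:
#' molecules are packed into a box by overlap-rejected random placement with
#' random rigid orientations and small per-atom jitter, and reference forces
#' are the ground-truth evaluator's output plus i.i.d. Gaussian noise.
#' Neat records contain `n_molecules` cyclohexene-like molecules with all
#' atoms active; hydrated records contain one solute plus a shell of rigid
#' three-site solvent molecules, with only the solute atoms in the active
#' mask (the QM/MM convention).
#'
#' @param seed integer seed (substreamed internally).
#' @param n_configs number of configurations.
#' @param n_molecules molecules per neat configuration (hydrated: solvent
#'   count is `n_molecules - 1`).
#' @param phase `"neat"` or `"hydrated"`.
#' @param params ground-truth [forcefield_params()]; defaults to
#'   [ground_truth_params()] for the phase.
#' @param sigma Gaussian force-noise s.d., kcal/(mol A).
#' @param scheme typing scheme for the solute (the hydrated and mixed models
#'   share the hydrated typing).
#' @param box cubic box length (Angstrom).
#' @param cutoff nonbonded cutoff used by the ground-truth evaluator.
#' @param jitter per-atom Gaussian jitter s.d. (Angstrom) after packing.
#' @return list of `training_record` objects: each has `config`,
#'   `ref_forces`, `phase`, `mask` (logical per atom). Ground truth in the
#'   `"ground_truth"` attribute.
#' @export
gen_training_set <- function(seed, n_configs = 20, n_molecules = 8,
                             phase = c("neat", "hydrated"),
                             params = NULL,
                             sigma = 0,
                             scheme = if (phase == "neat") "neat" else
                               "hydrated",
                             box = 30, cutoff = 12, jitter = 0.05) {
  phase <- match.arg(phase)
  if (is.null(params)) params <- ground_truth_params(scheme)
  che_graph <- cyclohexene_graph()
  che_types <- assign_atom_types(che_graph, atom_type_scheme(scheme))
  che_xyz <- cyclohexene_geometry()
  solv <- solvent_surrogate()

  records <- with_substream(seed, paste0("training_", phase), {
    lapply(seq_len(n_configs), function(cfg_i) {
      if (phase == "neat") {
        mols <- rep(list(list(xyz = che_xyz, graph = che_graph,
                              types = che_types,
                              elements = che_graph$elements)), n_molecules)
        mask_mols <- seq_len(n_molecules)
      } else {
        solute <- list(xyz = che_xyz, graph = che_graph, types = che_types,
                       elements = che_graph$elements)
        waters <- rep(list(list(xyz = solv$coords, graph = solv$graph,
                                types = solv$types,
                                elements = solv$graph$elements)),
                      max(0L, n_molecules - 1L))
        mols <- c(list(solute), waters)
        mask_mols <- 1L
      }
      config <- pack_molecules(mols, box = box, jitter = jitter)
      ev <- evaluate_energy_forces(config, params, cutoff = cutoff)
      ref <- ev$forces
      if (sigma > 0)
        ref <- ref + matrix(stats::rnorm(length(ref), sd = sigma),
                            nrow(ref), 3)
      mask <- config$molecule_id %in% mask_mols
      structure(list(config = config, ref_forces = ref, phase = phase,
                     mask = mask),
                class = "training_record")
    })
  })
  attr(records, "ground_truth") <- list(params = params, sigma = sigma,
                                        seed = seed, phase = phase,
                                        scheme = scheme, cutoff = cutoff)
  records
}

# overlap-rejected cluster packing, consuming the current RNG stream:
# each new molecule is anchored at van-der-Waals contact distance to a
# random already-placed atom, so the training set samples the short-range
# repulsive wall the fit must see (condensed-phase contact geometry)
pack_molecules <- function(mols, box, jitter = 0.05,
                           contact = c(1.9, 3.2), max_attempts = 2000) {
  placed <- list()
  all_atoms <- matrix(NA_real_, 0, 3)
  for (m in seq_along(mols)) {
    xyz0 <- mols[[m]]$xyz
    com0 <- colMeans(xyz0)
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      Rm <- random_rotation()
      body <- sweep(xyz0, 2, com0) %*% t(Rm)
      if (m == 1) {
        cand <- body + matrix(box / 2, nrow(body), 3, byrow = TRUE)
        ok <- TRUE; break
      }
      anchor <- all_atoms[sample.int(nrow(all_atoms), 1), ]
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      radius <- max(sqrt(rowSums(body^2)))
      s <- radius + stats::runif(1, contact[1], contact[2])
      cand <- sweep(body, 2, anchor + u * s, `+`)
      dmin <- min(proxy_min_dist(cand, all_atoms))
      if (dmin >= contact[1] && dmin <= contact[2] + 0.5) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("packing failure: could not place molecule ", m,
                  " after ", max_attempts, " attempts")
    if (jitter > 0)
      cand <- cand + matrix(stats::rnorm(length(cand), sd = jitter),
                            nrow(cand), 3)
    placed[[m]] <- cand
    all_atoms <- rbind(all_atoms, cand)
  }
  coords <- do.call(rbind, placed)
  # recentre the cluster in the box
  coords <- sweep(coords, 2, colMeans(coords) - box / 2, `-`)
  md_configuration(
    coords = coords,
    elements = unlist(lapply(mols, `[[`, "elements")),
    molecule_id = rep(seq_along(mols), vapply(mols, function(x)
      nrow(x$xyz), integer(1))),
    types = unlist(lapply(mols, `[[`, "types")),
    box = rep(box, 3), periodic = FALSE,
    topology = lapply(mols, `[[`, "graph")
  )
}

# minimum distance from each row of a to the point set b
proxy_min_dist <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i)
    min(sqrt(rowSums(sweep(b, 2, a[i, ])^2))), numeric(1))
}

# uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a pressure-tensor time series with known surface tension
#'
#' Builds the inverse of the slab tension estimator: the lateral pressures
#' carry a built-in anisotropy \eqn{P_Z - (P_X+P_Y)/2 = 2\gamma/L_Z} (in
#' bar, with gamma in mN/m and L_Z in nm) plus AR(1)-correlated Gaussian
#' noise, so [surface_tension()] recovers `gamma_true`.
#'
#' @param seed integer seed.
#' @param gamma_true ground-truth tension (mN/m); default is a typical
#'   organic-liquid value.
#' @param L_Z box length along the slab normal (nm).
#' @param mean_PZ mean normal pressure (bar).
#' @param sigma per-channel noise s.d. (bar).
#' @param rho_ar AR(1) autocorrelation of the noise.
#' @param n series length.
#' @param dt time step between samples (ps).
#' @return a [pressure_tensor_series()] with ground truth attached.
#' @export
gen_pressure_series <- function(seed, gamma_true = 25.4, L_Z = 12,
                                mean_PZ = 1, sigma = 50, rho_ar = 0.5,
                                n = 5000, dt = 1) {
  aniso <- 2 * gamma_true / physical_constants$bar_nm_to_mN_m / L_Z  # bar
  with_substream(seed, "pressure_series", {
    ar1 <- function() {
      x <- numeric(n)
      x[1] <- stats::rnorm(1, sd = sigma / sqrt(1 - rho_ar^2))
      innov <- stats::rnorm(n - 1, sd = sigma)
      for (t in 2:n) x[t] <- rho_ar * x[t - 1] + innov[t - 1]
      x
    }
    PZ <- mean_PZ + ar1()
    PX <- mean_PZ - aniso + ar1()
    PY <- mean_PZ - aniso + ar1()
    s <- pressure_tensor_series(time = (seq_len(n) - 1) * dt,
                                PX = PX, PY = PY, PZ = PZ, L_Z = L_Z)
    attr(s, "ground_truth") <- list(gamma = gamma_true, L_Z = L_Z,
                                    mean_PZ = mean_PZ, sigma = sigma,
                                    rho_ar = rho_ar, seed = seed)
    s
  })
}

#' Generate slab density profiles or frames with a tanh interface
#'
#' Realises the two-phase slab density
#' \deqn{\rho(z) = \rho_g + (\rho_l - \rho_g)/2 \,
#'   [\tanh((z - z_1)/w) - \tanh((z - z_2)/w)]}
#' either directly as a noisy binned profile or as particle frames placed by
#' a spatial Poisson process with that intensity. Optional spherical
#' cavities (density holes) can be carved at chosen depths to emulate the
#' interface-cavitation phenomenology that motivates the two-step density
#' measurement.
#'
#' @param seed integer seed.
#' @param rho_l,rho_g liquid and vapor densities (g/L).
#' @param width interface 10-90 width parameter `w` (nm).
#' @param L_Z box length along z (nm); the liquid slab spans the central
#'   `slab_fraction` of it.
#' @param slab_fraction fraction of `L_Z` occupied by liquid.
#' @param n_bins number of profile bins.
#' @param n_frames frames averaged.
#' @param noise_sd multiplicative bin-noise s.d. (fraction of bin value).
#' @param cavities optional data.frame with columns `z` (center, nm) and
#'   `radius` (nm); density inside a cavity is set to `rho_g`.
#' @return a [density_profile()] with ground truth attached.
#' @export
gen_slab_profile <- function(seed, rho_l = 800, rho_g = 4, width = 0.25,
                             L_Z = 12, slab_fraction = 0.5, n_bins = 120,
                             n_frames = 50, noise_sd = 0.01,
                             cavities = NULL) {
  z1 <- L_Z * (0.5 - slab_fraction / 2)
  z2 <- L_Z * (0.5 + slab_fraction / 2)
  edges <- seq(0, L_Z, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  base <- rho_g + (rho_l - rho_g) / 2 *
    (tanh((centers - z1) / width) - tanh((centers - z2) / width))
  if (!is.null(cavities)) {
    for (r in seq_len(nrow(cavities))) {
      inside <- abs(centers - cavities$z[r]) <= cavities$radius[r]
      base[inside] <- rho_g
    }
  }
  with_substream(seed, "slab_profile", {
    acc <- matrix(stats::rnorm(n_bins * n_frames, mean = 1, sd = noise_sd),
                  n_bins, n_frames)
    dens <- pmax(0, base * rowMeans(acc))
    p <- density_profile(z = centers, density = dens, n_frames = n_frames)
    attr(p, "ground_truth") <- list(rho_l = rho_l, rho_g = rho_g,
                                    width = width, z1 = z1, z2 = z2,
                                    cavities = cavities, seed = seed)
    p
  })
}

#' @rdname gen_slab_profile
#' @param L_XY lateral box lengths (nm) for generated frames.
#' @param molar_mass particle molar mass (g/mol) used to convert the target
#'   mass density into a number intensity; defaults to the mass of the
#'   single-site particles written into the frames, so the binned mass
#'   density reproduces the target exactly.
#' @details `gen_slab_frames` realises the same tanh density as particle
#'   frames: single-site particles are placed by a spatial Poisson process
#'   whose z-intensity follows the profile (cavities carved as spherical
#'   exclusions), so [profile_from_frames()] recovers the generating tanh
#'   within binning and shot noise.
#' @export
gen_slab_frames <- function(seed, rho_l = 800, rho_g = 4, width = 0.25,
                            L_Z = 12, slab_fraction = 0.5, L_XY = 4,
                            n_frames = 20, cavities = NULL,
                            molar_mass = atomic_mass("C")) {
  z1 <- L_Z * (0.5 - slab_fraction / 2)
  z2 <- L_Z * (0.5 + slab_fraction / 2)
  rho_z <- function(z) rho_g + (rho_l - rho_g) / 2 *
    (tanh((z - z1) / width) - tanh((z - z2) / width))
  # number density (particles / nm^3) from mass density (g/L):
  # g/L = g/dm^3 -> mol/L -> particles/nm^3: 1 L = 1e24 nm^3
  num_dens <- function(z) rho_z(z) / molar_mass *
    physical_constants$avogadro / 1e24
  rho_max <- num_dens(mean(c(z1, z2)))
  vol <- L_XY^2 * L_Z
  frames <- with_substream(seed, "slab_frames", {
    lapply(seq_len(n_frames), function(f) {
      n_try <- stats::rpois(1, rho_max * vol)
      pos <- cbind(stats::runif(n_try, 0, L_XY),
                   stats::runif(n_try, 0, L_XY),
                   stats::runif(n_try, 0, L_Z))
      keep <- stats::runif(n_try) < num_dens(pos[, 3]) / rho_max
      pos <- pos[keep, , drop = FALSE]
      if (!is.null(cavities)) {
        for (r in seq_len(nrow(cavities))) {
          ctr <- c(L_XY / 2, L_XY / 2, cavities$z[r])
          d2 <- rowSums(sweep(pos, 2, ctr)^2)
          pos <- pos[d2 > cavities$radius[r]^2, , drop = FALSE]
        }
      }
      n <- nrow(pos)
      md_configuration(pos * 10,                 # nm -> Angstrom
                       elements = rep("C", n),
                       molecule_id = seq_len(n),
                       types = rep("P", n),
                       box = c(L_XY, L_XY, L_Z) * 10, periodic = TRUE)
    })
  })
  attr(frames, "ground_truth") <- list(rho_l = rho_l, rho_g = rho_g,
                                       width = width, z1 = z1, z2 = z2,
                                       cavities = cavities, seed = seed)
  frames
}

#' Generate coexistence and vapor-pressure curves from closed-form truths
#'
#' `gen_coexistence_curve` constructs \eqn{\rho_l - \rho_g} from the Wegner
#' expansion and \eqn{\rho_l + \rho_g} from the rectilinear-diameter law,
#' then splits them into the two branches; `gen_vapor_pressure_curve`
#' evaluates an Antoine law. Defaults follow the six-temperature 360-460 K
#' design with 3D-Ising exponents and amplitude set
#' A0 = 579.5, A1 = 4637.6, A2 = -8973.0, A3 = 5706.9 g/L.
#'
#' @param seed integer seed.
#' @param T_C,amplitudes,rho_C,D_terms ground truths: critical temperature
#'   (K), Wegner amplitudes A0..A3 (g/L), critical density (g/L), diameter
#'   coefficients `c(D_1ma, D_1)` (g/L). The diameter defaults are chosen
#'   so that both branches stay physical (`rho_l > rho_g > 0`) over the
#'   default temperature range; the amplitude set alone fixes the branch
#'   difference that the Wegner fit consumes.
#' @param temperatures sampling temperatures (K).
#' @param noise multiplicative noise s.d. on each density (fraction).
#' @param beta_c,Delta,alpha_prime fixed critical exponents.
#' @return a [coexistence_curve()] with ground truth attached.
#' @export
gen_coexistence_curve <- function(seed, T_C = 513,
                                  amplitudes = c(579.5, 4637.6, -8973.0,
                                                 5706.9),
                                  rho_C = 303.9,
                                  D_terms = c(0, 1200),
                                  temperatures = seq(360, 460, by = 20),
                                  noise = 0,
                                  beta_c = 0.325, Delta = 0.5,
                                  alpha_prime = 0.11) {
  tau <- abs(1 - temperatures / T_C)
  diff <- wegner_eval(tau, amplitudes, beta_c, Delta)
  sum_ <- 2 * rho_C + D_terms[1] * tau^(1 - alpha_prime) + D_terms[2] * tau
  rho_l <- (sum_ + diff) / 2
  rho_g <- (sum_ - diff) / 2
  if (noise > 0) {
    rl <- rho_l; rg <- rho_g
    out <- with_substream(seed, "coexistence", {
      list(l = rl * (1 + stats::rnorm(length(rl), sd = noise)),
           g = pmax(rg * (1 + stats::rnorm(length(rg), sd = noise)),
                    1e-6))
    })
    rho_l <- out$l; rho_g <- out$g
  }
  cc <- coexistence_curve(T = temperatures, rho_l = rho_l, rho_g = rho_g)
  attr(cc, "ground_truth") <- list(T_C = T_C, amplitudes = amplitudes,
                                   rho_C = rho_C, D_terms = D_terms,
                                   beta_c = beta_c, Delta = Delta,
                                   alpha_prime = alpha_prime,
                                   noise = noise, seed = seed)
  cc
}

#' @rdname gen_coexistence_curve
#' @param antoine ground-truth Antoine coefficients `c(A, B, C)` for
#'   pressure in bar (defaults: the low-temperature window fit
#'   A = 5.7, B = -612.2 K, C = -236.3 K).
#' @param lognormal_sigma multiplicative (log-scale) noise s.d. on P.
#' @export
gen_vapor_pressure_curve <- function(seed,
                                     antoine = c(A = 5.7, B = -612.2,
                                                 C = -236.3),
                                     temperatures = seq(360, 440, by = 16),
                                     lognormal_sigma = 0) {
  P <- exp(antoine[1] + antoine[2] / (temperatures + antoine[3]))
  if (lognormal_sigma > 0)
    P <- with_substream(seed, "vapor_pressure",
      P * exp(stats::rnorm(length(P), sd = lognormal_sigma)))
  vp <- vapor_pressure_curve(T = temperatures, P = unname(P))
  attr(vp, "ground_truth") <- list(antoine = antoine,
                                   lognormal_sigma = lognormal_sigma,
                                   seed = seed)
  vp
}

#' Generate Brownian trajectories and equilibrium volume series
#'
#' `gen_brownian` draws independent Gaussian displacement increments with
#' per-dimension variance `2 D dt`, the exact discrete realisation of free
#' diffusion; `gen_volume_series` draws i.i.d. Gaussian volumes with the
#' equilibrium fluctuation variance \eqn{\langle\delta V^2\rangle =
#' \kappa_T k_B T \langle V \rangle}, so the compressibility estimator
#' recovers `kappa_T`. Default truths are a typical small-molecule aqueous
#' diffusivity and the cyclohexene-scale compressibility.
#'
#' @param seed integer seed.
#' @param D_true diffusion constant (cm^2/s).
#' @param n_particles,steps,dt trajectory shape (dt in ps).
#' @return `gen_brownian`: an array `steps+1 x n_particles x 3` of positions
#'   (Angstrom); `gen_volume_series`: numeric vector of volumes (nm^3).
#'   Ground truth attached as attribute.
#' @export
gen_brownian <- function(seed, D_true = 0.99e-5, n_particles = 200,
                         steps = 2000, dt = 1) {
  # D in cm^2/s -> A^2/ps
  D_A2ps <- D_true / physical_constants$A2_ps_to_cm2_s
  sd_step <- sqrt(2 * D_A2ps * dt)
  with_substream(seed, "brownian", {
    inc <- array(stats::rnorm(steps * n_particles * 3, sd = sd_step),
                 dim = c(steps, n_particles, 3))
    pos <- array(0, dim = c(steps + 1, n_particles, 3))
    pos[-1, , ] <- apply(inc, c(2, 3), cumsum)
    attr(pos, "ground_truth") <- list(D = D_true, dt = dt, seed = seed)
    attr(pos, "dt") <- dt
    pos
  })
}

#' @rdname gen_brownian
#' @param kappa_T ground-truth isothermal compressibility (1/MPa).
#' @param V_mean mean volume (nm^3).
#' @param temperature temperature (K).
#' @param n series length.
#' @export
gen_volume_series <- function(seed, kappa_T = 1.0366e-3, V_mean = 100,
                              temperature = 298.15, n = 1e5) {
  # var(V) = kappa_T kB T <V>; kappa in 1/Pa, V in m^3 -> convert
  kap_Pa <- kappa_T * 1e-6
  var_m6 <- kap_Pa * physical_constants$kB_J * temperature * V_mean * 1e-27
  sd_nm3 <- sqrt(var_m6 * 1e54)  # var(V) in nm^6: 1 m^3 = 1e27 nm^3
  with_substream(seed, "volume_series", {
    v <- stats::rnorm(n, mean = V_mean, sd = sd_nm3)
    attr(v, "ground_truth") <- list(kappa_T = kappa_T, V_mean = V_mean,
                                    temperature = temperature, seed = seed)
    v
  })
}

#' Generate a stress time series with a known Green-Kubo viscosity
#'
#' Draws the three off-diagonal pressure components as independent AR(1)
#' processes, whose exact autocorrelation is exponential with time constant
#' \eqn{\tau_c = -dt/\ln\rho} and variance \eqn{\sigma_0^2}, giving a
#' closed-form Green-Kubo viscosity.
#'
#' @param seed integer seed.
#' @param sigma0 stationary s.d. of each stress component (bar).
#' @param rho_ar AR(1) coefficient per step.
#' @param n,dt series shape (dt in ps).
#' @param volume box volume (nm^3).
#' @param temperature temperature (K).
#' @return a `stress_series` (see [viscosity_green_kubo()]) with the
#'   implied ground-truth viscosity in the attribute.
#' @export
gen_stress_series <- function(seed, sigma0 = 100, rho_ar = 0.8, n = 20000,
                              dt = 0.1, volume = 60,
                              temperature = 298.15) {
  with_substream(seed, "stress_series", {
    ar1 <- function() {
      x <- numeric(n)
      x[1] <- stats::rnorm(1, sd = sigma0)
      innov <- stats::rnorm(n - 1, sd = sigma0 * sqrt(1 - rho_ar^2))
      for (t in 2:n) x[t] <- rho_ar * x[t - 1] + innov[t - 1]
      x
    }
    s <- stress_series(time = (seq_len(n) - 1) * dt,
                       Pxy = ar1(), Pxz = ar1(), Pyz = ar1(),
                       volume = volume, temperature = temperature)
    # discrete GK integral of the exact ACF sigma0^2 rho^|k| (trapezoid):
    # sigma0^2 dt (1/2 + rho/(1-rho))
    eta_true <- gk_eta_from_acf0(sigma0^2 * dt * (0.5 + rho_ar / (1 - rho_ar)),
                                 volume, temperature)
    attr(s, "ground_truth") <- list(eta = eta_true, sigma0 = sigma0,
                                    rho_ar = rho_ar, seed = seed)
    s
  })
}

# bar^2 nm^3 ps integral -> mPa s
gk_eta_from_acf0 <- function(integral_bar2ps, volume_nm3, temperature) {
  (volume_nm3 * 1e-27) * integral_bar2ps * 1e10 * 1e-12 /
    (physical_constants$kB_J * temperature) * 1e3
}
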