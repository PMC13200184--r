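#' Evaluate energy and atomic forces for a configuration
#'
#' Computes the total potential energy (kcal/mol) and per-atom forces
#' (kcal/(mol A)) of a configuration under a Buckingham-class force field:
#' pairwise \eqn{A e^{-b r} - C_6/r^6 - C_8/r^8 + k_e q_i q_j/r} over all
#' intermolecular pairs within the cutoff (minimum-image convention when
#' periodic) and over intramolecular pairs allowed by the exclusion policy,
#' plus harmonic bond and angle terms and cosine-series dihedrals from the
#' configuration's topology. Forces are the exact analytic negative gradient
#' of the returned energy.
#'
#' Internally the energy is assembled from a decomposition into contributions
#' that are linear in the parameters (repulsion prefactors, dispersion
#' coefficients, bonded stiffnesses); `return_basis = TRUE` exposes that
#' decomposition, which the force-matching fits use to build exact linear
#' design matrices.
#'
#' @param config an [md_configuration()]; bonded terms require its `topology`.
#' @param params a [forcefield_params()].
#' @param cutoff nonbonded cutoff (Angstrom); must not exceed half the
#'   smallest box length when periodic.
#' @param exclusion intramolecular nonbonded exclusion policy: `"12-13"`
#'   (default: first and second bonded neighbours excluded, 1-4 and beyond
#'   at full strength), `"12"`, `"12-13-14"`, or `"none"`.
#' @param overlap_floor pair distances below this (Angstrom) raise a
#'   degenerate-geometry error instead of returning huge numbers.
#' @param return_basis if `TRUE`, also return the per-parameter linear basis.
#' @return list with `energy` (kcal/mol), `forces` (N x 3, kcal/(mol A)) of
#'   class `force_record`, and when requested `basis`: a list keyed
#'   `"<kind>|<type key>"` (`kind` in `A`, `C6`, `C8`, `kbond`, `kangle`,
#'   `kdih1`..`kdih3`), each with unit-parameter `energy` and `forces`, plus
#'   `rest` (the Coulomb part, not linear in per-type charges).
#' @examples
#' p <- forcefield_params(data.frame(type1 = "X", type2 = "X",
#'                                   A = 0, b = 1, C6 = 1))
#' cfg <- md_configuration(rbind(c(0, 0, 0), c(2, 0, 0)), c("C", "C"),
#'                         c(1, 2), c("X", "X"))
#' evaluate_energy_forces(cfg, p, cutoff = 10)$energy  # -1/64
#' @export
evaluate_energy_forces <- function(config, params, cutoff,
                                   exclusion = c("12-13", "12", "12-13-14",
                                                 "none"),
                                   overlap_floor = 0.1,
                                   return_basis = FALSE) {
  exclusion <- match.arg(exclusion)
  stopifnot(inherits(config, "md_configuration"),
            inherits(params, "forcefield_params"))
  if (config$periodic && cutoff > min(config$box) / 2)
    stop("cutoff exceeds half the smallest box length")
  n <- n_atoms(config)
  zero <- matrix(0, n, 3)

  basis <- list()
  rest_energy <- 0
  rest_forces <- zero
  add_basis <- function(key, energy, forces) {
    if (is.null(basis[[key]])) {
      basis[[key]] <<- list(energy = energy, forces = forces)
    } else {
      basis[[key]]$energy <<- basis[[key]]$energy + energy
      basis[[key]]$forces <<- basis[[key]]$forces + forces
    }
  }

  ## ---- nonbonded pairs -------------------------------------------------
  np <- nonbonded_pairs(config, cutoff, exclusion)
  if (nrow(np)) {
    if (any(np$r < overlap_floor))
      stop("degenerate geometry: atom pair at distance below ",
           overlap_floor, " A")
    prow <- pair_rows(params, config$types[np$i], config$types[np$j])
    pkey <- rownames(params$pairs)[prow]
    b <- params$pairs$b[prow]
    expbr <- exp(-b * np$r)
    inv6 <- np$r^-6
    inv8 <- np$r^-8
    # unit-parameter energies and dU/dr
    u_A <- expbr;            du_A <- -b * expbr
    u_C6 <- -inv6;           du_C6 <- 6 * np$r^-7
    u_C8 <- -inv8;           du_C8 <- 8 * np$r^-9
    qprod <- charge_of(params, config$types[np$i]) *
      charge_of(params, config$types[np$j])
    ke <- physical_constants$coulomb_kcal
    u_q <- ke * qprod / np$r; du_q <- -ke * qprod / np$r^2

    pair_force_mats <- function(dudr) {
      # force on i = -dU/dr * d/r with d = r_i - r_j
      s <- -dudr / np$r
      contrib <- cbind(s * np$dx, s * np$dy, s * np$dz)
      fi <- rowsum(contrib, np$i, reorder = FALSE)
      fj <- rowsum(-contrib, np$j, reorder = FALSE)
      out <- zero
      out[as.integer(rownames(fi)), ] <- out[as.integer(rownames(fi)), ] + fi
      out[as.integer(rownames(fj)), ] <- out[as.integer(rownames(fj)), ] + fj
      out
    }

    for (k in unique(pkey)) {
      sel <- pkey == k
      add_basis(paste0("A|", k), sum(u_A[sel]),
                pair_force_subset(np, sel, du_A, zero))
      add_basis(paste0("C6|", k), sum(u_C6[sel]),
                pair_force_subset(np, sel, du_C6, zero))
      if (any(params$pairs$C8 != 0))
        add_basis(paste0("C8|", k), sum(u_C8[sel]),
                  pair_force_subset(np, sel, du_C8, zero))
    }
    rest_energy <- rest_energy + sum(u_q)
    rest_forces <- rest_forces + pair_force_mats(du_q)
  }

  ## ---- bonded terms ----------------------------------------------------
  bt <- bonded_terms(config)
  if (!is.null(bt)) {
    co <- config$coords
    mi <- function(d) minimum_image(d, config)
    # bonds: U = k (r - r0)^2 per unit k
    if (nrow(bt$bonds) && nrow(params$bonds)) {
      i <- bt$bonds$i; j <- bt$bonds$j
      key <- bond_type_key(config$types[i], config$types[j])
      ridx <- match(key, rownames(params$bonds))
      if (anyNA(ridx))
        stop("missing bond parameters for: ",
             paste(unique(key[is.na(ridx)]), collapse = ", "))
      d <- mi(co[i, , drop = FALSE] - co[j, , drop = FALSE])
      r <- sqrt(rowSums(d^2))
      r0 <- params$bonds$r0[ridx]
      u <- (r - r0)^2
      dudr <- 2 * (r - r0)
      s <- -dudr / r
      contrib <- d * s
      for (k in unique(key)) {
        sel <- key == k
        f <- zero
        f <- accumulate_rows(f, i[sel], contrib[sel, , drop = FALSE])
        f <- accumulate_rows(f, j[sel], -contrib[sel, , drop = FALSE])
        add_basis(paste0("kbond|", k), sum(u[sel]), f)
      }
    }
    # angles: U = k (theta - theta0)^2 per unit k
    if (nrow(bt$angles) && nrow(params$angles)) {
      i <- bt$angles$i; j <- bt$angles$j; k3 <- bt$angles$k
      key <- angle_type_key(config$types[i], config$types[j],
                            config$types[k3])
      ridx <- match(key, rownames(params$angles))
      if (anyNA(ridx))
        stop("missing angle parameters for: ",
             paste(unique(key[is.na(ridx)]), collapse = ", "))
      u_v <- mi(co[i, , drop = FALSE] - co[j, , drop = FALSE])
      v_v <- mi(co[k3, , drop = FALSE] - co[j, , drop = FALSE])
      nu <- sqrt(rowSums(u_v^2)); nv <- sqrt(rowSums(v_v^2))
      cth <- rowSums(u_v * v_v) / (nu * nv)
      cth <- pmin(1 - 1e-12, pmax(-1 + 1e-12, cth))
      th <- acos(cth)
      sth <- sqrt(1 - cth^2)
      th0 <- params$angles$theta0[ridx]
      u_en <- (th - th0)^2
      dudth <- 2 * (th - th0)
      # dtheta/dri = -1/sin * (v/(|u||v|) - cos * u/|u|^2)
      dth_di <- -(v_v / (nu * nv) - cth * u_v / nu^2) / sth
      dth_dk <- -(u_v / (nu * nv) - cth * v_v / nv^2) / sth
      fi <- -dudth * dth_di
      fk <- -dudth * dth_dk
      fj <- -(fi + fk)
      for (kk in unique(key)) {
        sel <- key == kk
        f <- zero
        f <- accumulate_rows(f, i[sel], fi[sel, , drop = FALSE])
        f <- accumulate_rows(f, j[sel], fj[sel, , drop = FALSE])
        f <- accumulate_rows(f, k3[sel], fk[sel, , drop = FALSE])
        add_basis(paste0("kangle|", kk), sum(u_en[sel]), f)
      }
    }
    # dihedrals: U = sum_n kn (1 + cos(n phi)) per unit kn
    if (nrow(bt$dihedrals) && nrow(params$dihedrals)) {
      i <- bt$dihedrals$i; j <- bt$dihedrals$j
      k4 <- bt$dihedrals$k; l <- bt$dihedrals$l
      key <- dihedral_type_key(config$types[i], config$types[j],
                               config$types[k4], config$types[l])
      ridx <- match(key, rownames(params$dihedrals))
      if (anyNA(ridx))
        stop("missing dihedral parameters for: ",
             paste(unique(key[is.na(ridx)]), collapse = ", "))
      b1 <- mi(co[j, , drop = FALSE] - co[i, , drop = FALSE])
      b2 <- mi(co[k4, , drop = FALSE] - co[j, , drop = FALSE])
      b3 <- mi(co[l, , drop = FALSE] - co[k4, , drop = FALSE])
      n1 <- row_cross(b1, b2)
      n2 <- row_cross(b2, b3)
      n1sq <- rowSums(n1^2); n2sq <- rowSums(n2^2)
      nb2 <- sqrt(rowSums(b2^2))
      phi <- atan2(rowSums(row_cross(n1, n2) * b2) / nb2, rowSums(n1 * n2))
      # dphi/dri = -|b2|/|n1|^2 n1 ; dphi/drl = |b2|/|n2|^2 n2
      dphi_di <- -nb2 / n1sq * n1
      dphi_dl <- nb2 / n2sq * n2
      c12 <- rowSums(b1 * b2) / nb2^2
      c23 <- rowSums(b3 * b2) / nb2^2
      dphi_dj <- -(1 + c12) * dphi_di + c23 * dphi_dl
      dphi_dk <- -(dphi_di + dphi_dj + dphi_dl)
      for (nord in 1:3) {
        u_en <- 1 + cos(nord * phi)
        dudphi <- -nord * sin(nord * phi)
        fi <- -dudphi * dphi_di
        fj <- -dudphi * dphi_dj
        fk <- -dudphi * dphi_dk
        fl <- -dudphi * dphi_dl
        for (kk in unique(key)) {
          sel <- key == kk
          f <- zero
          f <- accumulate_rows(f, i[sel], fi[sel, , drop = FALSE])
          f <- accumulate_rows(f, j[sel], fj[sel, , drop = FALSE])
          f <- accumulate_rows(f, k4[sel], fk[sel, , drop = FALSE])
          f <- accumulate_rows(f, l[sel], fl[sel, , drop = FALSE])
          add_basis(paste0("kdih", nord, "|", kk), sum(u_en[sel]), f)
        }
      }
    }
  }

  ## ---- assemble from the decomposition ---------------------------------
  energy <- rest_energy
  forces <- rest_forces
  for (key in names(basis)) {
    val <- basis_param_value(params, key)
    energy <- energy + val * basis[[key]]$energy
    forces <- forces + val * basis[[key]]$forces
  }
  rec <- structure(list(forces = forces, energy = energy),
                   class = "force_record")
  out <- list(energy = energy, forces = forces, record = rec)
  if (return_basis)
    out$basis <- c(basis, list(rest = list(energy = rest_energy,
                                           forces = rest_forces)))
  out
}

# parameter value addressed by a basis key "<kind>|<type key>"
basis_param_value <- function(params, key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  kind <- parts[1]; tkey <- parts[2]
  switch(kind,
    A = params$pairs[tkey, "A"],
    C6 = params$pairs[tkey, "C6"],
    C8 = params$pairs[tkey, "C8"],
    kbond = params$bonds[tkey, "k"],
    kangle = params$angles[tkey, "k"],
    kdih1 = params$dihedrals[tkey, "k1"],
    kdih2 = params$dihedrals[tkey, "k2"],
    kdih3 = params$dihedrals[tkey, "k3"],
    stop("unknown basis kind: ", kind)
  )
}

# set the parameter addressed by a basis key (used by the fitters)
basis_param_assign <- function(params, key, value) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  kind <- parts[1]; tkey <- parts[2]
  switch(kind,
    A = params$pairs[tkey, "A"] <- value,
    C6 = params$pairs[tkey, "C6"] <- value,
    C8 = params$pairs[tkey, "C8"] <- value,
    kbond = params$bonds[tkey, "k"] <- value,
    kangle = params$angles[tkey, "k"] <- value,
    kdih1 = params$dihedrals[tkey, "k1"] <- value,
    kdih2 = params$dihedrals[tkey, "k2"] <- value,
    kdih3 = params$dihedrals[tkey, "k3"] <- value,
    stop("unknown basis kind: ", kind)
  )
  params
}

minimum_image <- function(d, config) {
  if (!config$periodic) return(d)
  for (ax in 1:3)
    d[, ax] <- d[, ax] - config$box[ax] * round(d[, ax] / config$box[ax])
  d
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

accumulate_rows <- function(mat, idx, contrib) {
  if (!length(idx)) return(mat)
  agg <- rowsum(contrib, idx, reorder = FALSE)
  rows <- as.integer(rownames(agg))
  mat[rows, ] <- mat[rows, ] + agg
  mat
}

pair_force_subset <- function(np, sel, dudr, zero) {
  s <- -dudr[sel] / np$r[sel]
  contrib <- cbind(s * np$dx[sel], s * np$dy[sel], s * np$dz[sel])
  f <- accumulate_rows(zero, np$i[sel], contrib)
  accumulate_rows(f, np$j[sel], -contrib)
}

# all nonbonded pairs within cutoff honouring the exclusion policy
nonbonded_pairs <- function(config, cutoff, exclusion) {
  n <- n_atoms(config)
  empty <- data.frame(i = integer(), j = integer(), dx = numeric(),
                      dy = numeric(), dz = numeric(), r = numeric())
  if (n < 2) return(empty)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  d <- minimum_image(config$coords[i, , drop = FALSE] -
                       config$coords[j, , drop = FALSE], config)
  r <- sqrt(rowSums(d^2))
  keep <- r <= cutoff
  same_mol <- config$molecule_id[i] == config$molecule_id[j]
  if (exclusion != "none" && any(same_mol & keep)) {
    excl <- exclusion_pairs(config, exclusion)
    if (nrow(excl)) {
      pk <- paste(i, j)
      ek <- paste(pmin(excl$i, excl$j), pmax(excl$i, excl$j))
      keep <- keep & !(pk %in% ek)
    }
  }
  data.frame(i = i[keep], j = j[keep], dx = d[keep, 1], dy = d[keep, 2],
             dz = d[keep, 3], r = r[keep])
}

# global-index pairs excluded by the policy, from the topology
exclusion_pairs <- function(config, exclusion) {
  depth <- switch(exclusion, "12" = 1L, "12-13" = 2L, "12-13-14" = 3L)
  out <- list()
  blocks <- molecule_blocks(config)
  topo <- config$topology
  if (is.null(topo)) return(data.frame(i = integer(), j = integer()))
  for (m in seq_len(nrow(blocks))) {
    g <- topo[[m]]
    off <- blocks$start[m] - 1L
    nn <- length(g$elements)
    if (nn < 2) next
    # BFS bonded distance up to `depth`
    adj <- graph_adjacency(g)
    for (a in seq_len(nn - 1L)) {
      dist <- rep(NA_integer_, nn); dist[a] <- 0L
      frontier <- a
      for (dd in seq_len(depth)) {
        nxt <- unique(unlist(adj[frontier]))
        nxt <- nxt[is.na(dist[nxt])]
        if (!length(nxt)) break
        dist[nxt] <- dd
        frontier <- nxt
      }
      hit <- which(!is.na(dist) & dist > 0L)
      hit <- hit[hit > a]
      if (length(hit))
        out[[length(out) + 1L]] <- cbind(a + off, hit + off)
    }
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer()))
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2])
}

# bond/angle/dihedral instances with global atom indices
bonded_terms <- function(config) {
  topo <- config$topology
  if (is.null(topo)) return(NULL)
  blocks <- molecule_blocks(config)
  bonds <- list(); angles <- list(); dihedrals <- list()
  for (m in seq_len(nrow(blocks))) {
    g <- topo[[m]]
    off <- blocks$start[m] - 1L
    if (nrow(g$bonds))
      bonds[[length(bonds) + 1L]] <- g$bonds + off
    ad <- enumerate_angles_dihedrals(g)
    if (nrow(ad$angles))
      angles[[length(angles) + 1L]] <- ad$angles + off
    if (nrow(ad$dihedrals))
      dihedrals[[length(dihedrals) + 1L]] <- ad$dihedrals + off
  }
  tdf <- function(lst, nm) {
    if (!length(lst))
      return(stats::setNames(as.data.frame(matrix(integer(), ncol = length(nm))), nm))
    stats::setNames(as.data.frame(do.call(rbind, lst)), nm)
  }
  list(bonds = tdf(bonds, c("i", "j")),
       angles = tdf(angles, c("i", "j", "k")),
       dihedrals = tdf(dihedrals, c("i", "j", "k", "l")))
}

#' Per-molecule net forces and torques
#'
#' Sums atomic forces into molecular net forces and computes the torque about
#' each molecule's center of mass, \eqn{\tau = \sum_i (r_i - r_{COM}) \times
#' F_i} (kcal/mol, since lever arms are in Angstrom and forces in
#' kcal/(mol A)).
#'
#' @param forces N x 3 force matrix (or a `force_record`).
#' @param config the matching [md_configuration()].
#' @return data.frame with one row per molecule: `molecule`, `fx, fy, fz`
#'   (net force) and `tx, ty, tz` (torque about the COM).
#' @export
molecular_force_torque <- function(forces, config) {
  if (inherits(forces, "force_record")) forces <- forces$forces
  stopifnot(nrow(forces) == n_atoms(config))
  blocks <- molecule_blocks(config)
  out <- vector("list", nrow(blocks))
  mass <- atomic_mass(config$elements)
  for (m in seq_len(nrow(blocks))) {
    sel <- blocks$start[m]:blocks$end[m]
    if (!length(sel)) stop("molecule with zero atoms")
    f <- forces[sel, , drop = FALSE]
    co <- config$coords[sel, , drop = FALSE]
    w <- mass[sel]
    if (sum(w) <= 0) stop("molecule with zero total mass")
    com <- colSums(co * w) / sum(w)
    arm <- sweep(co, 2, com)
    tq <- colSums(row_cross(arm, f))
    out[[m]] <- c(blocks$molecule[m], colSums(f), tq)
  }
  res <- as.data.frame(do.call(rbind, out))
  names(res) <- c("molecule", "fx", "fy", "fz", "tx", "ty", "tz")
  res
}
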