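#' Fit-stage specification
#'
#' One stage of a staged force-matching fit: which parameters are free, how
#' the three observable classes are weighted, and an optional ridge penalty.
#' Parameters are addressed by ids `"<kind>|<type key>"`:
#' linear kinds `A`, `C6`, `C8`, `kbond`, `kangle`, `kdih1`..`kdih3`;
#' nonlinear kinds `b` (pair key), `q` (type), `r0` (bond key), `theta0`
#' (angle key). Dispersion coefficients come from an upstream fit and stay
#' frozen unless explicitly freed.
#'
#' Torque residuals are divided by a 1 Angstrom lever arm so all three
#' observable classes share force units; the default weights are neutral
#' (1:1:1).
#'
#' @param free character vector of free-parameter ids.
#' @param w_atomic,w_molforce,w_torque observable weights.
#' @param ridge ridge penalty lambda on the linear solve (0 = none).
#' @param name optional stage label.
#' @return An object of class `fit_stage`.
#' @export
fit_stage_spec <- function(free, w_atomic = 1, w_molforce = 1,
                           w_torque = 1, ridge = 0, name = "stage") {
  stopifnot(length(free) >= 1, all(grepl("\\|", free)))
  kinds <- sub("\\|.*", "", free)
  known <- c("A", "C6", "C8", "kbond", "kangle", "kdih1", "kdih2", "kdih3",
             "b", "q", "r0", "theta0")
  bad <- setdiff(kinds, known)
  if (length(bad)) stop("unknown parameter kind(s): ",
                        paste(unique(bad), collapse = ", "))
  structure(list(free = free, w_atomic = w_atomic, w_molforce = w_molforce,
                 w_torque = w_torque, ridge = ridge, name = name),
            class = "fit_stage")
}

.LINEAR_KINDS <- c("A", "C6", "C8", "kbond", "kangle",
                   "kdih1", "kdih2", "kdih3")

# bounds for nonlinear parameter kinds
nonlinear_bounds <- function(ids) {
  kinds <- sub("\\|.*", "", ids)
  lower <- c(b = 1, q = -2, r0 = 0.5, theta0 = 0.5)[kinds]
  upper <- c(b = 10, q = 2, r0 = 3, theta0 = 3.1)[kinds]
  list(lower = unname(lower), upper = unname(upper))
}

nonlinear_value <- function(params, id) {
  parts <- strsplit(id, "|", fixed = TRUE)[[1]]
  switch(parts[1],
    b = params$pairs[parts[2], "b"],
    q = unname(params$charges[parts[2]]),
    r0 = params$bonds[parts[2], "r0"],
    theta0 = params$angles[parts[2], "theta0"],
    stop("not a nonlinear parameter kind: ", parts[1]))
}

nonlinear_assign <- function(params, id, value) {
  parts <- strsplit(id, "|", fixed = TRUE)[[1]]
  switch(parts[1],
    b = params$pairs[parts[2], "b"] <- value,
    q = params$charges[parts[2]] <- value,
    r0 = params$bonds[parts[2], "r0"] <- value,
    theta0 = params$angles[parts[2], "theta0"] <- value,
    stop("not a nonlinear parameter kind: ", parts[1]))
  params
}

# molecules whose atoms are all inside the active mask
masked_molecules <- function(config, mask) {
  blocks <- molecule_blocks(config)
  keep <- vapply(seq_len(nrow(blocks)), function(m)
    all(mask[blocks$start[m]:blocks$end[m]]), logical(1))
  blocks[keep, , drop = FALSE]
}

# torque of an arbitrary force field about each molecule's COM (linear in F)
component_vector <- function(F, config, mask, blocks, weights,
                             torque_lever = 1) {
  out <- list(sqrt(weights$w_atomic) * as.numeric(F[mask, , drop = FALSE]))
  if (nrow(blocks)) {
    mf <- matrix(0, nrow(blocks), 3)
    tq <- matrix(0, nrow(blocks), 3)
    mass <- atomic_mass(config$elements)
    for (m in seq_len(nrow(blocks))) {
      sel <- blocks$start[m]:blocks$end[m]
      f <- F[sel, , drop = FALSE]
      mf[m, ] <- colSums(f)
      co <- config$coords[sel, , drop = FALSE]
      com <- colSums(co * mass[sel]) / sum(mass[sel])
      tq[m, ] <- colSums(row_cross(sweep(co, 2, com), f))
    }
    out <- c(out, list(sqrt(weights$w_molforce) * as.numeric(mf),
                       sqrt(weights$w_torque) * as.numeric(tq) /
                         torque_lever))
  }
  unlist(out)
}

# componentized basis cache: the basis force arrays depend on the
# configurations and the nonlinear parameters only, so across linear-only
# stages and cycles they can be computed once and reused
component_cache <- function(params, records, stage, cutoff) {
  weights <- stage[c("w_atomic", "w_molforce", "w_torque")]
  recs <- lapply(records, function(rec) {
    config <- rec$config
    blocks <- masked_molecules(config, rec$mask)
    ev <- evaluate_energy_forces(config, params, cutoff = cutoff,
                                 return_basis = TRUE)
    comp <- lapply(ev$basis, function(bb)
      component_vector(bb$forces, config, rec$mask, blocks, weights))
    list(ref = component_vector(rec$ref_forces, config, rec$mask, blocks,
                                weights),
         comp = comp)
  })
  list(weights = weights, recs = recs)
}

# reference vector, offset (frozen-model) vector and design columns for the
# free linear ids, assembled from a component cache
stage_design <- function(params, records, stage, cutoff, free_linear,
                         cache = NULL) {
  if (is.null(cache) ||
      !identical(cache$weights, stage[c("w_atomic", "w_molforce",
                                        "w_torque")]))
    cache <- component_cache(params, records, stage, cutoff)
  refs <- list(); offsets <- list(); designs <- list()
  for (rc in cache$recs) {
    comp <- rc$comp
    offset <- comp$rest
    for (key in setdiff(names(comp), c("rest", free_linear))) {
      val <- basis_param_value(params, key)
      if (val != 0) offset <- offset + val * comp[[key]]
    }
    X <- matrix(0, length(rc$ref), length(free_linear))
    for (ci in seq_along(free_linear)) {
      key <- free_linear[ci]
      if (!is.null(comp[[key]])) X[, ci] <- comp[[key]]
    }
    refs[[length(refs) + 1L]] <- rc$ref
    offsets[[length(offsets) + 1L]] <- offset
    designs[[length(designs) + 1L]] <- X
  }
  list(ref = unlist(refs), offset = unlist(offsets),
       X = do.call(rbind, designs))
}

# ridge-aware linear solve with rank handling. Rows whose design is
# entirely zero carry no information about the free parameters and are
# dropped (they would only add a constant to the objective). Columns are
# equilibrated to unit norm before solving: the raw bases span many orders
# of magnitude (exp(-b r) at contact vs harmonic bonded terms), and both
# rank detection and the ridge penalty should act on the scaled problem.
solve_linear_stage <- function(X, y, ridge, free_linear,
                               singular_action = c("auto_ridge", "error")) {
  singular_action <- match.arg(singular_action)
  keep <- rowSums(abs(X)) > 0
  Xk <- X[keep, , drop = FALSE]
  yk <- y[keep]
  if (nrow(Xk) < ncol(Xk))
    stop("fewer informative residual components (", nrow(Xk),
         ") than free parameters (", ncol(Xk), ")")
  cs <- sqrt(colSums(Xk^2))
  cs[cs == 0] <- 1
  Xs <- sweep(Xk, 2, cs, `/`)
  qr_ <- qr(Xs)
  if (qr_$rank < ncol(Xs) && ridge <= 0) {
    uncon <- free_linear[qr_$pivot[(qr_$rank + 1):ncol(Xs)]]
    if (singular_action == "error")
      stop("singular fit: unconstrained parameter(s) ",
           paste(uncon, collapse = ", "))
    warning("rank-deficient design (unconstrained: ",
            paste(uncon, collapse = ", "),
            "); enabling ridge penalty 1e-8")
    ridge <- 1e-8
  }
  if (ridge > 0) {
    Xa <- rbind(Xs, sqrt(ridge) * diag(ncol(Xs)))
    ya <- c(yk, numeric(ncol(Xs)))
    theta_s <- qr.coef(qr(Xa), ya)
  } else {
    theta_s <- qr.coef(qr_, yk)
  }
  theta_s[is.na(theta_s)] <- 0
  theta <- theta_s / cs
  resid <- yk - Xk %*% theta
  list(theta = as.numeric(theta), rss = sum(resid^2))
}

#' Weighted force-matching residual vector
#'
#' The residuals the stage objective minimises:
#' \eqn{\sqrt{w}\,(\mathrm{model} - \mathrm{reference})} concatenated over
#' atomic-force components of active (masked) atoms, molecular net-force
#' components, and molecular torque components of fully active molecules,
#' record by record.
#'
#' @param params a [forcefield_params()].
#' @param records list of `training_record`s (see [gen_training_set()]).
#' @param stage a [fit_stage_spec()] (only its weights are used here).
#' @param cutoff nonbonded cutoff (Angstrom).
#' @return numeric residual vector.
#' @export
fm_residuals <- function(params, records, stage = fit_stage_spec("A|none"),
                         cutoff = 12) {
  if (!length(records)) stop("empty training set")
  weights <- stage[c("w_atomic", "w_molforce", "w_torque")]
  out <- lapply(records, function(rec) {
    ev <- evaluate_energy_forces(rec$config, params, cutoff = cutoff)
    blocks <- masked_molecules(rec$config, rec$mask)
    component_vector(ev$forces, rec$config, rec$mask, blocks, weights) -
      component_vector(rec$ref_forces, rec$config, rec$mask, blocks,
                       weights)
  })
  unlist(out)
}

#' Fit one stage of a staged force-matching fit
#'
#' Minimises the weighted least-squares objective over the stage's free
#' parameters. Parameters in which the model forces are linear (repulsion
#' prefactors, dispersion coefficients, bonded stiffnesses) are solved by
#' exact linear least squares; nonlinear parameters (repulsion decays `b`,
#' charges `q`, equilibrium geometry `r0`, `theta0`) are refined by a
#' bounded quasi-Newton search wrapping the linear solve. All parameters
#' not named in the stage are returned bit-identical.
#'
#' @param params starting [forcefield_params()].
#' @param records list of `training_record`s.
#' @param stage a [fit_stage_spec()].
#' @param cutoff nonbonded cutoff (Angstrom).
#' @param singular_action on a rank-deficient linear design with no ridge:
#'   `"auto_ridge"` (warn, apply lambda = 1e-8) or `"error"` (name the
#'   unconstrained parameters).
#' @param reltol objective tolerance of the nonlinear refinement.
#' @param cache optional component cache from an earlier evaluation with
#'   identical nonlinear parameters (managed by [fit_forcefield()]);
#'   ignored whenever the stage frees nonlinear parameters.
#' @return updated `forcefield_params`, with the achieved stage objective in
#'   attribute `"stage_rss"`.
#' @export
fit_stage <- function(params, records, stage, cutoff = 12,
                      singular_action = c("auto_ridge", "error"),
                      reltol = 1e-10, cache = NULL) {
  singular_action <- match.arg(singular_action)
  if (!length(records)) stop("empty training set")
  kinds <- sub("\\|.*", "", stage$free)
  free_linear <- stage$free[kinds %in% .LINEAR_KINDS]
  free_nonlin <- stage$free[!kinds %in% .LINEAR_KINDS]
  if (length(free_nonlin)) cache <- NULL  # basis changes under the search

  solve_at <- function(p, use_cache = cache) {
    if (!length(free_linear)) {
      r <- fm_residuals(p, records, stage, cutoff)
      return(list(params = p, rss = sum(r^2)))
    }
    sd_ <- stage_design(p, records, stage, cutoff, free_linear, use_cache)
    sol <- solve_linear_stage(sd_$X, sd_$ref - sd_$offset, stage$ridge,
                              free_linear, singular_action)
    for (ci in seq_along(free_linear))
      p <- basis_param_assign(p, free_linear[ci], sol$theta[ci])
    list(params = p, rss = sol$rss)
  }

  if (length(free_nonlin)) {
    v0 <- vapply(free_nonlin, function(id) nonlinear_value(params, id),
                 numeric(1))
    bounds <- nonlinear_bounds(free_nonlin)
    objective <- function(v) {
      p <- params
      for (k in seq_along(free_nonlin))
        p <- nonlinear_assign(p, free_nonlin[k], v[k])
      solve_at(p)$rss
    }
    opt <- if (length(free_nonlin) == 1) {
      o <- stats::optimize(objective, lower = bounds$lower,
                           upper = bounds$upper, tol = 1e-8)
      list(par = o$minimum, value = o$objective)
    } else {
      stats::optim(v0, objective, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(factr = reltol / .Machine$double.eps,
                                  maxit = 200))
    }
    # keep whichever of start/optimum is better (bounded searches can
    # return an interior probe worse than a start on the boundary)
    if (objective(opt$par) <= objective(v0)) v_best <- opt$par
    else v_best <- v0
    for (k in seq_along(free_nonlin))
      params <- nonlinear_assign(params, free_nonlin[k], v_best[k])
  }
  final <- solve_at(params)
  structure(final$params, stage_rss = final$rss,
            class = class(final$params))
}

#' Run a sequence of fit stages
#'
#' Applies [fit_stage()] stage by stage (the staged convention: dispersion
#' frozen throughout, intermolecular parameters before intramolecular
#' ones). Because each stage holds the other stages' parameters fixed, the
#' stage list is cycled until the objective stabilises (block coordinate
#' descent); with every stage linear this converges to the joint optimum.
#'
#' @param params starting [forcefield_params()].
#' @param records list of `training_record`s.
#' @param stages list of [fit_stage_spec()]s.
#' @param cutoff nonbonded cutoff (Angstrom).
#' @param max_cycles maximum passes over the stage list.
#' @param tol stop when the relative objective change between cycles falls
#'   below this.
#' @param final_joint after the staged cycles, refine all linear free
#'   parameters of every stage in one simultaneous exact least-squares
#'   solve (the staged objective is linear in them once the nonlinear
#'   parameters have settled, so this lands on the joint optimum instead
#'   of approaching it at the block-descent rate).
#' @param ... passed to [fit_stage()].
#' @return fitted `forcefield_params` with attribute `"stage_history"`
#'   (data.frame of cycle, stage name and objective).
#' @export
fit_forcefield <- function(params, records, stages, cutoff = 12,
                           max_cycles = 25, tol = 1e-10,
                           final_joint = TRUE, ...) {
  hist <- data.frame(cycle = integer(), stage = character(),
                     rss = numeric())
  last <- Inf
  cache <- NULL
  for (cyc in seq_len(max_cycles)) {
    for (st in stages) {
      st_nonlin <- any(!sub("\\|.*", "", st$free) %in% .LINEAR_KINDS)
      if (is.null(cache) && !st_nonlin)
        cache <- component_cache(params, records, st, cutoff)
      params <- fit_stage(params, records, st, cutoff = cutoff,
                          cache = cache, ...)
      if (st_nonlin) cache <- NULL  # nonlinear params moved: basis stale
      hist <- rbind(hist, data.frame(cycle = cyc, stage = st$name,
                                     rss = attr(params, "stage_rss")))
    }
    cur <- utils::tail(hist$rss, 1)
    if (is.finite(last) &&
        abs(last - cur) <= tol * max(cur, .Machine$double.eps)) break
    last <- cur
  }
  all_free <- unique(unlist(lapply(stages, `[[`, "free")))
  all_linear <- all_free[sub("\\|.*", "", all_free) %in% .LINEAR_KINDS]
  if (final_joint && length(all_linear)) {
    joint <- stages[[1]]
    joint$free <- all_linear
    joint$name <- "joint linear refinement"
    params <- fit_stage(params, records, joint, cutoff = cutoff,
                        cache = cache, ...)
    hist <- rbind(hist, data.frame(cycle = NA_integer_, stage = joint$name,
                                   rss = attr(params, "stage_rss")))
  }
  attr(params, "stage_history") <- hist
  params
}

#' Default stage lists
#'
#' The staged-fit conventions used by the synthetic scenarios:
#' intermolecular repulsion prefactors before intramolecular stiffnesses,
#' with solute-solvent cross pairs in their own stage (they are determined
#' exclusively by solvent-containing records). Dispersion stays frozen in
#' every stage. `groups` selects which stage groups to build: a
#' hydrated-only fit uses `c("cross", "intra")` (infinite-dilution records
#' cannot constrain solute-solute intermolecular repulsion), a neat fit
#' `c("solute", "intra")`, the joint mixed-phase refit
#' `c("solute", "intra")` with cross pairs frozen.
#'
#' @param params a [forcefield_params()] (used to enumerate keys).
#' @param solvent_types type labels belonging to the solvent surrogate.
#' @param groups stage groups to include, in order: `"cross"`
#'   (solute-solvent A), `"solute"` (solute-solute A), `"intra"` (bonded
#'   stiffnesses).
#' @param free_b also free the repulsion decays `b` of the intermolecular
#'   stages.
#' @param ridge ridge penalty for every stage.
#' @return list of [fit_stage_spec()]s.
#' @export
default_fit_stages <- function(params, solvent_types = c("OW", "HW"),
                               groups = c("cross", "solute", "intra"),
                               free_b = FALSE, ridge = 0) {
  pk <- rownames(params$pairs)
  involves_solvent <- vapply(strsplit(pk, "-"), function(p)
    any(p %in% solvent_types), logical(1))
  solvent_only <- vapply(strsplit(pk, "-"), function(p)
    all(p %in% solvent_types), logical(1))
  cross <- involves_solvent & !solvent_only
  addA <- function(keys) {
    ids <- paste0("A|", keys)
    if (free_b) ids <- c(ids, paste0("b|", keys))
    ids
  }
  # bonded terms internal to the solvent belong to the fixed solvent model
  not_solvent_key <- function(keys) {
    keys[!vapply(strsplit(keys, "-"), function(p)
      all(p %in% solvent_types), logical(1))]
  }
  intra <- c(
    if (nrow(params$bonds))
      paste0("kbond|", not_solvent_key(rownames(params$bonds))),
    if (nrow(params$angles))
      paste0("kangle|", not_solvent_key(rownames(params$angles))),
    if (nrow(params$dihedrals))
      as.vector(outer(c("kdih1|", "kdih2|", "kdih3|"),
                      not_solvent_key(rownames(params$dihedrals)), paste0))
  )
  stages <- list()
  for (g in groups) {
    if (g == "cross" && any(cross))
      stages <- c(stages, list(fit_stage_spec(
        addA(pk[cross]), ridge = ridge,
        name = "intermolecular solute-solvent")))
    if (g == "solute" && any(!involves_solvent))
      stages <- c(stages, list(fit_stage_spec(
        addA(pk[!involves_solvent]), ridge = ridge,
        name = "intermolecular solute-solute")))
    if (g == "intra" && length(intra))
      stages <- c(stages, list(fit_stage_spec(intra, ridge = ridge,
                                              name = "intramolecular")))
  }
  stages
}

#' Joint mixed-phase fit
#'
#' Fits one parameter set to neat and hydrated training records together,
#' following the staged convention for mixed-phase models. The charge
#' policy fixes the partial charges to the hydrated-model values
#' (`charges`). Solute-solvent nonbonded parameters are determined by an
#' inner hydrated-only fit -- neat records contain no solute-solvent pairs
#' and cannot inform them -- and are then frozen while a single
#' solute-solute nonbonded and bonded parameter set is fitted across both
#' phases. The solute-solvent parameters of the joint fit are therefore
#' identical to those of a hydrated-only fit started from the same initial
#' values. With an empty neat set the result is exactly the hydrated-only
#' fit.
#'
#' @param neat_records,hydrated_records training-record lists; phase tags
#'   must be present and consistent.
#' @param params starting [forcefield_params()] covering both phases.
#' @param charges named charge vector imposed by the policy (defaults to
#'   the charges already in `params`).
#' @param cutoff nonbonded cutoff (Angstrom).
#' @param solvent_types type labels belonging to the solvent.
#' @param ... passed to [fit_forcefield()].
#' @return fitted `forcefield_params`.
#' @export
joint_mixed_phase_fit <- function(neat_records, hydrated_records, params,
                                  charges = params$charges, cutoff = 12,
                                  solvent_types = c("OW", "HW"), ...) {
  if (!length(hydrated_records)) stop("hydrated record set is empty")
  tags <- vapply(c(neat_records, hydrated_records),
                 function(r) r$phase %||% NA_character_, character(1))
  if (anyNA(tags)) stop("phase tags missing on some records")
  params$charges[names(charges)] <- charges
  # phase 1: complete hydrated-only fit (solute-solute terms are freed too:
  # hydrated records constrain them through intramolecular 1-4 pairs, and
  # freezing them at arbitrary start values would bias the cross pairs)
  hyd_stages <- default_fit_stages(params, solvent_types)
  fit_h <- fit_forcefield(params, hydrated_records, hyd_stages,
                          cutoff = cutoff, ...)
  if (!length(neat_records)) return(fit_h)
  joint_stages <- default_fit_stages(fit_h, solvent_types,
                                     groups = c("solute", "intra"))
  fit_forcefield(fit_h, c(neat_records, hydrated_records), joint_stages,
                 cutoff = cutoff, ...)
}

#' Regression metrics between model and reference values
#'
#' RMSE, regression slope and R-squared between pooled model and reference
#' vector components. Forces are signed and symmetric about zero, so the
#' default regression is through the origin (slope
#' \eqn{\sum m r / \sum r^2}, uncentered R-squared); set
#' `intercept = TRUE` for the ordinary convention.
#'
#' @param model,reference numeric vectors of equal length >= 2.
#' @param intercept include an intercept in the regression.
#' @return named numeric `c(rmse, slope, r_squared)`.
#' @export
regression_metrics <- function(model, reference, intercept = FALSE) {
  if (length(model) != length(reference)) stop("length mismatch")
  if (length(model) < 2) stop("need at least 2 values")
  rmse <- sqrt(mean((model - reference)^2))
  if (intercept) {
    fit <- stats::lm(model ~ reference)
    slope <- stats::coef(fit)[[2]]
    r2 <- summary(fit)$r.squared
  } else {
    slope <- sum(model * reference) / sum(reference^2)
    r2 <- sum(model * reference)^2 / (sum(model^2) * sum(reference^2))
  }
  c(rmse = rmse, slope = slope, r_squared = r2)
}

#' Fit-quality metrics per observable class
#'
#' Computes [regression_metrics()] for the three observable classes of a
#' training set under a parameter set: molecular net force, molecular
#' torque, atomic force (pooled vector components of active atoms and
#' fully-active molecules).
#'
#' @param params a [forcefield_params()].
#' @param records list of `training_record`s.
#' @param cutoff nonbonded cutoff (Angstrom).
#' @param intercept regression convention, as in [regression_metrics()].
#' @return data.frame of class `fit_metrics` with one row per observable
#'   class: `rmse`, `slope`, `r_squared`, and the units of each class.
#' @export
fit_metrics <- function(params, records, cutoff = 12, intercept = FALSE) {
  if (!length(records)) stop("empty training set")
  pools <- list(atomic = list(m = c(), r = c()),
                molforce = list(m = c(), r = c()),
                torque = list(m = c(), r = c()))
  for (rec in records) {
    ev <- evaluate_energy_forces(rec$config, params, cutoff = cutoff)
    blocks <- masked_molecules(rec$config, rec$mask)
    w1 <- list(w_atomic = 1, w_molforce = 0, w_torque = 0)
    pools$atomic$m <- c(pools$atomic$m,
                        as.numeric(ev$forces[rec$mask, , drop = FALSE]))
    pools$atomic$r <- c(pools$atomic$r,
                        as.numeric(rec$ref_forces[rec$mask, , drop = FALSE]))
    mtq_m <- molecular_force_torque(ev$forces, rec$config)
    mtq_r <- molecular_force_torque(rec$ref_forces, rec$config)
    keep <- mtq_m$molecule %in% blocks$molecule
    pools$molforce$m <- c(pools$molforce$m,
                          unlist(mtq_m[keep, c("fx", "fy", "fz")]))
    pools$molforce$r <- c(pools$molforce$r,
                          unlist(mtq_r[keep, c("fx", "fy", "fz")]))
    pools$torque$m <- c(pools$torque$m,
                        unlist(mtq_m[keep, c("tx", "ty", "tz")]))
    pools$torque$r <- c(pools$torque$r,
                        unlist(mtq_r[keep, c("tx", "ty", "tz")]))
  }
  rows <- lapply(names(pools), function(nm)
    regression_metrics(pools[[nm]]$m, pools[[nm]]$r, intercept = intercept))
  out <- as.data.frame(do.call(rbind, rows))
  out$class <- c("atomic force", "molecular force", "molecular torque")
  out$units <- c("kcal/(mol A)", "kcal/(mol A)", "kcal/mol")
  structure(out[, c("class", "rmse", "slope", "r_squared", "units")],
            class = c("fit_metrics", "data.frame"))
}
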