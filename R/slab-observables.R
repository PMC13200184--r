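#' Slab observable containers
#'
#' `density_profile` holds a binned mass-density profile along the slab
#' normal; `pressure_tensor_series` holds the time-resolved diagonal
#' pressure components of a slab simulation together with the box length
#' along the normal.
#'
#' @param z uniform bin centers along the slab normal (nm).
#' @param density mass density per bin (g/L), non-negative.
#' @param n_frames number of frames averaged into the profile.
#' @return An object of class `density_profile`.
#' @export
density_profile <- function(z, density, n_frames = 1L) {
  stopifnot(length(z) == length(density), length(z) >= 2)
  dz <- diff(z)
  if (any(abs(dz - dz[1]) > 1e-8 * abs(dz[1])))
    stop("bins must be uniform")
  if (any(density < 0)) stop("densities must be >= 0")
  structure(list(z = z, density = density, n_frames = as.integer(n_frames)),
            class = "density_profile")
}

#' @rdname density_profile
#' @param time sample times (ps).
#' @param PX,PY,PZ diagonal pressure-tensor components (bar).
#' @param L_Z box length along the slab normal (nm).
#' @export
pressure_tensor_series <- function(time, PX, PY, PZ, L_Z) {
  n <- length(time)
  stopifnot(length(PX) == n, length(PY) == n, length(PZ) == n)
  if (L_Z <= 0) stop("L_Z must be > 0")
  structure(list(time = time, PX = PX, PY = PY, PZ = PZ, L_Z = L_Z),
            class = "pressure_tensor_series")
}

#' @export
print.density_profile <- function(x, ...) {
  cat("density_profile:", length(x$z), "bins over",
      sprintf("%.2f-%.2f nm,", min(x$z), max(x$z)),
      x$n_frames, "frames; max", sprintf("%.1f g/L", max(x$density)), "\n")
  invisible(x)
}

#' @export
print.pressure_tensor_series <- function(x, ...) {
  cat("pressure_tensor_series:", length(x$time), "samples, L_Z =",
      x$L_Z, "nm\n")
  invisible(x)
}

#' Mass-density profile from configuration frames
#'
#' Bins atoms by coordinate along one axis, mass-weights them, and averages
#' over frames. Total mass is conserved: the sum of bin density times bin
#' volume equals the per-frame total mass.
#'
#' @param frames list of [md_configuration()]s sharing one box.
#' @param axis 1, 2 or 3 (x, y, z).
#' @param n_bins number of bins (>= 10).
#' @return a [density_profile()] with `z` in nm and density in g/L.
#' @export
profile_from_frames <- function(frames, axis = 3, n_bins = 100) {
  if (!length(frames)) stop("zero frames")
  if (n_bins < 10) stop("n_bins must be >= 10")
  box <- frames[[1]]$box
  for (f in frames)
    if (any(abs(f$box - box) > 1e-9)) stop("inconsistent box across frames")
  L <- box[axis]                       # Angstrom
  edges <- seq(0, L, length.out = n_bins + 1)
  bin_volume_A3 <- prod(box[-axis]) * (L / n_bins)
  acc <- numeric(n_bins)
  for (f in frames) {
    x <- f$coords[, axis] %% L
    idx <- pmin(n_bins, pmax(1L, findInterval(x, edges,
                                              rightmost.closed = TRUE)))
    agg <- rowsum(atomic_mass(f$elements), idx)
    bins <- numeric(n_bins)
    bins[as.integer(rownames(agg))] <- agg[, 1]
    acc <- acc + bins
  }
  mass_per_bin <- acc / length(frames)          # g/mol per bin
  # g/mol / A^3 -> g/L: 1 A^3 = 1e-27 L; mass g = mass_gmol / N_A
  dens <- mass_per_bin / physical_constants$avogadro / (bin_volume_A3 * 1e-27)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2 / 10  # A -> nm
  density_profile(z = centers, density = dens, n_frames = length(frames))
}

#' Two-step cavity-robust liquid density
#'
#' Step 1 identifies the liquid region as the longest contiguous run of bins
#' above `interface_threshold` (a fraction of the profile's dynamic range);
#' step 2 averages the density over the central `core_fraction` of that run.
#' Measuring only the core makes the estimate insensitive to cavities and
#' interface roughness that would bias a naive maximum-density shortcut.
#'
#' @param profile a [density_profile()].
#' @param interface_threshold fraction of (max - min) above min defining
#'   liquid bins.
#' @param core_fraction central fraction of the liquid run to average.
#' @return liquid density (g/L).
#' @export
liquid_core_density <- function(profile, interface_threshold = 0.5,
                                core_fraction = 0.5) {
  run <- liquid_run(profile, interface_threshold)
  n <- run$end - run$start + 1L
  ncore <- max(1L, floor(n * core_fraction))
  lo <- run$start + (n - ncore) %/% 2
  mean(profile$density[lo:(lo + ncore - 1L)])
}

# longest contiguous run of bins above the threshold
liquid_run <- function(profile, interface_threshold) {
  d <- profile$density
  thr <- min(d) + interface_threshold * (max(d) - min(d))
  above <- d >= thr
  if (!any(above)) stop("no-liquid error: no bin exceeds the threshold")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]
  list(start = starts[best], end = ends[best], threshold = thr)
}

#' Coexistence densities from a slab profile
#'
#' Liquid density from [liquid_core_density()]; vapor density as the mean
#' over bins farther than `vapor_buffer` from either edge of the liquid run.
#'
#' @inheritParams liquid_core_density
#' @param vapor_buffer distance (nm) to keep clear of the liquid edges.
#' @return named numeric `c(rho_l, rho_g)` (g/L).
#' @export
coexistence_densities <- function(profile, interface_threshold = 0.5,
                                  core_fraction = 0.5, vapor_buffer = 1) {
  run <- liquid_run(profile, interface_threshold)
  rho_l <- liquid_core_density(profile, interface_threshold, core_fraction)
  z <- profile$z
  zlo <- z[run$start]; zhi <- z[run$end]
  vap <- which(z < zlo - vapor_buffer | z > zhi + vapor_buffer)
  if (!length(vap))
    stop("vapor region shorter than the buffer: no vapor bins left")
  c(rho_l = rho_l, rho_g = mean(profile$density[vap]))
}

#' Surface tension from the pressure tensor
#'
#' \deqn{\gamma = \frac{L_Z}{2}\left(\langle P_Z\rangle -
#'   \frac{\langle P_X\rangle + \langle P_Y\rangle}{2}\right)}
#' with the factor 2 accounting for the slab's two interfaces; the result is
#' converted from bar nm to mN/m (x 0.1). The standard error is estimated by
#' block averaging. The identical estimator applies to a liquid-liquid
#' interfacial-tension slab; only the box contents differ.
#'
#' @param series a [pressure_tensor_series()].
#' @param n_blocks blocks for the standard-error estimate.
#' @return named numeric `c(gamma, se)` in mN/m.
#' @export
surface_tension <- function(series, n_blocks = 5) {
  stopifnot(inherits(series, "pressure_tensor_series"))
  if (length(series$time) < 2) stop("need >= 2 samples for an error estimate")
  aniso <- series$PZ - (series$PX + series$PY) / 2           # bar
  g_inst <- series$L_Z / 2 * aniso * physical_constants$bar_nm_to_mN_m
  c(gamma = mean(g_inst), se = block_se(g_inst, n_blocks))
}

#' Mean normal pressure of a slab
#'
#' Mean and block-averaged standard error of `P_Z`, the pressure normal to
#' the slab surface; feeds the Antoine fits.
#'
#' @inheritParams surface_tension
#' @return named numeric `c(P, se)` (bar).
#' @export
normal_pressure <- function(series, n_blocks = 5) {
  stopifnot(inherits(series, "pressure_tensor_series"))
  c(P = mean(series$PZ), se = block_se(series$PZ, n_blocks))
}

# block-averaged standard error of the mean (1 sigma)
block_se <- function(x, n_blocks = 5) {
  n <- length(x)
  if (n < n_blocks) return(stats::sd(x) / sqrt(n))
  size <- n %/% n_blocks
  means <- vapply(seq_len(n_blocks), function(b)
    mean(x[((b - 1) * size + 1):(b * size)]), numeric(1))
  stats::sd(means) / sqrt(n_blocks)
}
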