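#' Mean-squared displacement from a trajectory
#'
#' Multiple-time-origin MSD: for each lag, displacements are averaged over
#' particles and over time origins taken every `origin_stride` frames (a
#' cost/variance trade-off).
#'
#' @param positions array `frames x particles x 3` of unwrapped coordinates
#'   (Angstrom), e.g. from [gen_brownian()].
#' @param dt time between frames (ps); taken from the array's `dt`
#'   attribute when present.
#' @param max_lag_fraction largest lag as a fraction of the trajectory.
#' @param origin_stride frames between time origins.
#' @param n_lag_points at most this many lag values are evaluated, evenly
#'   spaced up to the maximum lag (the curve is smooth; sampling every lag
#'   of a long trajectory buys nothing but cost).
#' @return An object of class `msd_curve`: data.frame with `lag` (ps),
#'   `msd` (A^2, with `msd[lag=0] = 0`), `n_samples`; `dt` and particle
#'   count in attributes.
#' @export
msd_from_trajectory <- function(positions, dt = attr(positions, "dt") %||% 1,
                                max_lag_fraction = 0.5,
                                origin_stride = 10,
                                n_lag_points = 200) {
  stopifnot(length(dim(positions)) == 3, dim(positions)[3] == 3)
  n_frames <- dim(positions)[1]
  n_part <- dim(positions)[2]
  if (n_frames < 100) stop("too few frames (need >= 100)")
  n_lag <- max(2L, floor((n_frames - 1) * max_lag_fraction))
  lags <- unique(round(seq(1L, n_lag, length.out = min(n_lag_points,
                                                       n_lag))))
  origins <- seq(1L, n_frames - 1L, by = origin_stride)
  msd <- numeric(length(lags))
  cnt <- integer(length(lags))
  for (li in seq_along(lags)) {
    lag <- lags[li]
    orig <- origins[origins + lag <= n_frames]
    if (!length(orig)) { msd <- msd[1:(li - 1)]; cnt <- cnt[1:(li - 1)]
      lags <- lags[1:(li - 1)]; break }
    d <- positions[orig + lag, , , drop = FALSE] -
      positions[orig, , , drop = FALSE]
    # per-origin sum over particles and xyz, then per-particle average
    msd[li] <- mean(rowSums(matrix(d, nrow = length(orig))^2) / n_part)
    cnt[li] <- length(orig) * n_part
  }
  structure(data.frame(lag = c(0, lags) * dt, msd = c(0, msd),
                       n_samples = c(length(origins) * n_part, cnt)),
            class = c("msd_curve", "data.frame"), dt = dt,
            n_particles = n_part)
}

#' Diffusion constant from an MSD curve
#'
#' Einstein relation in three dimensions: \eqn{D = \mathrm{slope}/6} of the
#' MSD over the diffusive window. The fit is a straight line over lags
#' between `window[1]` and `window[2]` of the maximum lag. A ballistic
#' regime guard checks the log-log slope of the windowed MSD: if it is
#' closer to 2 than to 1 the input is not diffusive and an error is raised.
#' The standard error is propagated from the linear fit.
#'
#' @param curve an `msd_curve` from [msd_from_trajectory()].
#' @param window diffusive fit window as fractions of the maximum lag.
#' @return named numeric `c(D, se)` in cm^2/s. A negative fitted slope
#'   yields `D = NA` with a warning.
#' @export
diffusion_from_msd <- function(curve, window = c(0.2, 0.8)) {
  stopifnot(inherits(curve, "msd_curve"))
  lag <- curve$lag; msd <- curve$msd
  lmax <- max(lag)
  sel <- lag >= window[1] * lmax & lag <= window[2] * lmax & lag > 0
  if (sum(sel) < 2) stop("diffusive window contains fewer than 2 points")
  loglog <- stats::coef(stats::lm(log(msd[sel]) ~ log(lag[sel])))[[2]]
  if (abs(loglog - 2) < abs(loglog - 1))
    stop("diffusive-regime check failed: MSD grows ~t^", round(loglog, 2),
         " (ballistic), not ~t")
  fit <- stats::lm(msd[sel] ~ lag[sel])
  slope <- stats::coef(fit)[[2]]             # A^2/ps
  slope_se <- summary(fit)$coefficients[2, 2]
  if (slope <= 0) {
    warning("negative fitted MSD slope; returning NA")
    return(c(D = NA_real_, se = NA_real_))
  }
  conv <- physical_constants$A2_ps_to_cm2_s / 6
  c(D = slope * conv, se = slope_se * conv)
}

#' Off-diagonal stress time series
#'
#' Container for the Green-Kubo viscosity estimator: the three off-diagonal
#' pressure-tensor components with the box volume and temperature.
#'
#' @param time sample times (ps).
#' @param Pxy,Pxz,Pyz off-diagonal pressure components (bar).
#' @param volume box volume (nm^3).
#' @param temperature temperature (K).
#' @return An object of class `stress_series`.
#' @export
stress_series <- function(time, Pxy, Pxz, Pyz, volume, temperature) {
  n <- length(time)
  stopifnot(length(Pxy) == n, length(Pxz) == n, length(Pyz) == n,
            volume > 0, temperature > 0)
  structure(list(time = time, Pxy = Pxy, Pxz = Pxz, Pyz = Pyz,
                 volume = volume, temperature = temperature),
            class = "stress_series")
}

#' Green-Kubo shear viscosity
#'
#' \deqn{\eta = \frac{V}{k_B T} \int_0^{t_{max}}
#'   \langle P_{ab}(0) P_{ab}(t)\rangle \, dt}
#' averaged over the three off-diagonal components, with trapezoidal
#' integration of the empirical autocorrelation. By default the integral is
#' truncated at the first zero crossing of the averaged ACF (capped at
#' `max_lag`), where the signal is exhausted and further integration only
#' accumulates noise. The standard error is the spread of the three
#' per-component estimates.
#'
#' @param series a [stress_series()].
#' @param max_lag maximum lag (ps); default one tenth of the series.
#' @param truncate_at_zero stop integrating at the ACF's first zero
#'   crossing.
#' @return named numeric `c(eta, se)` in mPa s.
#' @export
viscosity_green_kubo <- function(series, max_lag = NULL,
                                 truncate_at_zero = TRUE) {
  stopifnot(inherits(series, "stress_series"))
  n <- length(series$time)
  dt <- series$time[2] - series$time[1]
  if (is.null(max_lag)) max_lag <- series$time[max(2L, n %/% 10L)]
  n_lag <- floor(max_lag / dt)
  if (n_lag >= n) stop("max lag must be shorter than the series")
  comp <- list(series$Pxy, series$Pxz, series$Pyz)
  acfs <- lapply(comp, function(x) {
    a <- stats::acf(x, lag.max = n_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)
    as.numeric(a$acf)
  })
  mean_acf <- Reduce(`+`, acfs) / 3
  cut <- length(mean_acf)
  if (truncate_at_zero) {
    zc <- which(mean_acf < 0)
    if (length(zc)) cut <- min(zc[1], cut)
  }
  integ <- function(a) {
    a <- a[seq_len(cut)]
    if (length(a) < 2) return(a[1] * dt / 2)
    sum((a[-1] + a[-length(a)]) / 2) * dt
  }
  etas <- vapply(acfs, function(a)
    gk_eta_from_acf0(integ(a), series$volume, series$temperature),
    numeric(1))
  c(eta = mean(etas), se = stats::sd(etas) / sqrt(length(etas)))
}
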