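#' Liquid-vapor coexistence curve
#'
#' Rows of (T, rho_l, rho_g) along the coexistence envelope, with
#' temperatures strictly increasing and `rho_l > rho_g > 0`.
#'
#' @param T temperatures (K), strictly increasing.
#' @param rho_l,rho_g liquid and vapor densities (g/L).
#' @return An object of class `coexistence_curve` (also a data.frame).
#' @export
coexistence_curve <- function(T, rho_l, rho_g) {
  stopifnot(length(T) == length(rho_l), length(T) == length(rho_g))
  if (any(diff(T) <= 0)) stop("temperatures must be strictly increasing")
  if (any(rho_g <= 0) || any(rho_l <= rho_g))
    stop("need rho_l > rho_g > 0 at every temperature")
  structure(data.frame(T = T, rho_l = rho_l, rho_g = rho_g),
            class = c("coexistence_curve", "data.frame"))
}

# Wegner sum: sum_k A_k |tau|^(beta + k Delta)
wegner_eval <- function(tau, amplitudes, beta_c = 0.325, Delta = 0.5) {
  tau <- abs(tau)
  out <- 0
  for (k in seq_along(amplitudes))
    out <- out + amplitudes[k] * tau^(beta_c + (k - 1) * Delta)
  out
}

#' Critical temperature by the Wegner expansion
#'
#' Fits \deqn{\rho_l - \rho_g = \sum_{k=0}^{3} A_k |\tau|^{\beta_c + k\Delta},
#'   \quad \tau = 1 - T/T_C}
#' with the 3D-Ising exponents fixed (\eqn{\beta_c = 0.325},
#' \eqn{\Delta = 0.5}). The amplitudes are linear given `T_C`, so the fit is
#' a bounded one-dimensional search over `T_C` wrapping an exact linear
#' least-squares solve.
#'
#' @param curve a [coexistence_curve()] with at least 5 rows.
#' @param beta_c,Delta fixed exponents.
#' @param n_amplitudes number of Wegner terms (default 4: A0..A3).
#' @param bracket search interval for `T_C` relative to the largest data
#'   temperature (K above it).
#' @return list of class `wegner_fit`: `T_C` (K), `amplitudes` (g/L),
#'   `beta_c`, `Delta`, `rss`, plus the data range.
#' @export
fit_wegner <- function(curve, beta_c = 0.325, Delta = 0.5,
                       n_amplitudes = 4, bracket = c(1, 300)) {
  stopifnot(inherits(curve, "coexistence_curve"))
  if (nrow(curve) < n_amplitudes + 1)
    stop("need at least ", n_amplitudes + 1, " rows (T_C plus ",
         n_amplitudes, " amplitudes)")
  y <- curve$rho_l - curve$rho_g
  Tmax <- max(curve$T)

  design <- function(T_C) {
    tau <- abs(1 - curve$T / T_C)
    vapply(seq_len(n_amplitudes),
           function(k) tau^(beta_c + (k - 1) * Delta),
           numeric(nrow(curve)))
  }
  rss_at <- function(T_C) {
    X <- design(T_C)
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  opt <- stats::optimize(rss_at, interval = Tmax + bracket, tol = 1e-7)
  T_C <- opt$minimum
  span <- diff(bracket)
  if (T_C - Tmax - bracket[1] < 1e-3 * span ||
      Tmax + bracket[2] - T_C < 1e-3 * span)
    stop("best T_C lies at the search bound (", round(T_C, 2),
         " K); widen the bracket or inspect the data")
  X <- design(T_C)
  fit <- stats::lm.fit(X, y)
  structure(list(T_C = T_C, amplitudes = unname(fit$coefficients),
                 beta_c = beta_c, Delta = Delta,
                 rss = sum(fit$residuals^2),
                 T_range = range(curve$T)),
            class = "wegner_fit")
}

#' @export
print.wegner_fit <- function(x, ...) {
  cat(sprintf("wegner_fit: T_C = %.2f K (beta = %.3f, Delta = %.2f)\n",
              x$T_C, x$beta_c, x$Delta))
  cat("  amplitudes (g/L):",
      paste(sprintf("%.1f", x$amplitudes), collapse = ", "), "\n")
  invisible(x)
}

#' Critical density by the rectilinear-diameter law
#'
#' With `T_C` fixed from the Wegner fit, fits
#' \deqn{\rho_l + \rho_g = 2\rho_C + D_{1-\alpha'} |\tau|^{1-\alpha'} +
#'   D_1 |\tau|}
#' by linear least squares (\eqn{\alpha' = 0.11}); the critical density is
#' half the intercept.
#'
#' @param curve a [coexistence_curve()] with at least 3 rows.
#' @param T_C critical temperature (K), from [fit_wegner()].
#' @param alpha_prime fixed exponent.
#' @return list of class `rectilinear_fit`: `rho_C` (g/L), `D_1ma`, `D_1`
#'   (g/L), `alpha_prime`, `T_C`, `rss`.
#' @export
fit_rectilinear <- function(curve, T_C, alpha_prime = 0.11) {
  stopifnot(inherits(curve, "coexistence_curve"))
  if (nrow(curve) < 3) stop("need at least 3 rows")
  if (T_C <= max(curve$T)) stop("T_C must exceed all data temperatures")
  tau <- abs(1 - curve$T / T_C)
  X <- cbind(1, tau^(1 - alpha_prime), tau)
  y <- curve$rho_l + curve$rho_g
  fit <- stats::lm.fit(X, y)
  if (any(is.na(fit$coefficients))) stop("degenerate design")
  co <- unname(fit$coefficients)
  structure(list(rho_C = co[1] / 2, D_1ma = co[2], D_1 = co[3],
                 alpha_prime = alpha_prime, T_C = T_C,
                 rss = sum(fit$residuals^2)),
            class = "rectilinear_fit")
}

#' @export
print.rectilinear_fit <- function(x, ...) {
  cat(sprintf(
    "rectilinear_fit: rho_C = %.1f g/L at T_C = %.2f K (alpha' = %.2f)\n",
    x$rho_C, x$T_C, x$alpha_prime))
  invisible(x)
}
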