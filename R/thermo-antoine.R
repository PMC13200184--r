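#' Vapor-pressure curve
#'
#' Rows of (T, P) along the saturation line.
#'
#' @param T temperatures (K), strictly increasing.
#' @param P vapor pressures (bar), positive.
#' @return An object of class `vapor_pressure_curve` (also a data.frame).
#' @export
vapor_pressure_curve <- function(T, P) {
  stopifnot(length(T) == length(P))
  if (any(diff(T) <= 0)) stop("temperatures must be strictly increasing")
  if (any(P <= 0)) stop("pressures must be positive")
  structure(data.frame(T = T, P = P),
            class = c("vapor_pressure_curve", "data.frame"))
}

#' Antoine vapor-pressure fit
#'
#' Fits \deqn{\ln P = A + \frac{B}{T + C}} by minimising the least-squares
#' error of \eqn{\ln P}. Given `C`, the problem is linear in `A` and `B`,
#' so the fit is a bounded one-dimensional search over `C` wrapping an exact
#' linear solve. The Antoine form drifts over wide temperature spans, so
#' fits are windowed: pass `T_range` to restrict the rows used (the
#' convention here is one low window for the boiling point and one high
#' window for the critical pressure).
#'
#' @param vp a [vapor_pressure_curve()] with pressures in `unit`.
#' @param T_range optional `c(lo, hi)` (K); rows outside are dropped.
#' @param unit pressure unit tag carried through eval/invert (default
#'   `"bar"`).
#' @param C_bracket search interval for `C` (K).
#' @return list of class `antoine_fit`: `A` (dimensionless for P in `unit`),
#'   `B` (K), `C` (K), `T_range`, `unit`, `rss` (on ln P).
#' @export
fit_antoine <- function(vp, T_range = NULL, unit = "bar",
                        C_bracket = NULL) {
  stopifnot(inherits(vp, "vapor_pressure_curve"))
  if (!is.null(T_range))
    vp <- vp[vp$T >= T_range[1] & vp$T <= T_range[2], ]
  if (nrow(vp) < 3) stop("need at least 3 in-range rows")
  if (is.null(C_bracket))
    C_bracket <- c(-min(vp$T) + 1, 500)   # keep T + C > 0 over the data
  lnP <- log(vp$P)
  rss_at <- function(C) {
    X <- cbind(1, 1 / (vp$T + C))
    sum(stats::lm.fit(X, lnP)$residuals^2)
  }
  opt <- stats::optimize(rss_at, interval = C_bracket, tol = 1e-9)
  C <- opt$minimum
  fit <- stats::lm.fit(cbind(1, 1 / (vp$T + C)), lnP)
  co <- unname(fit$coefficients)
  structure(list(A = co[1], B = co[2], C = C,
                 T_range = range(vp$T), unit = unit,
                 rss = sum(fit$residuals^2)),
            class = "antoine_fit")
}

#' @export
print.antoine_fit <- function(x, ...) {
  cat(sprintf(
    "antoine_fit (P in %s): ln P = %.4g + %.6g/(T + %.6g), T in %.0f-%.0f K\n",
    x$unit, x$A, x$B, x$C, x$T_range[1], x$T_range[2]))
  invisible(x)
}

#' Evaluate or invert an Antoine fit
#'
#' `antoine_eval` returns \eqn{P = \exp(A + B/(T + C))};
#' `antoine_invert` returns \eqn{T = B/(\ln P - A) - C}. The two compose to
#' the identity on the valid range.
#'
#' @param fit an `antoine_fit` (or list with `A`, `B`, `C`).
#' @param T temperature(s) (K).
#' @param P pressure(s), in the fit's unit.
#' @param warn_extrapolation warn when `T` falls outside the fitted window.
#' @return pressures (eval) or temperatures (invert).
#' @export
antoine_eval <- function(fit, T, warn_extrapolation = TRUE) {
  if (any(T + fit$C <= 0)) stop("T + C <= 0: outside the Antoine domain")
  if (warn_extrapolation && !is.null(fit$T_range) &&
      any(T < fit$T_range[1] | T > fit$T_range[2]))
    warning(sprintf(
      "evaluating Antoine fit outside its %.0f-%.0f K window",
      fit$T_range[1], fit$T_range[2]))
  exp(fit$A + fit$B / (T + fit$C))
}

#' @rdname antoine_eval
#' @export
antoine_invert <- function(fit, P) {
  lnP <- log(P)
  if (any(abs(lnP - fit$A) < .Machine$double.eps))
    stop("ln P equals A: inversion undefined")
  T <- fit$B / (lnP - fit$A) - fit$C
  if (any(T + fit$C <= 0)) stop("inverted T leaves the Antoine domain")
  T
}

#' Critical pressure from an Antoine fit
#'
#' Evaluates the (high-temperature-window) Antoine fit at the critical
#' temperature. Extrapolation beyond the fitted window is allowed but
#' warned about, since the saturation line is only known up to the last
#' coexistence point.
#'
#' @param fit an `antoine_fit`.
#' @param T_C critical temperature (K).
#' @return critical pressure in the fit's unit.
#' @export
critical_pressure <- function(fit, T_C) {
  antoine_eval(fit, T_C, warn_extrapolation = TRUE)
}
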