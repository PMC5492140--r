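#' Volatility calibrated from boundary conditions
#'
#' The log-scale of the process grows as sigmaL * sqrt(t - ts); requiring the
#' process standard deviation at `te` to equal `dNe` fixes
#' sigmaL = sqrt( ln(1 + (dNe/Ne)^2) / (te - ts) ), with units time^(-1/2).
#' It is zero exactly when `dNe` is zero (a deterministic process).
#'
#' @param bc a [boundary_conditions()] object.
#' @return The volatility sigmaL (non-negative scalar).
#' @examples
#' sigma_from_boundary(boundary_conditions(-530, 1, 0, 4000, 1000)) # ~0.0107
#' @export
sigma_from_boundary <- function(bc) {
  bc <- as_boundary_conditions(bc)
  sqrt(log(1 + (bc$dNe / bc$Ne)^2) / (bc$te - bc$ts))
}

#' Lognormal stochastic process of diversity through time
#'
#' Constructs the lognormal stochastic process L(t) of species (or genus)
#' counts: at every t > ts the marginal law of L(t) is lognormal with
#' log-location M(t) and log-scale sigmaL * sqrt(t - ts), where M(t) is
#' chosen so that the mean E[L(t)] follows the requested mean-value curve.
#' The five boundary parameters determine everything: the mean curve is
#' calibrated through (ts, Ns) and (te, Ne), and the volatility sigmaL
#' through the end-time standard deviation `dNe` (see
#' [sigma_from_boundary()]).  At t = ts the process is the point mass
#' L(ts) = Ns with probability one.
#'
#' `gbm_process()` builds the geometric-Brownian-motion special case in its
#' classical (A, B) parameterisation: mean A * exp(B t) from time origin 0,
#' with the GBM identification sigmaL = sqrt(2 B) tying the volatility to
#' the growth rate.  Under this tie the peak-locus log-scale sigma(p) is
#' constant in p and EvoEntropy is exactly linear in time (the
#' molecular-clock property).
#'
#' @param bc a [boundary_conditions()] object, or the five numbers via
#'   `ts, Ns, te, Ne, dNe`.
#' @param family mean-curve family; see [mean_curve()].
#' @param ts,Ns,te,Ne,dNe boundary parameters, used when `bc` is missing.
#' @param tMax,tmin cubic extrema times (family `"cubic"`).
#' @param coeffs polynomial coefficients (family `"polynomial"`).
#'
#' @return Object of class `"lognormal_process"`: list with components
#'   `bc`, `mean_curve`, `sigmaL`, and for `gbm_process()` also `A`, `B`.
#'
#' @examples
#' # Phanerozoic genus diversity, cubic trend with Cambrian/post-Permian shape
#' proc <- lognormal_process(ts = -530, Ns = 1, te = 0, Ne = 4000, dNe = 1000,
#'                           family = "cubic", tMax = -400, tmin = -220)
#' proc
#' predict(proc, t = c(-530, -265, 0))
#' @export
lognormal_process <- function(bc, family = c("gbm", "straight_line",
                                             "parabola", "cubic",
                                             "polynomial"),
                              ts, Ns, te, Ne, dNe,
                              tMax = NULL, tmin = NULL, coeffs = NULL) {
  if (missing(bc)) bc <- boundary_conditions(ts, Ns, te, Ne, dNe)
  bc <- as_boundary_conditions(bc)
  family <- match.arg(family)
  mc <- mean_curve(family, bc, tMax = tMax, tmin = tmin, coeffs = coeffs)
  structure(list(bc = bc, mean_curve = mc,
                 sigmaL = sigma_from_boundary(bc)),
            class = "lognormal_process")
}

#' @rdname lognormal_process
#' @param A initial mean count of the GBM at t = 0; positive.
#' @param B exponential growth rate per unit time; non-negative.
#' @param horizon end time `te` recorded for the process (defaults to 1 time
#'   unit past the origin; the GBM needs no end-time calibration).
#' @export
gbm_process <- function(A, B, horizon = 1) {
  if (A <= 0) stop("'A' must be positive", call. = FALSE)
  if (B < 0) stop("'B' must be non-negative", call. = FALSE)
  sigmaL <- sqrt(2 * B)
  Ne <- A * exp(B * horizon)
  dNe <- Ne * sqrt(exp(sigmaL^2 * horizon) - 1)
  bc <- boundary_conditions(ts = 0, Ns = A, te = horizon, Ne = Ne, dNe = dNe)
  mc <- mean_curve("gbm", bc)
  structure(list(bc = bc, mean_curve = mc, sigmaL = sigmaL, A = A, B = B),
            class = c("gbm_process", "lognormal_process"))
}

is_lognormal_process <- function(x) inherits(x, "lognormal_process")

#' @export
print.lognormal_process <- function(x, ...) {
  cat("Lognormal stochastic process of diversity\n")
  print(x$bc)
  cat(sprintf("  mean-curve family: %s\n", x$mean_curve$family))
  cat(sprintf("  volatility sigmaL = %g per sqrt(time unit)\n", x$sigmaL))
  invisible(x)
}

#' @export
summary.lognormal_process <- function(object, ...) {
  bc <- object$bc
  band <- stddev_band(object, bc$te)
  out <- list(bc = bc, family = object$mean_curve$family,
              sigmaL = object$sigmaL,
              gbm_rate_boundary = gbm_rate(bc),
              end_band = band,
              end_cv = variation_coefficient(object, bc$te))
  class(out) <- "summary.lognormal_process"
  out
}

#' @export
print.summary.lognormal_process <- function(x, ...) {
  cat("Lognormal diversity process --- summary\n")
  print(x$bc)
  cat(sprintf("  mean-curve family:      %s\n", x$family))
  cat(sprintf("  volatility sigmaL:      %g time^(-1/2)\n", x$sigmaL))
  cat(sprintf("  boundary growth rate:   %g per unit time\n",
              x$gbm_rate_boundary))
  cat(sprintf("  band at te:             mean %g, +/- %g\n",
              x$end_band$mean, x$end_band$delta))
  cat(sprintf("  variation coeff at te:  %g\n", x$end_cv))
  invisible(x)
}

#' @export
coef.lognormal_process <- function(object, ...) {
  bc <- object$bc
  c(ts = bc$ts, Ns = bc$Ns, te = bc$te, Ne = bc$Ne, dNe = bc$dNe,
    sigmaL = object$sigmaL)
}

#' Evaluate process curves at given times
#'
#' @param object a [lognormal_process()].
#' @param t times (vectorised); must satisfy t >= ts.
#' @param type which curve: the mean, the lower/upper one-standard-deviation
#'   curves, the standard deviation itself, or the log-location M(t).
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.lognormal_process <- function(object, t,
                                      type = c("mean", "lower", "upper",
                                               "delta", "loglocation"),
                                      ...) {
  type <- match.arg(type)
  if (any(t < object$bc$ts))
    stop("process curves are defined for t >= ts", call. = FALSE)
  m <- predict(object$mean_curve, t)
  if (type == "mean") return(m)
  if (type == "loglocation") return(m_to_M(object, t))
  delta <- m * sqrt(exp(object$sigmaL^2 * (t - object$bc$ts)) - 1)
  switch(type, delta = delta, lower = m - delta, upper = m + delta)
}

#' Log-location M(t) from the mean curve
#'
#' The lognormal mean identity m(t) = exp(M(t)) * exp(sigmaL^2 (t - ts) / 2)
#' inverts to M(t) = ln m(t) - sigmaL^2 (t - ts) / 2.  At t = ts this is
#' ln(Ns).
#'
#' @param process a [lognormal_process()].
#' @param t times, t >= ts; the mean must be positive there.
#' @return Numeric vector of log-locations.
#' @export
m_to_M <- function(process, t) {
  stopifnot(is_lognormal_process(process))
  if (any(t < process$bc$ts))
    stop("M(t) is defined for t >= ts", call. = FALSE)
  m <- predict(process$mean_curve, t)
  if (any(m <= 0))
    stop("mean curve must be positive to take its logarithm", call. = FALSE)
  log(m) - process$sigmaL^2 * (t - process$bc$ts) / 2
}

#' Marginal density of the process at one time
#'
#' For t > ts the marginal law of L(t) is lognormal with log-location M(t)
#' and log-scale sigmaL * sqrt(t - ts); `marginal_pdf()` evaluates its
#' density at counts `n`.  At t = ts the law degenerates to the point mass
#' at Ns; `marginal_density()` returns an explicit point-mass marker there
#' (class `"point_mass"`) rather than a density, and `marginal_pdf()`
#' refuses t = ts so the degenerate case cannot be mistaken for a density
#' value.
#'
#' @param process a [lognormal_process()].
#' @param t a single time, t > ts for `marginal_pdf()`.
#' @param n counts at which to evaluate the density (vectorised, n > 0).
#' @return `marginal_pdf()`: densities per unit count.
#'   `marginal_density()`: either a `"point_mass"` object (at t = ts) or a
#'   `"lognormal_marginal"` object with fields `meanlog`, `sdlog` and a
#'   `pdf` function.
#' @examples
#' proc <- lognormal_process(ts = 0, Ns = 1, te = 10, Ne = 100, dNe = 20,
#'                           family = "gbm")
#' marginal_pdf(proc, t = 5, n = c(5, 10, 20))
#' marginal_density(proc, t = 0)   # point mass at Ns
#' @export
marginal_pdf <- function(process, t, n) {
  stopifnot(is_lognormal_process(process), length(t) == 1L)
  if (t <= process$bc$ts)
    stop("marginal_pdf() requires t > ts; at t = ts the law is the point ",
         "mass at Ns (see marginal_density())", call. = FALSE)
  if (any(n <= 0)) stop("'n' must be positive", call. = FALSE)
  if (process$sigmaL == 0) {
    # zero-volatility limit: deterministic at the mean; no proper density
    stop("sigmaL = 0: the marginal at t > ts is the point mass at m(t)",
         call. = FALSE)
  }
  stats::dlnorm(n, meanlog = m_to_M(process, t),
                sdlog = process$sigmaL * sqrt(t - process$bc$ts))
}

#' @rdname marginal_pdf
#' @export
marginal_density <- function(process, t) {
  stopifnot(is_lognormal_process(process), length(t) == 1L)
  if (t < process$bc$ts)
    stop("the process is defined for t >= ts", call. = FALSE)
  if (t == process$bc$ts || process$sigmaL == 0) {
    at <- if (t == process$bc$ts) process$bc$Ns
          else predict(process$mean_curve, t)
    return(structure(list(at = at, t = t), class = "point_mass"))
  }
  meanlog <- m_to_M(process, t)
  sdlog <- process$sigmaL * sqrt(t - process$bc$ts)
  structure(list(t = t, meanlog = meanlog, sdlog = sdlog,
                 pdf = function(n) stats::dlnorm(n, meanlog, sdlog)),
            class = "lognormal_marginal")
}

#' @export
print.point_mass <- function(x, ...) {
  cat(sprintf("Point mass: Pr{ L(%g) = %g } = 1\n", x$t, x$at))
  invisible(x)
}

#' @export
print.lognormal_marginal <- function(x, ...) {
  cat(sprintf("Lognormal marginal at t = %g: meanlog %g, sdlog %g\n",
              x$t, x$meanlog, x$sdlog))
  invisible(x)
}

#' Standard-deviation band of the process
#'
#' The process standard deviation is Delta(t) = m(t) * sqrt(exp(sigmaL^2
#' (t - ts)) - 1); the band is the pair of curves m(t) +/- Delta(t).  Both
#' equal Ns at t = ts, and the band half-width at te equals `dNe` by
#' calibration.  The lower curve may go negative for large sigmaL; it is
#' reported unclipped (a plotting layer may clip visually, the data never
#' are).
#'
#' @param process a [lognormal_process()].
#' @param t times, t >= ts (vectorised).
#' @return A data frame with columns `t`, `mean`, `lower`, `upper`, `delta`.
#' @export
stddev_band <- function(process, t) {
  stopifnot(is_lognormal_process(process))
  m <- predict(process, t, type = "mean")
  delta <- predict(process, t, type = "delta")
  data.frame(t = t, mean = m, lower = m - delta, upper = m + delta,
             delta = delta)
}

#' Variation coefficient of the process
#'
#' The ratio of the process standard deviation to its mean,
#' sqrt(exp(sigmaL^2 (t - ts)) - 1): zero at ts, equal to dNe/Ne at te, and
#' non-decreasing in between.
#'
#' @inheritParams stddev_band
#' @return Numeric vector of ratios.
#' @export
variation_coefficient <- function(process, t) {
  stopifnot(is_lognormal_process(process))
  if (any(t < process$bc$ts))
    stop("variation coefficient is defined for t >= ts", call. = FALSE)
  sqrt(exp(process$sigmaL^2 * (t - process$bc$ts)) - 1)
}

#' Plot the mean and standard-deviation band
#'
#' @param x a [lognormal_process()].
#' @param from,to time range (defaults to `[ts, te]`).
#' @param n number of grid points.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lognormal_process <- function(x, from = x$bc$ts, to = x$bc$te,
                                   n = 201, ...) {
  t <- seq(from, to, length.out = n)
  band <- stddev_band(x, t)
  ylim <- range(band$lower, band$upper)
  graphics::plot(t, band$mean, type = "l", col = "red", lwd = 2,
                 xlab = "time", ylab = "number of species/genera",
                 ylim = ylim, ...)
  graphics::lines(t, band$upper, lty = 2, col = "blue")
  graphics::lines(t, band$lower, lty = 2, col = "blue")
  graphics::legend("topleft", legend = c("mean", "mean +/- sd"),
                   col = c("red", "blue"), lty = c(1, 2), bty = "n")
  invisible(band)
}
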