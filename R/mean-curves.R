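#' Mean-value curve families
#'
#' Closed-form families for the mean value m(t) of the diversity process,
#' each calibrated so that m(ts) = Ns and m(te) = Ne:
#'
#' * `gbm_mean()` — exponential growth, Ns * exp(B (t - ts)), with the rate
#'   B = ln(Ne/Ns) / (te - ts) fixed by the endpoint condition.  This is the
#'   mean of a geometric Brownian motion.
#' * `straight_line_mean()` — the affine interpolant through (ts, Ns) and
#'   (te, Ne).
#' * `parabola_mean()` — the quadratic in (t - ts) through both endpoints
#'   whose vertex sits at t = te (zero slope there).
#' * `cubic_mean()` — the cubic in (t - ts) through both endpoints whose
#'   derivative vanishes exactly at the two prescribed interior instants
#'   `tMax` (local maximum) and `tmin` (local minimum); the shape used to
#'   represent the non-monotonic Phanerozoic genus-diversity trend.
#' * `polynomial_mean()` — a generic polynomial in (t - ts) with user
#'   coefficients, Horner-evaluated.
#'
#' Curves may be evaluated at any t (including t < ts, convenient for
#' plotting); process-level consumers restrict to t >= ts where the
#' stochastic process is defined.
#'
#' @param t time (vectorised).
#' @param bc a [boundary_conditions()] object.
#' @param tMax,tmin times of the cubic's local maximum and minimum; must
#'   satisfy ts < tMax < tmin < te.
#' @param coeffs numeric vector of polynomial coefficients, `coeffs[k+1]`
#'   multiplying (t - ts)^k.
#' @param ts start time for `polynomial_mean()`.
#'
#' @return Numeric vector of mean counts, same length as `t`.
#' @name mean_curves
NULL

#' @rdname mean_curves
#' @export
gbm_mean <- function(t, bc) {
  bc <- as_boundary_conditions(bc)
  if (any(t < bc$ts)) stop("gbm_mean() requires t >= ts", call. = FALSE)
  B <- gbm_rate(bc)
  bc$Ns * exp(B * (t - bc$ts))
}

#' @rdname mean_curves
#' @export
gbm_rate <- function(bc) {
  bc <- as_boundary_conditions(bc)
  log(bc$Ne / bc$Ns) / (bc$te - bc$ts)
}

#' @rdname mean_curves
#' @export
straight_line_mean <- function(t, bc) {
  bc <- as_boundary_conditions(bc)
  (bc$Ne - bc$Ns) * (t - bc$ts) / (bc$te - bc$ts) + bc$Ns
}

#' @rdname mean_curves
#' @export
parabola_mean <- function(t, bc) {
  bc <- as_boundary_conditions(bc)
  x <- (t - bc$ts) / (bc$te - bc$ts)
  (bc$Ne - bc$Ns) * x * (2 - x) + bc$Ns
}

#' @rdname mean_curves
#' @export
cubic_mean <- function(t, bc, tMax, tmin) {
  bc <- as_boundary_conditions(bc)
  if (!(bc$ts < tMax && tMax < tmin && tmin < bc$te))
    stop("cubic extrema must satisfy ts < tMax < tmin < te", call. = FALSE)
  tau  <- t - bc$ts
  tauM <- tMax - bc$ts
  taum <- tmin - bc$ts
  taue <- bc$te - bc$ts
  # bracket(x) = 2 x^2 - 3 (tauM + taum) x + 6 tauM taum, so that
  # d/dtau [x * bracket(x)] = 6 (x - tauM)(x - taum)
  bracket <- function(x) 2 * x^2 - 3 * (tauM + taum) * x + 6 * tauM * taum
  den <- taue * bracket(taue)
  if (den == 0) stop("degenerate cubic configuration: zero denominator",
                     call. = FALSE)
  (bc$Ne - bc$Ns) * tau * bracket(tau) / den + bc$Ns
}

#' @rdname mean_curves
#' @export
polynomial_mean <- function(t, coeffs, ts) {
  if (length(coeffs) == 0L) stop("'coeffs' must be non-empty", call. = FALSE)
  tau <- t - ts
  acc <- rep(coeffs[length(coeffs)], length(tau))
  for (k in rev(seq_len(length(coeffs) - 1L))) acc <- acc * tau + coeffs[k]
  acc
}

#' Construct a mean-value curve object
#'
#' Bundles a family name, boundary conditions and shape parameters into a
#' `"mean_curve"` object evaluable via [predict()] at arbitrary times.
#'
#' @param family one of `"gbm"`, `"straight_line"`, `"parabola"`, `"cubic"`,
#'   `"polynomial"`.
#' @param bc a [boundary_conditions()] object (not used by `"polynomial"`
#'   beyond its `ts`).
#' @param tMax,tmin cubic extrema times (family `"cubic"` only).
#' @param coeffs polynomial coefficients (family `"polynomial"` only).
#'
#' @return Object of class `"mean_curve"`.
#' @examples
#' bc <- boundary_conditions(-530, 1, 0, 4000, 1000)
#' mc <- mean_curve("cubic", bc, tMax = -400, tmin = -220)
#' predict(mc, t = c(-530, -400, -220, 0))
#' @export
mean_curve <- function(family = c("gbm", "straight_line", "parabola",
                                  "cubic", "polynomial"),
                       bc, tMax = NULL, tmin = NULL, coeffs = NULL) {
  family <- match.arg(family)
  bc <- as_boundary_conditions(bc)
  if (family == "cubic") {
    if (is.null(tMax) || is.null(tmin))
      stop("family 'cubic' requires 'tMax' and 'tmin'", call. = FALSE)
    if (!(bc$ts < tMax && tMax < tmin && tmin < bc$te))
      stop("cubic extrema must satisfy ts < tMax < tmin < te", call. = FALSE)
  }
  if (family == "polynomial" && is.null(coeffs))
    stop("family 'polynomial' requires 'coeffs'", call. = FALSE)
  structure(list(family = family, bc = bc, tMax = tMax, tmin = tmin,
                 coeffs = coeffs),
            class = "mean_curve")
}

#' @rdname mean_curve
#' @param object a `"mean_curve"` object.
#' @param t times at which to evaluate the curve.
#' @param ... unused.
#' @export
predict.mean_curve <- function(object, t, ...) {
  switch(object$family,
    gbm           = gbm_mean(t, object$bc),
    straight_line = straight_line_mean(t, object$bc),
    parabola      = parabola_mean(t, object$bc),
    cubic         = cubic_mean(t, object$bc, object$tMax, object$tmin),
    polynomial    = polynomial_mean(t, object$coeffs, object$bc$ts))
}

#' @export
print.mean_curve <- function(x, ...) {
  cat(sprintf("Mean-value curve, family '%s'\n", x$family))
  print(x$bc)
  if (x$family == "cubic")
    cat(sprintf("  extrema: maximum at t = %g, minimum at t = %g\n",
                x$tMax, x$tmin))
  if (x$family == "polynomial")
    cat("  coefficients:", paste(signif(x$coeffs, 6), collapse = ", "), "\n")
  if (x$family == "gbm")
    cat(sprintf("  growth rate B = %g per unit time\n", gbm_rate(x$bc)))
  invisible(x)
}
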