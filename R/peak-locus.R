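#' Peak-locus family of b-lognormals
#'
#' For every peak abscissa p there is exactly one b-lognormal whose peak
#' sits on the mean curve at (p, m(p)).  Its parameters are, in closed form,
#'
#'   sigma(p) = exp(sigmaL^2 p / 2) / (sqrt(2 pi) m(p))
#'   mu(p)    = exp(sigmaL^2 p) / (4 pi m(p)^2) - p sigmaL^2 / 2
#'   b(p)     = p - exp(mu(p) - sigma(p)^2)
#'
#' Note the exponents use the *absolute* abscissa p, not p - ts, so for
#' ts != 0 the family depends on the chosen time origin; this convention is
#' what reproduces the published Phanerozoic entropy values.  The
#' alternative origin-anchored convention (p - ts in the exponents) is
#' available via `convention = "shifted"` for sensitivity analysis.
#'
#' `peak_locus_boundary()` is the algebraically identical form written in
#' the boundary parameters alone, with exp(sigmaL^2) replaced by
#' (1 + (dNe/Ne)^2)^(1/(te-ts)).
#'
#' `gbm_peak_locus()` is the classical special case for a GBM mean
#' A exp(B t) from origin 0 with the volatility tie sigmaL^2 = 2B:
#' mu(p) = 1/(4 pi A^2) - B p and sigma = 1/(sqrt(2 pi) A), constant in p.
#'
#' @param process a [lognormal_process()].
#' @param p peak abscissae (vectorised); the mean must be positive there.
#' @param convention `"absolute"` (as published; default) or `"shifted"`.
#' @return A data frame with columns `p`, `mu`, `sigma`, `b` --- one
#'   b-lognormal per row.
#' @examples
#' proc <- lognormal_process(ts = -530, Ns = 1, te = 0, Ne = 4000,
#'                           dNe = 1000, family = "cubic",
#'                           tMax = -400, tmin = -220)
#' pl <- peak_locus(proc, p = c(-400, -100, 0))
#' # the peak of each member rides the mean curve:
#' blognormal_mode(pl$mu[3], pl$sigma[3], pl$b[3])
#' @export
peak_locus <- function(process, p, convention = c("absolute", "shifted")) {
  stopifnot(is_lognormal_process(process))
  convention <- match.arg(convention)
  m <- predict(process$mean_curve, p)
  if (any(m <= 0))
    stop("mean curve must be positive at every peak abscissa", call. = FALSE)
  x <- if (convention == "absolute") p else p - process$bc$ts
  s2 <- process$sigmaL^2
  sigma <- exp(s2 * x / 2) / (sqrt(2 * pi) * m)
  mu <- exp(s2 * x) / (4 * pi * m^2) - x * s2 / 2
  b <- p - exp(mu - sigma^2)
  data.frame(p = p, mu = mu, sigma = sigma, b = b)
}

#' @rdname peak_locus
#' @export
peak_locus_boundary <- function(process, p,
                                convention = c("absolute", "shifted")) {
  stopifnot(is_lognormal_process(process))
  convention <- match.arg(convention)
  bc <- process$bc
  m <- predict(process$mean_curve, p)
  if (any(m <= 0))
    stop("mean curve must be positive at every peak abscissa", call. = FALSE)
  x <- if (convention == "absolute") p else p - bc$ts
  C <- 1 + (bc$dNe / bc$Ne)^2          # = exp(sigmaL^2 (te - ts))
  span <- bc$te - bc$ts
  sigma <- C^(x / (2 * span)) / (sqrt(2 * pi) * m)
  mu <- C^(x / span) / (4 * pi * m^2) - log(C^(x / (2 * span)))
  b <- p - exp(mu - sigma^2)
  data.frame(p = p, mu = mu, sigma = sigma, b = b)
}

#' @rdname peak_locus
#' @param A initial mean count of the GBM (at t = 0); positive.
#' @param B exponential growth rate per unit time.
#' @export
gbm_peak_locus <- function(A, B, p) {
  if (A <= 0) stop("'A' must be positive", call. = FALSE)
  mu <- 1 / (4 * pi * A^2) - B * p
  sigma <- rep(1 / (sqrt(2 * pi) * A), length(p))
  b <- p - exp(mu - sigma^2)
  data.frame(p = p, mu = mu, sigma = sigma, b = b)
}
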