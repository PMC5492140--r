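#' Entropy along the peak locus and EvoEntropy
#'
#' The Shannon differential entropy (in bits) of the peak-locus b-lognormal
#' at abscissa p reduces, after substituting the peak-locus parameters, to
#'
#'   H(p) = (1/ln 2) { exp(sigmaL^2 p) / (4 pi m(p)^2) - ln m(p) + 1/2 }.
#'
#' H decreases as life gets more organized; EvoEntropy is its sign-reversed,
#' origin-anchored version,
#'
#'   EvoEntropy(p) = -( H(p) - H(ts) ),
#'
#' which starts at zero at ts and grows as the mean count grows.  It is
#' measured in bits per individual and is the model's evolution scale.
#'
#' Two modes are exposed.  `"with_end_stddev"` keeps the process volatility
#' in the two power terms (equivalently, the boundary form with the factor
#' (1 + (dNe/Ne)^2)^(p/(te-ts))); this is the form whose value at p = 0
#' reproduces the published Phanerozoic figure of about 12.074 bits per
#' individual.  `"squashed"` sets the power terms to one (the dNe = 0
#' limit, the curve "squashed" onto the mean curve),
#'
#'   EvoEntropy(p) = (1/ln 2) { 1/(4 pi Ns^2) - 1/(4 pi m(p)^2)
#'                              + ln(m(p)/Ns) },
#'
#' the deterministic-trend form used for family comparisons.  Both vanish
#' at p = ts.
#'
#' @param process a [lognormal_process()].
#' @param p peak abscissae (vectorised); the mean must be positive there.
#' @param mode `"with_end_stddev"` (default) or `"squashed"`; see Details.
#' @param convention passed to the peak-locus exponent: `"absolute"`
#'   (default, as published) or `"shifted"`.
#' @return Numeric vector, in bits (per individual for EvoEntropy).
#' @examples
#' proc <- lognormal_process(ts = -530, Ns = 1, te = 0, Ne = 4000,
#'                           dNe = 1000, family = "cubic",
#'                           tMax = -400, tmin = -220)
#' evo_entropy(proc, p = 0)                      # ~12.074 bits/individual
#' evo_entropy(proc, p = 0, mode = "squashed")   # ~12.081 bits/individual
#' @export
entropy_of_locus <- function(process, p,
                             convention = c("absolute", "shifted")) {
  stopifnot(is_lognormal_process(process))
  convention <- match.arg(convention)
  m <- predict(process$mean_curve, p)
  if (any(m <= 0))
    stop("mean curve must be positive at every abscissa", call. = FALSE)
  x <- if (convention == "absolute") p else p - process$bc$ts
  (exp(process$sigmaL^2 * x) / (4 * pi * m^2) - log(m) + 0.5) / log(2)
}

#' @rdname entropy_of_locus
#' @export
entropy_of_locus_boundary <- function(process, p,
                                      convention = c("absolute",
                                                     "shifted")) {
  stopifnot(is_lognormal_process(process))
  convention <- match.arg(convention)
  bc <- process$bc
  m <- predict(process$mean_curve, p)
  if (any(m <= 0))
    stop("mean curve must be positive at every abscissa", call. = FALSE)
  x <- if (convention == "absolute") p else p - bc$ts
  C <- 1 + (bc$dNe / bc$Ne)^2
  (C^(x / (bc$te - bc$ts)) / (4 * pi * m^2) - log(m) + 0.5) / log(2)
}

#' @rdname entropy_of_locus
#' @export
evo_entropy <- function(process, p,
                        mode = c("with_end_stddev", "squashed"),
                        convention = c("absolute", "shifted")) {
  stopifnot(is_lognormal_process(process))
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  bc <- process$bc
  m <- predict(process$mean_curve, p)
  if (any(m <= 0))
    stop("mean curve must be positive at every abscissa", call. = FALSE)
  if (mode == "with_end_stddev") {
    s2 <- process$sigmaL^2
    xs <- if (convention == "absolute") bc$ts else 0
    xp <- if (convention == "absolute") p else p - bc$ts
    (exp(s2 * xs) / (4 * pi * bc$Ns^2) -
       exp(s2 * xp) / (4 * pi * m^2) + log(m / bc$Ns)) / log(2)
  } else {
    squashed_evo(m, bc$Ns)
  }
}

# Eq-44-style deterministic-trend EvoEntropy, in bits
squashed_evo <- function(m, Ns) {
  (1 / (4 * pi * Ns^2) - 1 / (4 * pi * m^2) + log(m / Ns)) / log(2)
}

#' Closed-form GBM EvoEntropy (the molecular clock)
#'
#' When the mean is the boundary-calibrated exponential, EvoEntropy is
#' exactly linear in time: (B / ln 2) (p - ts) bits per individual with
#' B = ln(Ne/Ns)/(te - ts).  The slope B/ln 2 plays the role of the
#' molecular clock's constant divergence rate.  At p = te the value is
#' log2(Ne/Ns) bits.
#'
#' @param bc a [boundary_conditions()] object.
#' @param p times (vectorised), p >= ts.
#' @return EvoEntropy in bits per individual, exactly linear in `p`.
#' @examples
#' earth <- boundary_conditions(ts = -3.5e9, Ns = 1, te = 0, Ne = 5e7,
#'                              dNe = 3e7)
#' gbm_evo_entropy(earth, p = 0)   # log2(5e7) = 25.575 bits
#' @export
gbm_evo_entropy <- function(bc, p) {
  bc <- as_boundary_conditions(bc)
  if (any(p < bc$ts)) stop("'p' must be >= ts", call. = FALSE)
  gbm_rate(bc) * (p - bc$ts) / log(2)
}

#' EvoEntropy of a named mean-curve family
#'
#' Convenience dispatcher for the deterministic-trend ("squashed")
#' EvoEntropy of the straight-line, parabolic, cubic or GBM mean through the
#' same boundary points: all families start at 0 bits at ts and coincide
#' again at te (where every mean equals Ne), diverging in between according
#' to the shape of the growth.
#'
#' @param family one of `"gbm"`, `"straight_line"`, `"parabola"`, `"cubic"`,
#'   `"polynomial"`.
#' @param bc a [boundary_conditions()] object.
#' @param p times (vectorised).
#' @param tMax,tmin cubic extrema (family `"cubic"`).
#' @param coeffs polynomial coefficients (family `"polynomial"`).
#' @return EvoEntropy in bits per individual.
#' @export
family_evo_entropy <- function(family, bc, p, tMax = NULL, tmin = NULL,
                               coeffs = NULL) {
  bc <- as_boundary_conditions(bc)
  mc <- mean_curve(family, bc, tMax = tMax, tmin = tmin, coeffs = coeffs)
  m <- predict(mc, p)
  if (any(m <= 0))
    stop("mean curve must be positive at every abscissa", call. = FALSE)
  squashed_evo(m, bc$Ns)
}

#' Sample entropy and EvoEntropy over a grid
#'
#' @param process a [lognormal_process()].
#' @param p_grid peak abscissae; defaults to 201 points spanning `[ts, te]`.
#' @param mode EvoEntropy mode, see [evo_entropy()].
#' @return A data frame of class `"entropy_curve"` with columns `p`,
#'   `H_bits`, `evo_bits` and attributes `mode`.
#' @export
entropy_curve <- function(process,
                          p_grid = seq(process$bc$ts, process$bc$te,
                                       length.out = 201),
                          mode = c("with_end_stddev", "squashed")) {
  mode <- match.arg(mode)
  out <- data.frame(p = p_grid,
                    H_bits = entropy_of_locus(process, p_grid),
                    evo_bits = evo_entropy(process, p_grid, mode = mode))
  attr(out, "mode") <- mode
  class(out) <- c("entropy_curve", "data.frame")
  out
}

#' @export
plot.entropy_curve <- function(x, ...) {
  graphics::plot(x$p, x$evo_bits, type = "l", lwd = 2, col = "blue",
                 xlab = "time", ylab = "EvoEntropy (bits / individual)",
                 ...)
  invisible(x)
}
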