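#' Boundary conditions of a lognormal diversity process
#'
#' The five calibration numbers that completely determine a lognormal
#' stochastic process of species (or genus) counts: the start time `ts` with
#' its known count `Ns`, the end time `te`, and the mean count `Ne` and
#' standard deviation `dNe` of the process at `te`.  Time units are abstract
#' (years, millions of years, ...); every derived quantity carries the unit
#' implied by the boundary values, e.g. the volatility has units
#' time^(-1/2).
#'
#' @param ts start time (the origin of life in planetary scenarios).
#' @param Ns count at `ts`, known with probability one; must be positive.
#' @param te end time; must satisfy `te > ts`.
#' @param Ne mean count at `te`; must be positive.
#' @param dNe standard deviation of the count at `te`; must be non-negative.
#'
#' @return An object of class `"boundary_conditions"`: a named list with
#'   components `ts`, `Ns`, `te`, `Ne`, `dNe`.
#'
#' @examples
#' # Phanerozoic genus counts: 1 genus 530 Myr ago, 4000 +/- 1000 today
#' bc <- boundary_conditions(ts = -530, Ns = 1, te = 0, Ne = 4000, dNe = 1000)
#' bc
#' @export
boundary_conditions <- function(ts, Ns, te, Ne, dNe) {
  for (nm in c("ts", "Ns", "te", "Ne", "dNe")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (te <= ts) stop("'te' must be strictly greater than 'ts'", call. = FALSE)
  if (Ns <= 0) stop("'Ns' must be positive", call. = FALSE)
  if (Ne <= 0) stop("'Ne' must be positive", call. = FALSE)
  if (dNe < 0) stop("'dNe' must be non-negative", call. = FALSE)
  structure(list(ts = as.numeric(ts), Ns = as.numeric(Ns),
                 te = as.numeric(te), Ne = as.numeric(Ne),
                 dNe = as.numeric(dNe)),
            class = "boundary_conditions")
}

#' @export
print.boundary_conditions <- function(x, ...) {
  cat("Boundary conditions of a lognormal diversity process\n")
  cat(sprintf("  start: t = %g, count = %g (known exactly)\n", x$ts, x$Ns))
  cat(sprintf("  end:   t = %g, mean count = %g, sd = %g\n",
              x$te, x$Ne, x$dNe))
  invisible(x)
}

is_boundary_conditions <- function(x) inherits(x, "boundary_conditions")

as_boundary_conditions <- function(x) {
  if (is_boundary_conditions(x)) return(x)
  if (is.list(x) && all(c("ts", "Ns", "te", "Ne", "dNe") %in% names(x)))
    return(boundary_conditions(x$ts, x$Ns, x$te, x$Ne, x$dNe))
  stop("cannot interpret 'x' as boundary conditions", call. = FALSE)
}
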