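#' Monte-Carlo trajectories of the diversity process
#'
#' Draws sample paths whose marginal at every grid time t is lognormal with
#' log-location M(t) and log-scale sigmaL * sqrt(t - ts), matching the
#' analytic mean and standard-deviation band.  The construction is
#' L(t) = exp( M(t) + sigmaL * W(t - ts) ) with W a standard Brownian
#' motion shared along each path: the minimal Markovian choice consistent
#' with the marginals, reducing to classical geometric Brownian motion for
#' the exponential mean.  Every path starts at exactly Ns.
#'
#' Reproducibility: one root seed; per-path seeds are drawn sequentially
#' from the root-seeded stream, so enlarging `n_paths` extends the ensemble
#' without altering earlier paths.
#'
#' @param process a [lognormal_process()].
#' @param t_grid strictly increasing times starting at `ts`.
#' @param n_paths number of trajectories (>= 1).
#' @param seed integer root seed.
#' @return Object of class `"trajectory_ensemble"`: list with `t_grid`,
#'   `paths` (matrix, `n_paths` rows by `length(t_grid)` columns), `seed`
#'   and the generating `process`.
#' @examples
#' proc <- lognormal_process(ts = 0, Ns = 1, te = 10, Ne = 100, dNe = 20,
#'                           family = "gbm")
#' ens <- simulate_paths(proc, t_grid = seq(0, 10, 0.5), n_paths = 200,
#'                       seed = 42)
#' st <- ensemble_stats(ens)
#' st$mean[length(st$mean)]    # close to Ne = 100
#' @export
simulate_paths <- function(process, t_grid, n_paths, seed) {
  stopifnot(is_lognormal_process(process))
  if (length(t_grid) < 1L || t_grid[1] != process$bc$ts)
    stop("'t_grid' must start at ts", call. = FALSE)
  if (any(diff(t_grid) <= 0))
    stop("'t_grid' must be strictly increasing", call. = FALSE)
  if (n_paths < 1L) stop("'n_paths' must be >= 1", call. = FALSE)

  nt <- length(t_grid)
  M <- m_to_M(process, t_grid)            # log-location along the grid
  sd_inc <- sqrt(diff(t_grid))            # Brownian increment scales

  set.seed(as.integer(seed))
  path_seeds <- sample.int(.Machine$integer.max, n_paths, replace = TRUE)

  paths <- matrix(NA_real_, nrow = n_paths, ncol = nt)
  for (i in seq_len(n_paths)) {
    set.seed(path_seeds[i])
    W <- c(0, cumsum(stats::rnorm(nt - 1L, sd = sd_inc)))
    paths[i, ] <- exp(M + process$sigmaL * W)
  }
  paths[, 1L] <- process$bc$Ns            # exact start, no rounding drift
  structure(list(t_grid = t_grid, paths = paths, seed = as.integer(seed),
                 process = process),
            class = "trajectory_ensemble")
}

#' @rdname simulate_paths
#' @param object a [lognormal_process()] (S3 method for [stats::simulate()]).
#' @param nsim number of trajectories.
#' @param t_grid as above; defaults to 101 points spanning `[ts, te]`.
#' @param ... unused.
#' @export
simulate.lognormal_process <- function(object, nsim = 1, seed = NULL,
                                       t_grid = seq(object$bc$ts,
                                                    object$bc$te,
                                                    length.out = 101),
                                       ...) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  simulate_paths(object, t_grid = t_grid, n_paths = nsim, seed = seed)
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: %d paths on %d grid points (t in [%g, %g]), seed %d\n",
              nrow(x$paths), ncol(x$paths), x$t_grid[1],
              x$t_grid[length(x$t_grid)], x$seed))
  invisible(x)
}

#' Per-time sample mean and standard deviation of an ensemble
#'
#' @param ens a `"trajectory_ensemble"`.
#' @return List with numeric vectors `mean` and `stddev` (sample sd,
#'   n - 1 denominator), one entry per grid time.
#' @export
ensemble_stats <- function(ens) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  list(mean = colMeans(ens$paths),
       stddev = apply(ens$paths, 2L, stats::sd))
}

#' Recover the volatility from an ensemble
#'
#' Inverts the variation-coefficient identity (dNe/Ne)^2 =
#' exp(sigmaL^2 (te - ts)) - 1 using the sample coefficient of variation at
#' the last grid time.  Returns 0 for a degenerate (zero-variance)
#' ensemble.
#'
#' @param ens a `"trajectory_ensemble"`.
#' @param bc boundary conditions supplying `ts` (defaults to those of the
#'   generating process).
#' @return Estimated volatility, units time^(-1/2).
#' @export
recover_sigma <- function(ens, bc = ens$process$bc) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  bc <- as_boundary_conditions(bc)
  nt <- length(ens$t_grid)
  st <- ensemble_stats(ens)
  cv <- st$stddev[nt] / st$mean[nt]
  if (!is.finite(cv) || cv == 0) return(0)
  sqrt(log(1 + cv^2) / (ens$t_grid[nt] - bc$ts))
}

#' Long-format export of an ensemble
#'
#' @param x a `"trajectory_ensemble"`.
#' @param ... unused.
#' @return Data frame with columns `path_id`, `t`, `value`.
#' @export
as.data.frame.trajectory_ensemble <- function(x, ...) {
  nt <- length(x$t_grid)
  np <- nrow(x$paths)
  data.frame(path_id = rep(seq_len(np), each = nt),
             t = rep(x$t_grid, times = np),
             value = as.vector(t(x$paths)))
}

#' @export
plot.trajectory_ensemble <- function(x, max_paths = 50, ...) {
  band <- stddev_band(x$process, x$t_grid)
  show <- seq_len(min(max_paths, nrow(x$paths)))
  ylim <- range(x$paths[show, ], band$upper, band$lower)
  graphics::matplot(x$t_grid, t(x$paths[show, , drop = FALSE]),
                    type = "l", lty = 1, col = grDevices::grey(0.7),
                    xlab = "time", ylab = "number of species/genera",
                    ylim = ylim, ...)
  graphics::lines(x$t_grid, band$mean, col = "red", lwd = 2)
  graphics::lines(x$t_grid, band$upper, col = "blue", lty = 2)
  graphics::lines(x$t_grid, band$lower, col = "blue", lty = 2)
  invisible(x)
}
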