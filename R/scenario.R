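#' Scenario configuration files
#'
#' A scenario bundles a name, a time unit, the five boundary parameters and
#' a mean-curve family (with shape parameters) into one human-readable YAML
#' file.  Two fixtures ship with the package:
#'
#' * `earth-gbm` --- exponential growth of species counts on Earth from one
#'   initial form of life 3.5 billion years ago to an assumed mean of 50
#'   million living species (sd 30 million) today; time unit years.
#' * `markov-korotayev-cubic` --- Phanerozoic genus diversity as a cubic
#'   trend from 1 genus 530 Myr ago to 4000 +/- 1000 genera today, with a
#'   local maximum 400 Myr ago and a local minimum 220 Myr ago; time unit
#'   millions of years.
#'
#' @param path path to a scenario YAML file.
#' @param name fixture name for `scenario_fixture()`.
#' @return `load_scenario()`: an object of class `"scenario"` (named list
#'   with `name`, `time_unit`, `bc`, `family`, `shape`, `grid`).
#'   `scenario_fixture()`: the same, loaded from the installed fixture.
#'   `write_scenario()`: the path, invisibly.
#' @examples
#' sc <- scenario_fixture("markov-korotayev-cubic")
#' proc <- scenario_process(sc)
#' evo_entropy(proc, p = 0)   # ~12.074 bits/individual
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (field in c("name", "time_unit", "boundary", "family"))
    if (is.null(raw[[field]]))
      stop("scenario file is missing required field '", field, "'",
           call. = FALSE)
  if (!raw$time_unit %in% c("yr", "Myr"))
    stop("field 'time_unit' must be 'yr' or 'Myr'", call. = FALSE)
  b <- raw$boundary
  for (field in c("ts", "Ns", "te", "Ne", "dNe")) {
    if (is.null(b[[field]]))
      stop("scenario field 'boundary' is missing '", field, "'",
           call. = FALSE)
    b[[field]] <- as.numeric(b[[field]])   # robust to YAML string scalars
  }
  bc <- boundary_conditions(b$ts, b$Ns, b$te, b$Ne, b$dNe)
  shape <- raw$shape
  if (!is.null(shape)) shape <- lapply(shape, as.numeric)
  if (identical(raw$family, "cubic")) {
    if (is.null(shape$tMax) || is.null(shape$tmin))
      stop("scenario family 'cubic' requires shape fields 'tMax', 'tmin'",
           call. = FALSE)
    if (!(bc$ts < shape$tMax && shape$tMax < shape$tmin &&
            shape$tmin < bc$te))
      stop("cubic extrema must satisfy ts < tMax < tmin < te",
           call. = FALSE)
  }
  grid <- raw$grid
  if (is.null(grid)) grid <- list(points = 201)
  grid$points <- as.integer(grid$points)
  structure(list(name = raw$name, time_unit = raw$time_unit, bc = bc,
                 family = raw$family, shape = shape, grid = grid),
            class = "scenario")
}

#' @rdname load_scenario
#' @param scenario a `"scenario"` object.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario"))
  bc <- scenario$bc
  out <- list(name = scenario$name, time_unit = scenario$time_unit,
              boundary = list(ts = bc$ts, Ns = bc$Ns, te = bc$te,
                              Ne = bc$Ne, dNe = bc$dNe),
              family = scenario$family)
  if (!is.null(scenario$shape)) out$shape <- scenario$shape
  out$grid <- scenario$grid
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname load_scenario
#' @export
scenario_fixture <- function(name = c("earth-gbm", "markov-korotayev-cubic")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"),
                      package = "evoentropy", mustWork = TRUE)
  load_scenario(path)
}

#' @rdname load_scenario
#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (time unit: %s; family: %s)\n",
              x$name, x$time_unit, x$family))
  print(x$bc)
  if (!is.null(x$shape))
    cat("  shape:", paste(names(x$shape), unlist(x$shape), sep = " = ",
                          collapse = ", "), "\n")
  invisible(x)
}

#' Build the lognormal process described by a scenario
#'
#' @param scenario a `"scenario"` object.
#' @return A [lognormal_process()].
#' @export
scenario_process <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  lognormal_process(scenario$bc, family = scenario$family,
                    tMax = scenario$shape$tMax, tmin = scenario$shape$tmin,
                    coeffs = scenario$shape$coeffs)
}

#' Run a scenario and write its artifacts
#'
#' Drives the whole model for one scenario: evaluates the mean and
#' standard-deviation band, the peak-locus family and the entropy curves on
#' the scenario grid, optionally simulates a trajectory ensemble, and
#' writes the results as CSV files plus a JSON summary of the headline
#' scalars (volatility, EvoEntropy at te in both modes, and the exact GBM
#' closed form).  Figures analogous to the band, locus and entropy plots
#' can be written as PNGs.
#'
#' If the mean curve is non-positive somewhere on the entropy grid those
#' outputs are skipped with a warning (partial artifact bundle).
#'
#' @param scenario a `"scenario"` object.
#' @param outputs subset of `c("summary", "curves", "peaklocus", "entropy",
#'   "ensemble")`.
#' @param dir output directory (created if needed).
#' @param seed root seed for the ensemble output.
#' @param n_paths ensemble size.
#' @param make_figures also write PNG figures.
#' @return Invisibly, a list with the computed tables and the summary.
#' @export
run_scenario <- function(scenario,
                         outputs = c("summary", "curves", "peaklocus",
                                     "entropy"),
                         dir = ".", seed = 1, n_paths = 100,
                         make_figures = FALSE) {
  stopifnot(inherits(scenario, "scenario"))
  outputs <- match.arg(outputs, c("summary", "curves", "peaklocus",
                                  "entropy", "ensemble"),
                       several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  proc <- scenario_process(scenario)
  bc <- proc$bc
  grid <- seq(bc$ts, bc$te, length.out = scenario$grid$points)
  res <- list(scenario = scenario, process = proc)
  stem <- function(what, ext = "csv")
    file.path(dir, sprintf("%s-%s.%s", scenario$name, what, ext))

  summary_scalars <- list(
    scenario = scenario$name, time_unit = scenario$time_unit,
    sigmaL = proc$sigmaL,
    evo_at_te_with_end_stddev = evo_entropy(proc, bc$te),
    evo_at_te_squashed = evo_entropy(proc, bc$te, mode = "squashed"),
    gbm_evo_at_te = gbm_evo_entropy(bc, bc$te))
  res$summary <- summary_scalars
  if ("summary" %in% outputs)
    jsonlite::write_json(summary_scalars, stem("summary", "json"),
                         auto_unbox = TRUE, digits = NA)

  if ("curves" %in% outputs) {
    res$curves <- stddev_band(proc, grid)
    utils::write.csv(res$curves, stem("curves"), row.names = FALSE)
  }

  # entropy and peak locus need a positive mean on the open grid
  mean_on_grid <- predict(proc$mean_curve, grid)
  pos <- mean_on_grid > 0
  if (!all(pos))
    warning("mean curve non-positive on part of the grid; ",
            "peak-locus/entropy outputs restricted to the positive part")
  pgrid <- grid[pos]

  if ("peaklocus" %in% outputs) {
    res$peaklocus <- peak_locus(proc, pgrid)
    utils::write.csv(res$peaklocus, stem("peaklocus"), row.names = FALSE)
  }
  if ("entropy" %in% outputs) {
    res$entropy <- entropy_curve(proc, pgrid)
    utils::write.csv(as.data.frame(res$entropy), stem("entropy"),
                     row.names = FALSE)
  }
  if ("ensemble" %in% outputs) {
    ens <- simulate_paths(proc, grid, n_paths = n_paths, seed = seed)
    res$ensemble <- ens
    utils::write.csv(as.data.frame(ens), stem("ensemble"),
                     row.names = FALSE)
  }

  if (make_figures) {
    fig <- function(what, expr) {
      grDevices::png(stem(what, "png"), width = 900, height = 600)
      on.exit(grDevices::dev.off(), add = TRUE)
      force(expr)
    }
    fig("band", plot(proc, main = scenario$name))
    if (any(pos))
      fig("evoentropy", plot(entropy_curve(proc, pgrid),
                             main = scenario$name))
    if (!is.null(res$ensemble))
      fig("paths", plot(res$ensemble, main = scenario$name))
  }
  invisible(res)
}
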