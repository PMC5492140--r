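# Randomized-but-reproducible generators used by the property tests.

random_bc <- function() {
  ts <- runif(1, -1000, 0)
  te <- ts + runif(1, 10, 1000)
  Ns <- runif(1, 0.5, 10)
  Ne <- Ns * runif(1, 1.5, 5000)
  dNe <- Ne * runif(1, 0, 0.8)
  boundary_conditions(ts, Ns, te, Ne, dNe)
}

# a random process drawn from any of the four boundary-calibrated families,
# with a mean curve that stays positive on [ts, te] (exotic cubics can dip
# below zero; those are rejected here and exercised in dedicated tests)
random_process <- function(bc = random_bc()) {
  family <- sample(c("gbm", "straight_line", "parabola", "cubic"), 1)
  if (family == "cubic") {
    span <- bc$te - bc$ts
    for (attempt in 1:20) {
      tMax <- bc$ts + span * runif(1, 0.15, 0.45)
      tmin <- bc$ts + span * runif(1, 0.55, 0.85)
      grid <- seq(bc$ts, bc$te, length.out = 101)
      if (min(cubic_mean(grid, bc, tMax, tmin)) > 0)
        return(lognormal_process(bc, family = "cubic",
                                 tMax = tMax, tmin = tmin))
    }
    family <- "parabola"
  }
  lognormal_process(bc, family = family)
}

mk_bc <- function() boundary_conditions(-530, 1, 0, 4000, 1000)
mk_process <- function()
  lognormal_process(mk_bc(), family = "cubic", tMax = -400, tmin = -220)
earth_bc <- function() boundary_conditions(-3.5e9, 1, 0, 5e7, 3e7)
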