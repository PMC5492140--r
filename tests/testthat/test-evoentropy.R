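test_that("locus entropy is the entropy of the locus b-lognormal
           (composition identity)", {
  set.seed(88)
  for (i in 1:15) {
    proc <- random_process()
    p <- runif(4, proc$bc$ts, proc$bc$te)
    p <- p[predict(proc$mean_curve, p) > 0]
    pl <- peak_locus(proc, p)
    direct <- mapply(blognormal_entropy_bits, pl$mu, pl$sigma, pl$b)
    expect_equal(entropy_of_locus(proc, p), unname(direct),
                 tolerance = 1e-10)
  }
})

test_that("boundary-parameter entropy form equals the volatility form", {
  set.seed(99)
  for (i in 1:10) {
    proc <- random_process()
    p <- runif(5, proc$bc$ts, proc$bc$te)
    p <- p[predict(proc$mean_curve, p) > 0]
    expect_equal(entropy_of_locus(proc, p),
                 entropy_of_locus_boundary(proc, p), tolerance = 1e-12)
  }
})

test_that("constant unit mean with zero volatility has the frozen locus
           entropy", {
  # quadrature-verified: (1/(4 pi) + 1/2) / ln 2
  det <- lognormal_process(boundary_conditions(-1, 1, 1, 1, 0),
                           family = "straight_line")
  expect_equal(entropy_of_locus(det, 0), 0.836153544010303,
               tolerance = 1e-9)
})

test_that("EvoEntropy vanishes at ts in both modes and equals the
           sign-reversed anchored entropy", {
  set.seed(111)
  for (i in 1:10) {
    proc <- random_process()
    expect_lt(abs(evo_entropy(proc, proc$bc$ts)), 1e-10)
    expect_lt(abs(evo_entropy(proc, proc$bc$ts, mode = "squashed")), 1e-10)
    p <- runif(4, proc$bc$ts, proc$bc$te)
    p <- p[predict(proc$mean_curve, p) > 0]
    expect_equal(evo_entropy(proc, p),
                 -(entropy_of_locus(proc, p) -
                     entropy_of_locus(proc, proc$bc$ts)),
                 tolerance = 1e-10)
  }
})

test_that("Phanerozoic cubic scenario reproduces the published present-day
           EvoEntropy in both conventions", {
  proc <- mk_process()
  expect_equal(evo_entropy(proc, 0), 12.074, tolerance = 1e-3)
  # the dNe = 0 (squashed) convention gives the slightly larger value
  expect_equal(evo_entropy(proc, 0, mode = "squashed"), 12.0805897,
               tolerance = 1e-6)
})

test_that("boundary-calibrated GBM EvoEntropy is the exact molecular-clock
           line", {
  bc <- earth_bc()
  expect_equal(gbm_evo_entropy(bc, 0), log2(5e7), tolerance = 1e-12)
  expect_equal(gbm_evo_entropy(bc, bc$ts), 0)
  p <- seq(bc$ts, 0, length.out = 100)
  expect_equal(max(abs(diff(diff(gbm_evo_entropy(bc, p))))), 0)
  expect_error(gbm_evo_entropy(bc, bc$ts - 1), "ts")
})

test_that("on a volatility-tied GBM process the locus EvoEntropy is linear
           in p (molecular clock) and matches the closed form", {
  proc <- gbm_process(A = 1, B = 0.05, horizon = 100)
  p <- seq(0, 100, length.out = 100)
  evo <- evo_entropy(proc, p)
  expect_lt(max(abs(diff(diff(evo)))), 1e-9)
  expect_equal(evo, proc$B * (p - proc$bc$ts) / log(2), tolerance = 1e-10)
})

test_that("squashed EvoEntropy of a monotone increasing mean is strictly
           increasing with no interior extrema", {
  set.seed(122)
  for (fam in c("gbm", "straight_line", "parabola")) {
    bc <- random_bc()
    proc <- lognormal_process(bc, family = fam)
    p <- seq(bc$ts, bc$te, length.out = 200)
    d1 <- diff(evo_entropy(proc, p, mode = "squashed"))
    expect_true(all(d1 > 0))
    expect_equal(length(unique(sign(d1))), 1L)   # no sign change anywhere
  }
})

test_that("term decomposition: printed constant and logarithmic dominance
           at large mean counts", {
  expect_equal(1 / (4 * pi), 0.079577471545948, tolerance = 1e-14)
  # at m = 1e6 the logarithmic term dwarfs the inverse-square term
  m <- 1e6
  expect_gt(log(m) / (1 / (4 * pi * m^2)), 1e12)
  # and the squashed curve is within one constant's width of log2(m) for Ns=1
  bc <- boundary_conditions(0, 1, 10, m, 0)
  proc <- lognormal_process(bc, family = "gbm")
  expect_equal(evo_entropy(proc, 10, mode = "squashed"),
               log2(m) + (1 / (4 * pi)) / log(2), tolerance = 1e-6)
})

test_that("all three polynomial growth families agree at both endpoints and
           differ in between", {
  bc <- mk_bc()
  end_val <- family_evo_entropy("straight_line", bc, 0)
  expect_equal(family_evo_entropy("parabola", bc, 0), end_val,
               tolerance = 1e-12)
  expect_equal(family_evo_entropy("cubic", bc, 0, tMax = -400, tmin = -220),
               end_val, tolerance = 1e-12)
  # frozen endpoint value: (1/ln2)(1/(4pi) - 1/(4pi Ne^2) + ln Ne)
  expect_equal(end_val, (1 / (4 * pi) - 1 / (4 * pi * 4000^2) +
                           log(4000)) / log(2), tolerance = 1e-12)
  expect_equal(end_val, 12.0805903010525, tolerance = 1e-10)
  for (fam in c("straight_line", "parabola"))
    expect_lt(abs(family_evo_entropy(fam, bc, bc$ts)), 1e-10)
  # mid-Phanerozoic they disagree (different growth shapes)
  mid <- -265
  vals <- c(family_evo_entropy("straight_line", bc, mid),
            family_evo_entropy("parabola", bc, mid),
            family_evo_entropy("cubic", bc, mid, tMax = -400, tmin = -220))
  expect_gt(min(dist(vals)), 0.01)
  # dispatcher equals the direct squashed composition for the cubic
  proc <- mk_process()
  p <- seq(-520, 0, length.out = 20)
  expect_equal(family_evo_entropy("cubic", bc, p, tMax = -400, tmin = -220),
               evo_entropy(proc, p, mode = "squashed"), tolerance = 1e-12)
})

test_that("entropy_curve samples both series over the grid", {
  proc <- mk_process()
  ec <- entropy_curve(proc, p_grid = seq(-529, 0, length.out = 50))
  expect_s3_class(ec, "entropy_curve")
  expect_named(ec, c("p", "H_bits", "evo_bits"))
  expect_equal(ec$evo_bits, -(ec$H_bits - entropy_of_locus(proc, -530)),
               tolerance = 1e-10)
})
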