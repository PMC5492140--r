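test_that("every boundary-calibrated family passes through both endpoints", {
  set.seed(101)
  for (i in 1:25) {
    bc <- random_bc()
    span <- bc$te - bc$ts
    tMax <- bc$ts + 0.3 * span
    tmin <- bc$ts + 0.7 * span
    vals <- list(
      gbm = gbm_mean(c(bc$ts, bc$te), bc),
      straight = straight_line_mean(c(bc$ts, bc$te), bc),
      parabola = parabola_mean(c(bc$ts, bc$te), bc),
      cubic = cubic_mean(c(bc$ts, bc$te), bc, tMax, tmin))
    for (v in vals) {
      expect_equal(v[1], bc$Ns, tolerance = 1e-12)
      expect_equal(v[2], bc$Ne, tolerance = 1e-12)
    }
  }
})

test_that("GBM mean has the boundary-calibrated rate and rejects t < ts", {
  bc <- earth_bc()
  expect_equal(gbm_rate(bc), 5.06500958954069e-9, tolerance = 1e-12)
  expect_equal(gbm_mean(bc$ts, bc), 1)
  expect_equal(gbm_mean(bc$te, bc), 5e7, tolerance = 1e-12)
  expect_true(all(diff(gbm_mean(seq(bc$ts, 0, length.out = 50), bc)) > 0))
  expect_error(gbm_mean(bc$ts - 1, bc), "t >= ts")
})

test_that("straight line is affine with the printed midpoint value", {
  bc <- mk_bc()
  expect_equal(straight_line_mean(-265, bc), 2000.5)
  t <- seq(-530, 0, length.out = 7)
  expect_equal(max(abs(diff(diff(straight_line_mean(t, bc))))), 0)
})

test_that("parabola has zero slope at te (vertex at the end time)", {
  set.seed(7)
  bc <- random_bc()
  h <- (bc$te - bc$ts) * 1e-7
  deriv <- (parabola_mean(bc$te + h, bc) - parabola_mean(bc$te - h, bc)) /
    (2 * h)
  scale <- abs(bc$Ne - bc$Ns) / (bc$te - bc$ts)
  expect_lt(abs(deriv) / scale, 1e-6)
})

test_that("cubic matches an independently constructed cubic and places its
           extrema at tMax and tmin", {
  bc <- mk_bc()
  # independent route: solve the 4x4 linear system for the coefficients of
  # c0 + c1 tau + c2 tau^2 + c3 tau^3 with m(ts)=Ns, m(te)=Ne, m'=0 at both
  # prescribed extremal times
  tauM <- -400 - bc$ts; taum <- -220 - bc$ts; taue <- bc$te - bc$ts
  A <- rbind(c(1, 0, 0, 0),
             c(1, taue, taue^2, taue^3),
             c(0, 1, 2 * tauM, 3 * tauM^2),
             c(0, 1, 2 * taum, 3 * taum^2))
  cf <- solve(A, c(bc$Ns, bc$Ne, 0, 0))
  t <- seq(-530, 0, length.out = 101)
  expect_equal(cubic_mean(t, bc, -400, -220),
               polynomial_mean(t, cf, bc$ts), tolerance = 1e-10)
  # frozen values at the extrema (independent linear-solve evaluation)
  expect_equal(cubic_mean(-400, bc, -400, -220), 981.88679245283,
               tolerance = 1e-10)
  expect_equal(cubic_mean(-220, bc, -400, -220), 558.770537010158,
               tolerance = 1e-10)
  # numeric search near each turning point lands on tMax / tmin (the
  # *global* extrema over [ts, te] sit at the endpoints of a rising cubic)
  tt1 <- seq(-529, -300, by = 0.5)
  expect_lt(abs(tt1[which.max(cubic_mean(tt1, bc, -400, -220))] - (-400)),
            0.5 + 1e-9)
  tt2 <- seq(-300, -100, by = 0.5)
  expect_lt(abs(tt2[which.min(cubic_mean(tt2, bc, -400, -220))] - (-220)),
            0.5 + 1e-9)
})

test_that("cubic rejects bad extrema ordering", {
  bc <- mk_bc()
  expect_error(cubic_mean(0, bc, -220, -400), "ts < tMax < tmin < te")
  expect_error(mean_curve("cubic", bc, tMax = -600, tmin = -220),
               "ts < tMax < tmin < te")
})

test_that("polynomial evaluator is a Horner scheme agreeing with explicit
           family expansions", {
  expect_equal(polynomial_mean(7, c(0, 1), ts = 0), 7)
  expect_equal(polynomial_mean(123, 5, ts = -10), 5)
  expect_error(polynomial_mean(1, numeric(0), ts = 0), "non-empty")
  bc <- mk_bc()
  # straight line expanded in powers of (t - ts)
  t <- seq(-530, 0, length.out = 41)
  expect_equal(polynomial_mean(t, c(bc$Ns, (bc$Ne - bc$Ns) / (bc$te - bc$ts)),
                               ts = bc$ts),
               straight_line_mean(t, bc), tolerance = 1e-12)
  # parabola: Ns + 2 a tau - (a / taue) tau^2 with a = (Ne-Ns)/taue
  a <- (bc$Ne - bc$Ns) / (bc$te - bc$ts)
  expect_equal(polynomial_mean(t, c(bc$Ns, 2 * a, -a / (bc$te - bc$ts)),
                               ts = bc$ts),
               parabola_mean(t, bc), tolerance = 1e-12)
})

test_that("mean_curve objects dispatch to the family evaluators", {
  bc <- mk_bc()
  mc <- mean_curve("cubic", bc, tMax = -400, tmin = -220)
  expect_equal(predict(mc, c(-530, 0)), c(1, 4000), tolerance = 1e-12)
  expect_output(print(mc), "cubic")
  expect_error(mean_curve("polynomial", bc), "coeffs")
})

test_that("boundary conditions validate their invariants", {
  expect_error(boundary_conditions(0, 1, -1, 10, 1), "te")
  expect_error(boundary_conditions(0, -1, 1, 10, 1), "Ns")
  expect_error(boundary_conditions(0, 1, 1, 0, 1), "Ne")
  expect_error(boundary_conditions(0, 1, 1, 10, -1), "dNe")
})
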