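# Fractional-order operators: constant-phase transfer, gain fitting,
# power-law superposition, Gruenwald-Letnikov derivatives, step responses.

test_that("fractional transfer has power-law gain and constant phase", {
  expect_equal(frac_phase(1), pi / 2)
  expect_equal(frac_phase(0), 0)
  expect_equal(frac_phase(0.3), 0.3 * pi / 2)

  freqs <- log_freqs(0.001, 1000, 300)
  for (a in c(0.1, 0.5, 0.9)) {
    H <- frac_transfer(a, g = 1.3, freqs)
    expect_equal(Arg(H), rep(a * pi / 2, length(freqs)), tolerance = 1e-14)
    # decade scaling of the magnitude
    expect_equal(Mod(frac_transfer(a, 1, 10 * 2)) /
                   Mod(frac_transfer(a, 1, 2)),
                 10^a, tolerance = 1e-12)
  }
  expect_equal(frac_transfer(1, 1, 1 / (2 * pi)), 0 + 1i,
               tolerance = 1e-14)
  expect_error(frac_transfer(0.5, 1, c(-1, 1)), "positive")
  expect_error(frac_transfer(1.5, 1, 1), "alpha")
})

test_that("constant-phase fits approximate fractional dynamics", {
  fit <- fit_gains_constant_phase(canonical_taus, 0.2)
  expect_s3_class(fit, "phase_fit")
  expect_true(fit$converged)
  expect_lt(fit$residual, 0.05)
  expect_true(all(fit$A_values >= 1))

  # no adaptation target: A -> 1, residual -> 0
  fit0 <- fit_gains_constant_phase(canonical_taus, 0)
  expect_equal(fit0$A_values, 1, tolerance = 1e-4)
  expect_lt(fit0$residual, 1e-4)

  # per-stage fit is nested within shared fit
  sh <- fit_gains_constant_phase(canonical_taus, 0.5, mode = "shared")
  ps <- fit_gains_constant_phase(canonical_taus, 0.5, mode = "per-stage")
  expect_length(ps$A_values, 3)
  expect_lte(ps$residual, sh$residual)

  expect_error(fit_gains_constant_phase(c(0.5, 0.5), 0.3), "distinct")
  expect_error(fit_gains_constant_phase(canonical_taus, 0.3,
                                        band = c(5, 0.05)),
               "band")
})

test_that("gamma superposition reproduces power-law decay", {
  expect_equal(gamma_superposition(1, 3), 1 / 3, tolerance = 1e-9)
  expect_equal(gamma_superposition(0.5, 2), 2^(-0.5), tolerance = 1e-9)
  expect_equal(gamma_superposition(0.1, 1), 1, tolerance = 1e-9)
  for (k in seq(0.1, 0.9, by = 0.2)) {
    t <- c(0.1, 0.5, 1, 3, 10)
    expect_equal(gamma_superposition(k, t), t^(-k), tolerance = 1e-6)
  }
  expect_error(gamma_superposition(-1, 1), "k")
  expect_error(gamma_superposition(0.5, 0), "t")
})

test_that("discrete fractional derivatives match closed forms on monomials", {
  h <- 1e-3
  t <- seq(0, 2, by = h)
  ramp <- sampled_signal(t, t)

  # identity and first-derivative limits
  expect_identical(fractional_derivative(ramp, 0)$values, ramp$values)
  d1 <- fractional_derivative(ramp, 1)$values
  expect_equal(d1[10:length(t)], rep(1, length(t) - 9), tolerance = 1e-8)

  # half derivative of t: Gamma(2)/Gamma(1.5) * sqrt(t) = 2*sqrt(t/pi)
  d05 <- fractional_derivative(ramp, 0.5)$values
  expect_equal(d05[t >= 0.5], 2 * sqrt(t[t >= 0.5] / pi),
               tolerance = 2e-3)
  expect_equal(d05[t == 1], 2 / sqrt(pi), tolerance = 1e-3)

  # semigroup: D^a then D^(1-a) equals the first derivative
  for (a in c(0.3, 0.5, 0.7)) {
    dd <- fractional_derivative(fractional_derivative(ramp, a), 1 - a)
    expect_equal(dd$values[10:length(t)], rep(1, length(t) - 9),
                 tolerance = 1e-6)
  }

  expect_error(fractional_derivative(sampled_signal(c(0, 1, 3), 1:3), 0.5),
               "uniform")
})

test_that("step responses satisfy limit theorems and multi-decade decay", {
  t <- seq(0, 100, by = 0.005)
  hp <- highpass_stage(g = 1, tau = 1, A = 2)
  y <- step_response(hp, t)$values
  expect_equal(y[1], 1)
  expect_equal(y[length(y)], 0.5, tolerance = 1e-6)
  # closed form vs cascade (zero-order-hold) evaluation of the same stage
  ycas <- step_response(filter_cascade(highpass = list(hp)), t)$values
  expect_equal(ycas, y, tolerance = 1e-4)

  lp <- lowpass_stage(k = 2, tau = 0.5)
  yl <- step_response(lp, t)$values
  expect_equal(yl[1], 0)
  expect_equal(yl[length(yl)], 2, tolerance = 1e-6)

  # decay span: time ratio between 50% and 5% of the remaining excess;
  # a single stage is a plain exponential (ratio log(.05)/log(.5) ~ 4.3),
  # the three-timescale cascade stretches over orders of magnitude
  span <- function(y) {
    e <- (y - y[length(y)]) / (y[1] - y[length(y)])
    t[max(which(e >= 0.05))] / t[max(which(e >= 0.5))]
  }
  A <- fit_gains_constant_phase(canonical_taus, 0.1)$A_values
  stages <- lapply(canonical_taus,
                   function(tt) highpass_stage(1, tt, A))
  expect_gt(span(step_response(filter_cascade(highpass = stages),
                               t)$values), 40)
  for (st in stages) expect_lt(span(step_response(st, t)$values), 6)

  # fractional step response is the pure power law t^(-alpha)/Gamma(1-alpha)
  fr <- step_response(frac_order(0.1), c(0.1, 1))
  expect_equal(fr$values[1] / fr$values[2], 10^0.1, tolerance = 1e-12)
})
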