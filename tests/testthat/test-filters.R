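# Closed-form adaptation filters: transfer functions, cascades, DC-gain
# analysis, PSD shaping.

test_that("SFA and linearized STD transfers match their closed-form limits", {
  f_lo <- 1e-9
  f_hi <- 1e9

  p <- sfa_params(gamma = 1, c_gain = 1, F_adapt = 0.5, tau = 1)
  expect_equal(Mod(sfa_transfer(p, f_lo)), 2 / 3, tolerance = 1e-6)
  expect_equal(Mod(sfa_transfer(p, f_hi)), 1, tolerance = 1e-6)

  s <- std_lin_params(gamma = 1, F_adapt = 0.5, tau = 1, x0 = 1)
  expect_equal(Mod(std_linear_transfer(s, f_lo)), 1 / 1.5^2,
               tolerance = 1e-6)
  expect_equal(Mod(std_linear_transfer(s, f_hi)), 1 / 1.5,
               tolerance = 1e-6)

  # degenerate limits reduce to pure gain
  freqs <- log_freqs(0.01, 100)
  p0 <- sfa_params(gamma = 2.5, c_gain = 1, F_adapt = 0, tau = 1)
  expect_equal(sfa_transfer(p0, freqs), rep(2.5 + 0i, length(freqs)))
  p0c <- sfa_params(gamma = 2.5, c_gain = 0, F_adapt = 0.5, tau = 1)
  expect_equal(sfa_transfer(p0c, freqs), rep(2.5 + 0i, length(freqs)))
  s0 <- std_lin_params(gamma = 1.7, F_adapt = 0.5, tau = 1, x0 = 0)
  expect_equal(std_linear_transfer(s0, freqs),
               rep(1.7 + 0i, length(freqs)))

  # closed-form DC gains on random parameter draws
  set.seed(41)
  for (i in 1:20) {
    g <- runif(1, 0.2, 3); cc <- runif(1, 0.2, 3)
    Fa <- runif(1, 0.05, 0.95); tau <- runif(1, 0.01, 10)
    x0 <- runif(1, 0, 5)
    expect_equal(Mod(sfa_transfer(sfa_params(g, cc, Fa, tau), 1e-10)),
                 g / (1 + cc * Fa), tolerance = 1e-6)
    expect_equal(Mod(std_linear_transfer(std_lin_params(g, Fa, tau, x0),
                                         1e-10)),
                 g / (1 + x0 * Fa)^2, tolerance = 1e-6)
  }

  expect_error(sfa_params(gamma = -1), "gamma")
  expect_error(sfa_params(tau = 0), "tau")
  expect_error(std_lin_params(x0 = -0.1), "x0")
})

test_that("cascade responses compose multiplicatively, any stage order", {
  hp <- highpass_stage(g = 1, tau = 1, A = 2)
  lp <- lowpass_stage(k = 1, tau = 1)
  f_corner <- 1 / (2 * pi)   # omega = 1 rad/s

  expect_equal(Mod(cascade_response(filter_cascade(highpass = list(hp)),
                                    1e-9)),
               0.5, tolerance = 1e-6)
  expect_equal(Mod(cascade_response(filter_cascade(lowpass = list(lp)),
                                    f_corner)),
               1 / sqrt(2), tolerance = 1e-9)
  both <- filter_cascade(highpass = list(hp), lowpass = list(lp))
  expect_equal(Mod(cascade_response(both, 1e-9)), 0.5, tolerance = 1e-6)

  # product of stage responses, independent of grouping
  freqs <- log_freqs(0.01, 50)
  expect_equal(cascade_response(both, freqs),
               cascade_response(filter_cascade(highpass = list(hp)),
                                freqs) *
                 cascade_response(filter_cascade(lowpass = list(lp)),
                                  freqs),
               tolerance = 1e-12)

  # |H| monotone: non-decreasing for high-pass, non-increasing for low-pass
  set.seed(7)
  for (i in 1:10) {
    st <- highpass_stage(runif(1, 0.5, 2), runif(1, 0.05, 5),
                         1 + runif(1, 0, 4))
    m <- Mod(cascade_response(filter_cascade(highpass = list(st)), freqs))
    expect_true(all(diff(m) >= -1e-12))
    sl <- lowpass_stage(runif(1, 0.5, 2), runif(1, 0.05, 5))
    m2 <- Mod(cascade_response(filter_cascade(lowpass = list(sl)), freqs))
    expect_true(all(diff(m2) <= 1e-12))
  }

  expect_error(filter_cascade(), "at least one stage")
  expect_error(highpass_stage(A = 0.5), "A")
})

test_that("combined magnitude formula equals stage-by-stage evaluation", {
  freqs <- log_freqs(0.001, 1000, 60)

  # printed reference point: all gains 1, F = 0.5, at DC
  m0 <- cascade_magnitude_sq(
    sfa_params(1, 1, 0.5, 1), std_lin_params(1, 0.5, 1, 1),
    lowpass_stage(1, 1), 1e-10)
  expect_equal(m0, (1 / 2.25)^3, tolerance = 1e-6)
  # low-pass dominates at high frequency
  expect_lt(cascade_magnitude_sq(
    sfa_params(1, 1, 0.5, 1), std_lin_params(1, 0.5, 1, 1),
    lowpass_stage(1, 1), 1e6), 1e-10)

  # independent evaluation path: product of the three stage transfers
  set.seed(99)
  for (i in 1:100) {
    sfa <- sfa_params(runif(1, 0.2, 3), runif(1, 0.2, 3),
                      runif(1, 0.05, 0.95), runif(1, 0.05, 5))
    std <- std_lin_params(runif(1, 0.2, 3), runif(1, 0.05, 0.95),
                          runif(1, 0.05, 5), runif(1, 0, 4))
    lp <- lowpass_stage(runif(1, 0.2, 3), runif(1, 0.05, 5))
    direct <- cascade_magnitude_sq(sfa, std, lp, freqs)
    byparts <- Mod(sfa_transfer(sfa, freqs) *
                     std_linear_transfer(std, freqs) *
                     cascade_response(filter_cascade(lowpass = list(lp)),
                                      freqs))^2
    expect_equal(direct, byparts, tolerance = 1e-10)
  }
})

test_that("DC output power is unimodal with the analytic peak", {
  # zero input gives zero output
  expect_identical(dc_output_power(1, 0.5, 1, 0), 0)

  # grid-search oracle for the reference parameter set
  x0 <- seq(1e-4, 5, by = 1e-4)
  p <- dc_output_power(3, 0.5, gamma = 2, x0 = x0)
  expect_equal(x0[which.max(p)], 1 / 5.5, tolerance = 1e-3)
  expect_equal(dc_peak_input(3, 0.5), 1 / 5.5, tolerance = 1e-12)
  expect_equal(dc_peak_input(1, 0.5), 2 / 3, tolerance = 1e-12)

  # monotone decreasing beyond the peak
  beyond <- x0[x0 > dc_peak_input(3, 0.5)]
  expect_true(all(diff(dc_output_power(3, 0.5, 2, beyond)) < 0))

  expect_error(dc_output_power(0, 0.5, 1, 1), "n")
  expect_error(dc_peak_input(1, 0), "F_adapt")
})

test_that("shaped PSDs multiply input spectra by the squared magnitude", {
  freqs <- log_freqs(0.01, 100)
  flat <- rep(1, length(freqs))

  lp <- filter_cascade(lowpass = list(lowpass_stage(1, 1)))
  expect_equal(shaped_psd(lp, flat, freqs),
               1 / ((2 * pi * freqs)^2 + 1), tolerance = 1e-12)

  ident <- filter_cascade(highpass = list(highpass_stage(1, 1, 1)))
  expect_equal(shaped_psd(ident, flat, freqs), flat, tolerance = 1e-12)

  expect_error(shaped_psd(lp, flat[-1], freqs), "length")

  # stronger adaptation setting has lower low-frequency power
  mk <- function(A, g) filter_cascade(
    highpass = lapply(canonical_taus,
                      function(tt) highpass_stage(g = g, tau = tt, A = A)),
    lowpass = list(lowpass_stage(k = 500, tau = 5)))
  p_weak <- shaped_psd(mk(1.1, 1.3), flat, freqs)
  p_strong <- shaped_psd(mk(1.5, 1.5), flat, freqs)
  i01 <- which.min(abs(freqs - 0.1))
  expect_lt(p_strong[i01], p_weak[i01])
})

test_that("log-log slope estimates recover known spectral shapes", {
  freqs <- log_freqs(0.01, 500, 400)
  lorentz <- 1 / ((2 * pi * freqs)^2 + 1)
  expect_equal(psd_slope(lorentz, freqs, band = c(20, 500)), -2,
               tolerance = 0.01)
  expect_equal(psd_slope(rep(3.7, length(freqs)), freqs, band = c(0.1, 10)),
               0, tolerance = 1e-10)
  expect_error(psd_slope(lorentz, freqs, band = c(100, 101)),
               "fewer than 5")
})
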