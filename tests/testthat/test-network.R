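# Population LFP proxy and Welch spectral estimation.

test_that("population runs are deterministic and compose from the
          single-neuron pipeline", {
  cfg <- network_config(n_neurons = 2, duration = 20, base_seed = 77,
                        burn_in = 2, std_level = "high",
                        sfa_level = "low")
  r1 <- run_network(cfg)
  r2 <- run_network(cfg)
  expect_identical(r1$signal$values, r2$signal$values)
  expect_identical(r1$rates, r2$rates)

  # n_neurons = 1 equals the hand-assembled single-neuron pipeline
  cfg1 <- network_config(n_neurons = 1, duration = 20, base_seed = 77,
                         burn_in = 2, std_level = "high",
                         sfa_level = "low")
  net <- run_network(cfg1)
  x <- generate_filtered_noise(noise_input(condition_noise_sd("medium"),
                                           20, seed = 78))
  sim <- simulate_neuron(x, ahp = ahp_for_level("low"),
                         keep_voltage = FALSE)
  at <- run_train(std_params("high"), sim$spikes)
  sig <- amplitudes_to_signal(at, dt = 1 / 200, duration = 20)
  keep <- sig$t >= 2
  expect_equal(net$signal$values, sig$values[keep], tolerance = 1e-12)

  # without depression the proxy is the filtered population spike train:
  # every spike contributes the same unit impulse
  cfg0 <- network_config(n_neurons = 2, duration = 20, base_seed = 77,
                         burn_in = 2, std_level = "none",
                         sfa_level = "none")
  r0 <- run_network(cfg0)
  expect_gte(min(r0$signal$values), 0)
  expect_gt(mean(r0$signal$values), mean(r1$signal$values))
})

test_that("welch estimates recover line, white, and Lorentzian spectra", {
  fs <- 200
  t <- seq(1 / fs, 60, by = 1 / fs)

  # unit sinusoid: peak at 1 Hz, total power 1/2
  p <- welch_psd(sin(2 * pi * t), fs = fs, segment_length = 10)
  expect_equal(p$freqs[which.max(p$power)], 1, tolerance = 1e-9)
  expect_equal(sum(p$power) * p$freqs[1], 0.5, tolerance = 0.02)

  # white noise integrates to its variance
  set.seed(8)
  x <- rnorm(length(t), sd = 1.7)
  pw <- welch_psd(x, fs = fs, segment_length = 5)
  expect_equal(sum(pw$power) * pw$freqs[1], var(x), tolerance = 0.05)

  # exponentially filtered noise has a Lorentzian -2 tail (corner at
  # 1/(2*pi*0.05 s) ~ 3.2 Hz, band well above it and below Nyquist)
  ou <- generate_filtered_noise(noise_input(1, 120, dt = 1,
                                            tau_filter = 50, seed = 3))
  po <- welch_psd(ou, fs = 1000, segment_length = 10)
  expect_equal(psd_slope(po$power, po$freqs, band = c(30, 150)), -2,
               tolerance = 0.3)

  expect_error(welch_psd(rnorm(100), fs = 200, segment_length = 10),
               "shorter")
})

test_that("condition comparisons report band powers and crossings", {
  freqs <- seq(0.05, 50, by = 0.05)
  mk <- function(power) structure(
    list(freqs = freqs, power = power, fs = 100, segment_length = 20,
         overlap = 0.5, window = "hann", n_segments = 10),
    class = "psd_estimate")

  flat <- mk(rep(2, length(freqs)))
  steep <- mk(2 / freqs)   # crosses the flat spectrum at 1 Hz

  same <- compare_conditions(list(a = flat, b = flat),
                             crossing_pair = c("a", "b"))
  expect_true(is.na(same$crossing_frequency))
  expect_equal(same$band_powers["a", ], same$band_powers["b", ])

  cmp <- compare_conditions(list(steep = steep, flat = flat),
                            crossing_pair = c("steep", "flat"),
                            smooth_bins = 1)
  expect_equal(cmp$crossing_frequency, 1, tolerance = 0.05)
  expect_gt(cmp$band_powers["steep", "low"],
            cmp$band_powers["flat", "low"])
  expect_lt(cmp$band_powers["steep", "high"],
            cmp$band_powers["flat", "high"])

  bad <- mk(rep(1, length(freqs)))
  bad$freqs <- freqs * 2
  expect_error(compare_conditions(list(flat, bad)), "frequency grid")
})
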