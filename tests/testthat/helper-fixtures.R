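# Shared fixtures: canonical timescales and small generators used across
# test files. All randomness is seeded locally inside each test.

canonical_taus <- c(0.05, 0.5, 5)

# log-spaced frequency grid
log_freqs <- function(f_lo, f_hi, n = 200) {
  exp(seq(log(f_lo), log(f_hi), length.out = n))
}

# Poisson spike train on [0, duration) at `rate` Hz (seeded)
poisson_train <- function(rate, duration, seed) {
  set.seed(seed)
  n <- rpois(1, rate * duration)
  spike_train(sort(runif(n, 0, duration)), duration)
}

# steady-state pre-spike depression level for a periodic train: fixed
# point of v <- 1 - (1 - f * v) * exp(-gap / tau), iterated to machine
# precision (contraction factor f * exp(-gap/tau) < 1)
periodic_fixed_point <- function(f, tau, gap) {
  v <- 1
  repeat {
    v_new <- 1 - (1 - f * v) * exp(-gap / tau)
    if (abs(v_new - v) < 1e-15) return(v_new)
    v <- v_new
  }
}
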