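# Linear filter models of adaptation: SFA and linearized STD transfer
# functions, general high-pass/low-pass cascades, PSD shaping, and the
# steady-state (DC) gain analysis of depressing synapses.

#' Parameters of the spike-frequency adaptation filter
#'
#' The firing-rate model of SFA is a first-order negative-feedback loop:
#' `y = gamma * x - c * a`, `tau * da/dt = -a + F * y`, whose transfer
#' function is `H(s) = gamma * (tau*s + 1) / (tau*s + 1 + c*F)`. It is a
#' high-pass (differentiating) filter: the DC gain `gamma / (1 + c*F)` is
#' below the high-frequency gain `gamma`.
#'
#' @param gamma Input gain (> 0, dimensionless).
#' @param c_gain Gain coupling the adaptation variable back to the rate
#'   (> 0).
#' @param F_adapt Adaptation fraction, strength of output-to-adaptation
#'   coupling, in `(0, 1)`. `F_adapt = 0` is accepted and turns adaptation
#'   off (pure gain `gamma`).
#' @param tau Effective adaptation time constant in seconds (> 0).
#' @return An object of class `sfa_params`.
#' @seealso [sfa_transfer()]
#' @export
#' @examples
#' p <- sfa_params(gamma = 1, c_gain = 1, F_adapt = 0.5, tau = 1)
#' sfa_transfer(p, c(0.001, 1, 100))
sfa_params <- function(gamma = 1, c_gain = 1, F_adapt = 0.5, tau = 1) {
  stopifnot(is.numeric(gamma), length(gamma) == 1, is.finite(gamma))
  if (gamma <= 0) stop("`gamma` must be positive")
  if (c_gain < 0) stop("`c_gain` must be non-negative")
  if (F_adapt < 0 || F_adapt >= 1) stop("`F_adapt` must lie in [0, 1)")
  if (tau <= 0) stop("`tau` must be positive (seconds)")
  structure(list(gamma = gamma, c_gain = c_gain, F_adapt = F_adapt,
                 tau = tau),
            class = "sfa_params")
}

#' Parameters of the linearized short-term depression filter
#'
#' Synaptic depression `y = gamma * x * a`,
#' `tau * da/dt = 1 - a - x * F * a` is nonlinear in the input. For small
#' fluctuations around the steady state (`a0 = 1 / (1 + x0 * F)`) it
#' linearizes to
#' `H(s) = gamma/(1 + x0*F) * (tau*s + 1) / (tau*s + 1 + x0*F)`: the same
#' high-pass form as SFA but with a gain that shrinks as the steady-state
#' input `x0` (the mean presynaptic rate) grows.
#'
#' @param gamma Input gain (> 0).
#' @param F_adapt Adaptation fraction in `[0, 1)`.
#' @param tau Effective time constant in seconds (> 0).
#' @param x0 Steady-state input (mean presynaptic rate), `>= 0`.
#' @return An object of class `std_lin_params`.
#' @seealso [std_linear_transfer()], [dc_output_power()]
#' @export
std_lin_params <- function(gamma = 1, F_adapt = 0.5, tau = 1, x0 = 1) {
  if (gamma <= 0) stop("`gamma` must be positive")
  if (F_adapt < 0 || F_adapt >= 1) stop("`F_adapt` must lie in [0, 1)")
  if (tau <= 0) stop("`tau` must be positive (seconds)")
  if (!is.numeric(x0) || length(x0) != 1 || !is.finite(x0) || x0 < 0)
    stop("`x0` must be a single non-negative number")
  a0 <- 1 / (1 + x0 * F_adapt)
  structure(list(gamma = gamma, F_adapt = F_adapt, tau = tau, x0 = x0,
                 a0 = a0),
            class = "std_lin_params")
}

#' High-pass (adaptation) filter stage
#'
#' One adaptive mechanism, `H(s) = g * (tau*s + 1) / (tau*s + A)`, with
#' `A >= 1`; `A` closer to 1 means less adaptation (DC gain `g/A` closer to
#' the high-frequency gain `g`).
#'
#' @param g Gain constant (> 0).
#' @param tau Time constant in seconds (> 0).
#' @param A Adaptation constant, `>= 1`.
#' @return An object of class `highpass_stage`.
#' @export
highpass_stage <- function(g = 1, tau = 1, A = 1) {
  if (g <= 0) stop("`g` must be positive")
  if (tau <= 0) stop("`tau` must be positive (seconds)")
  if (A < 1) stop("`A` must be >= 1")
  structure(list(g = g, tau = tau, A = A), class = "highpass_stage")
}

#' Low-pass (membrane) filter stage
#'
#' `H(s) = k / (tau*s + 1)`; magnitude is non-increasing in frequency.
#'
#' @param k Gain constant (> 0).
#' @param tau Time constant in seconds (> 0).
#' @return An object of class `lowpass_stage`.
#' @export
lowpass_stage <- function(k = 1, tau = 1) {
  if (k <= 0) stop("`k` must be positive")
  if (tau <= 0) stop("`tau` must be positive (seconds)")
  structure(list(k = k, tau = tau), class = "lowpass_stage")
}

#' Series cascade of high-pass and low-pass stages
#'
#' Adaptive mechanisms are assumed to act in series, so the cascade response
#' at any frequency is the product of the stage responses. Stage order is
#' therefore irrelevant to the response.
#'
#' @param highpass List of [highpass_stage()] objects (possibly empty).
#' @param lowpass List of [lowpass_stage()] objects (possibly empty).
#' @return An object of class `filter_cascade`. At least one stage is
#'   required.
#' @export
#' @examples
#' cas <- filter_cascade(
#'   highpass = list(highpass_stage(g = 1, tau = 1, A = 2)),
#'   lowpass  = list(lowpass_stage(k = 1, tau = 1)))
#' cascade_response(cas, c(0.001, 1, 10))
filter_cascade <- function(highpass = list(), lowpass = list()) {
  if (inherits(highpass, "highpass_stage")) highpass <- list(highpass)
  if (inherits(lowpass, "lowpass_stage")) lowpass <- list(lowpass)
  ok_hp <- all(vapply(highpass, inherits, logical(1), "highpass_stage"))
  ok_lp <- all(vapply(lowpass, inherits, logical(1), "lowpass_stage"))
  if (!ok_hp) stop("`highpass` must be a list of highpass_stage objects")
  if (!ok_lp) stop("`lowpass` must be a list of lowpass_stage objects")
  if (length(highpass) + length(lowpass) == 0)
    stop("cascade needs at least one stage")
  structure(list(highpass = highpass, lowpass = lowpass),
            class = "filter_cascade")
}

# frequencies in Hz: strictly increasing, all positive
check_freqs <- function(freqs) {
  if (!is.numeric(freqs) || length(freqs) == 0 || anyNA(freqs))
    stop("`freqs` must be a numeric vector without NA")
  if (any(freqs <= 0)) stop("`freqs` must be positive (Hz)")
  if (is.unsorted(freqs, strictly = TRUE))
    stop("`freqs` must be strictly increasing")
  invisible(freqs)
}

#' Transfer function of spike-frequency adaptation
#'
#' Evaluates `H(i*omega) = gamma * (tau*i*omega + 1) /
#' (tau*i*omega + 1 + c*F)` on a grid of frequencies in Hz
#' (`omega = 2*pi*f`).
#'
#' @param p An [sfa_params()] object.
#' @param freqs Frequencies in Hz, strictly increasing and positive.
#' @return Complex response, one value per frequency.
#' @export
sfa_transfer <- function(p, freqs) {
  stopifnot(inherits(p, "sfa_params"))
  check_freqs(freqs)
  s <- 2i * pi * freqs * p$tau
  p$gamma * (s + 1) / (s + 1 + p$c_gain * p$F_adapt)
}

#' Transfer function of linearized short-term depression
#'
#' Evaluates `H(i*omega) = gamma/(1 + x0*F) * (tau*i*omega + 1) /
#' (tau*i*omega + 1 + x0*F)`. With `x0 = 0` the synapse passes the input
#' through with gain `gamma`.
#'
#' @param p An [std_lin_params()] object.
#' @inheritParams sfa_transfer
#' @return Complex response per frequency.
#' @export
std_linear_transfer <- function(p, freqs) {
  stopifnot(inherits(p, "std_lin_params"))
  check_freqs(freqs)
  s <- 2i * pi * freqs * p$tau
  p$gamma * p$a0 * (s + 1) / (s + 1 + p$x0 * p$F_adapt)
}

#' Frequency response of a filter cascade
#'
#' Product over high-pass stages `g*(tau*s + 1)/(tau*s + A)` and low-pass
#' stages `k/(tau*s + 1)` with `s = 2i*pi*f`.
#'
#' @param cascade A [filter_cascade()] object.
#' @inheritParams sfa_transfer
#' @return Complex response per frequency.
#' @export
cascade_response <- function(cascade, freqs) {
  stopifnot(inherits(cascade, "filter_cascade"))
  check_freqs(freqs)
  s <- 2i * pi * freqs
  H <- rep(1 + 0i, length(freqs))
  for (st in cascade$highpass)
    H <- H * st$g * (st$tau * s + 1) / (st$tau * s + st$A)
  for (st in cascade$lowpass)
    H <- H * st$k / (st$tau * s + 1)
  H
}

#' Squared magnitude of the SFA + STD + membrane cascade
#'
#' Closed form for one SFA stage, one linearized STD stage and one membrane
#' low-pass in series:
#' \deqn{|H|^2 = \frac{\gamma_1^2 \gamma_2^2 k^2}{(1 + x_0 F_2)^2}
#'   \frac{\tau_1^2\omega^2 + 1}{\tau_1^2\omega^2 + (1 + cF_1)^2}
#'   \frac{\tau_2^2\omega^2 + 1}{\tau_2^2\omega^2 + (1 + x_0F_2)^2}
#'   \frac{1}{\tau_3^2\omega^2 + 1}}
#' It agrees to floating point with evaluating the three stages separately
#' and multiplying.
#'
#' @param sfa An [sfa_params()] object (time constant `tau1`, fraction `F1`).
#' @param std An [std_lin_params()] object (`tau2`, `F2`, operating point
#'   `x0`).
#' @param lp A [lowpass_stage()] object (`k`, `tau3`).
#' @inheritParams sfa_transfer
#' @return `|H|^2` per frequency.
#' @export
cascade_magnitude_sq <- function(sfa, std, lp, freqs) {
  stopifnot(inherits(sfa, "sfa_params"), inherits(std, "std_lin_params"),
            inherits(lp, "lowpass_stage"))
  check_freqs(freqs)
  w2 <- (2 * pi * freqs)^2
  d1 <- 1 + sfa$c_gain * sfa$F_adapt
  d2 <- 1 + std$x0 * std$F_adapt
  sfa$gamma^2 * std$gamma^2 * lp$k^2 / d2^2 *
    (sfa$tau^2 * w2 + 1) / (sfa$tau^2 * w2 + d1^2) *
    (std$tau^2 * w2 + 1) / (std$tau^2 * w2 + d2^2) /
    (lp$tau^2 * w2 + 1)
}

#' Steady-state (DC) output power of depressing synapses
#'
#' For `n` identical timescales of synaptic depression with shared
#' adaptation fraction `F` and gain `gamma`, the squared steady-state output
#' at `s = 0` is `x0 * gamma^(2n) / (1 + x0*F)^(4n)`. As a function of the
#' steady-state input `x0` it first rises, peaks at
#' `x0 = 1/(4nF - F)` (see [dc_peak_input()]), then falls: more drive can
#' mean less output power.
#'
#' @param n Number of depression timescales (integer `>= 1`).
#' @param F_adapt Adaptation fraction, in `(0, 1)`.
#' @param gamma Gain constant (> 0).
#' @param x0 Steady-state input(s), `>= 0`; vectorized.
#' @return DC output power, same length as `x0`.
#' @export
#' @examples
#' x0 <- seq(0, 2, by = 0.01)
#' p <- dc_output_power(3, 0.5, gamma = 2, x0 = x0)
#' x0[which.max(p)]              # close to dc_peak_input(3, 0.5)
dc_output_power <- function(n, F_adapt, gamma, x0) {
  if (length(n) != 1 || n < 1 || n != round(n))
    stop("`n` must be a whole number >= 1")
  if (F_adapt <= 0 || F_adapt >= 1) stop("`F_adapt` must lie in (0, 1)")
  if (gamma <= 0) stop("`gamma` must be positive")
  if (any(x0 < 0)) stop("`x0` must be non-negative")
  x0 * gamma^(2 * n) / (1 + x0 * F_adapt)^(4 * n)
}

#' Input level at which DC output power peaks
#'
#' Analytic maximizer of [dc_output_power()] over `x0`:
#' `x0* = 1 / (4nF - F)`.
#'
#' @inheritParams dc_output_power
#' @return The peak input `x0*`.
#' @export
dc_peak_input <- function(n, F_adapt) {
  if (length(n) != 1 || n < 1 || n != round(n))
    stop("`n` must be a whole number >= 1")
  if (F_adapt <= 0 || F_adapt >= 1)
    stop("`F_adapt` must lie in (0, 1): no finite peak otherwise")
  1 / (4 * n * F_adapt - F_adapt)
}

#' Shape an input PSD by a filter cascade
#'
#' Output PSD is `input_psd * |H|^2` with `H` the cascade response. A flat
#' input through a single low-pass stage yields the Lorentzian
#' `k^2 / (omega^2 tau^2 + 1)`.
#'
#' @param cascade A [filter_cascade()] object.
#' @param input_psd Non-negative input power per frequency, same length as
#'   `freqs`.
#' @inheritParams sfa_transfer
#' @return Output PSD per frequency.
#' @export
shaped_psd <- function(cascade, input_psd, freqs) {
  check_freqs(freqs)
  if (length(input_psd) != length(freqs))
    stop("`input_psd` and `freqs` must have the same length")
  if (any(input_psd < 0)) stop("`input_psd` must be non-negative")
  input_psd * Mod(cascade_response(cascade, freqs))^2
}

#' Log-log slope of a PSD over a frequency band
#'
#' Ordinary least-squares slope of `log10(power)` against `log10(f)`
#' restricted to `band`. For a fractional-differentiator cascade of order
#' `alpha` followed by one membrane low-pass, the mid-band slope is
#' approximately `-(2 - 2*alpha)`; a pure Lorentzian tail gives -2 and a
#' flat spectrum 0.
#'
#' @param psd Power per frequency (non-negative; zeros are dropped from the
#'   regression).
#' @param freqs Frequencies in Hz, strictly increasing and positive.
#' @param band Length-2 numeric `c(f_lo, f_hi)` in Hz; must contain at
#'   least 5 grid points. Default `c(0.1, 1)`, the low-to-midrange band
#'   where adaptation acts.
#' @return The slope (log10 power per log10 Hz).
#' @export
psd_slope <- function(psd, freqs, band = c(0.1, 1)) {
  check_freqs(freqs)
  if (length(psd) != length(freqs))
    stop("`psd` and `freqs` must have the same length")
  if (length(band) != 2 || band[1] >= band[2])
    stop("`band` must be c(f_lo, f_hi) with f_lo < f_hi")
  sel <- freqs >= band[1] & freqs <= band[2] & psd > 0
  if (sum(sel) < 5)
    stop("band contains fewer than 5 usable grid points")
  fit <- lm(log10(psd[sel]) ~ log10(freqs[sel]))
  unname(coef(fit)[2])
}
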