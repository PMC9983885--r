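# Conductance-based single neuron: Hodgkin-Huxley with three slow AHP
# currents, fixed-step RK4 integration, spike detection, firing rates.

#' Hodgkin-Huxley membrane parameters
#'
#' Standard squid-axon parameters: maximal conductances in mS/cm^2,
#' reversal potentials in mV, capacitance in uF/cm^2, integration step in
#' ms. Gating kinetics use the rest-shifted rate functions, so the resting
#' potential sits near -65 mV with `e_leak = -54.4` mV.
#'
#' @param g_na,g_k,g_leak Maximal Na+, K+, leak conductances (mS/cm^2).
#' @param e_na,e_k,e_leak Reversal potentials (mV).
#' @param c_m Membrane capacitance (uF/cm^2).
#' @param dt Integration time step (ms).
#' @return An object of class `hh_params`.
#' @export
hh_params <- function(g_na = 120, g_k = 36, g_leak = 0.3,
                      e_na = 50, e_k = -77, e_leak = -54.4,
                      c_m = 1, dt = 0.05) {
  if (any(c(g_na, g_k, g_leak) < 0)) stop("conductances must be >= 0")
  if (c_m <= 0) stop("`c_m` must be positive")
  if (dt <= 0) stop("`dt` must be positive (ms)")
  structure(list(g_na = g_na, g_k = g_k, g_leak = g_leak,
                 e_na = e_na, e_k = e_k, e_leak = e_leak,
                 c_m = c_m, dt = dt),
            class = "hh_params")
}

#' Slow AHP (adaptation) current set
#'
#' Three slow after-hyperpolarization currents implement spike-frequency
#' adaptation: each contributes `-G_j * a_j * (V - e_reversal)` to the
#' membrane equation, where `a_j` jumps by +1 at every spike and decays as
#' `da/dt = -a/tau_j`. Defaults follow the three-timescale parameterization
#' `tau = c(0.3, 1, 6)` s and `G_AHP = c(0.05, 0.006, 0.004) * G_Leak`;
#' `scale = 1` is the Low SFA condition, `scale = 5` High SFA, `scale = 0`
#' no adaptation. The reversal potential defaults to the K+ reversal
#' (-77 mV), these being slow potassium currents.
#'
#' @param taus Decay time constants in seconds.
#' @param g_ahp Maximal conductances in mS/cm^2 (same length as `taus`).
#' @param e_reversal Reversal potential in mV.
#' @param scale Non-negative multiplier on all conductances.
#' @return An object of class `ahp_set`.
#' @export
#' @examples
#' ahp_set(scale = 5)    # High SFA
#' ahp_set(scale = 0)    # adaptation off
ahp_set <- function(taus = c(0.3, 1, 6),
                    g_ahp = c(0.05, 0.006, 0.004) * 0.3,
                    e_reversal = -77, scale = 1) {
  if (any(taus <= 0)) stop("`taus` must be positive (seconds)")
  if (length(g_ahp) != length(taus))
    stop("`g_ahp` and `taus` must have the same length")
  if (any(g_ahp < 0)) stop("`g_ahp` must be non-negative")
  if (length(scale) != 1 || scale < 0) stop("`scale` must be >= 0")
  structure(list(taus = taus, g_ahp = g_ahp, e_reversal = e_reversal,
                 scale = scale),
            class = "ahp_set")
}

#' Helper for the named SFA conditions
#'
#' @param level `"none"`, `"low"` (scale 1), or `"high"` (scale 5).
#' @return An [ahp_set()] with the corresponding scale.
#' @export
ahp_for_level <- function(level = c("none", "low", "high")) {
  level <- match.arg(level)
  ahp_set(scale = c(none = 0, low = 1, high = 5)[[level]])
}

#' Spike train container
#'
#' @param times Spike times in seconds, strictly increasing, within
#'   `[0, duration]`.
#' @param duration Recording duration in seconds (> 0).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  if (length(duration) != 1 || duration <= 0)
    stop("`duration` must be positive (seconds)")
  if (length(times) > 0) {
    if (is.unsorted(times, strictly = TRUE))
      stop("spike `times` must be strictly increasing")
    if (times[1] < 0 || times[length(times)] > duration)
      stop("spike `times` must lie within [0, duration]")
  }
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("spike_train:", length(x$times), "spikes over", x$duration,
      "s (", signif(firing_rate(x), 4), "Hz )\n")
  invisible(x)
}

#' Simulate a Hodgkin-Huxley neuron with AHP currents
#'
#' Integrates the membrane equation
#' `C dV/dt = -I_Na - I_K - I_Leak - sum_j G_j a_j (V - E_AHP) + I(t)`
#' with standard gating kinetics by fixed-step fourth-order Runge-Kutta at
#' `hh$dt` (default 0.05 ms). The injected current is sampled on the `dt`
#' grid; half-step evaluations use the midpoint of the bracketing samples.
#' Spikes are detected online as upward crossings of `threshold` separated
#' by more than `min_separation`; at each detected spike every AHP variable
#' `a_j` is incremented by one. Integration starts from rest (-65 mV,
#' gating at steady state, `a = 0`). A voltage excursion beyond +/-200 mV
#' aborts with an error reporting the step.
#'
#' @param input Injected current trace in uA/cm^2, one sample per `dt`
#'   (e.g. from [generate_filtered_noise()]).
#' @param hh An [hh_params()] object.
#' @param ahp An [ahp_set()]; use `ahp_set(scale = 0)` or
#'   `ahp_for_level("none")` for no adaptation.
#' @param threshold Spike detection threshold in mV (default -10).
#' @param min_separation Minimum spike separation in ms (default 2).
#' @param keep_voltage Keep the full voltage trace (default `TRUE`; turn
#'   off for long population runs).
#' @return A list of class `hh_sim`: `spikes` (a [spike_train()]),
#'   `voltage` (mV trace, or `NULL`), `dt` (ms), `duration` (s), and
#'   `final_state` (named vector: `V`, gating `m`/`h`/`n` in `[0, 1]`, and
#'   one AHP variable per active timescale).
#' @export
#' @examples
#' x <- generate_filtered_noise(noise_input(sd = 2, duration = 2, seed = 1))
#' sim <- simulate_neuron(x, ahp = ahp_for_level("none"))
#' firing_rate(sim$spikes)
simulate_neuron <- function(input, hh = hh_params(), ahp = ahp_set(),
                            threshold = -10, min_separation = 2,
                            keep_voltage = TRUE) {
  stopifnot(inherits(hh, "hh_params"), inherits(ahp, "ahp_set"))
  if (!is.numeric(input) || length(input) < 2)
    stop("`input` must be a numeric trace with at least 2 samples")
  g <- ahp$scale * ahp$g_ahp
  keep <- ahp$scale > 0
  res <- hh_simulate_cpp(input, hh$dt,
                         c(hh$g_na, hh$g_k, hh$g_leak,
                           hh$e_na, hh$e_k, hh$e_leak, hh$c_m),
                         if (keep) g else numeric(0),
                         if (keep) ahp$taus else numeric(0),
                         ahp$e_reversal, threshold, min_separation,
                         keep_voltage)
  duration <- (length(input) - 1) * hh$dt / 1000
  times <- res$spike_index * hh$dt / 1000
  fs <- res$final_state
  names(fs) <- c("V", "m", "h", "n",
                 if (keep) paste0("a", seq_along(ahp$taus)))
  structure(list(spikes = spike_train(times, duration),
                 voltage = if (keep_voltage) res$voltage else NULL,
                 dt = hh$dt, duration = duration, final_state = fs),
            class = "hh_sim")
}

#' Detect spikes in a voltage trace
#'
#' A spike is an upward crossing of `threshold` (previous sample below, the
#' current sample at or above). Crossings closer than `min_separation` to
#' the last accepted spike are discarded, so the earlier crossing wins.
#'
#' @param voltage Voltage trace in mV, uniformly sampled.
#' @param dt Sample step in ms.
#' @param threshold Threshold in mV (default -10).
#' @param min_separation Minimum separation in ms (default 2).
#' @return A [spike_train()] (times in seconds).
#' @export
detect_spikes <- function(voltage, dt, threshold = -10, min_separation = 2) {
  if (!is.numeric(voltage) || length(voltage) < 2)
    stop("`voltage` must be a numeric trace with at least 2 samples")
  if (dt <= 0) stop("`dt` must be positive (ms)")
  n <- length(voltage)
  up <- which(voltage[-1] >= threshold & voltage[-n] < threshold)
  t_ms <- up * dt   # crossing at sample index up + 1, time (up+1-1)*dt
  keep <- numeric(0)
  last <- -Inf
  for (tt in t_ms) {
    if (tt - last > min_separation) {
      keep <- c(keep, tt)
      last <- tt
    }
  }
  spike_train(keep / 1000, (n - 1) * dt / 1000)
}

#' Mean firing rate of a spike train
#'
#' @param s A [spike_train()].
#' @return Rate in Hz (`count / duration`).
#' @export
firing_rate <- function(s) {
  stopifnot(inherits(s, "spike_train"))
  if (s$duration <= 0) stop("duration must be positive")
  length(s$times) / s$duration
}
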