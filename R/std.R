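# Two-timescale short-term synaptic depression: per-spike multiplicative
# depression of a fast (d) and a slow (D) resource variable, exponential
# recovery toward 1 between spikes, conductance amplitude G = d * D.

#' Short-term depression parameters
#'
#' Each presynaptic spike multiplies the fast variable `d` by `f_d` and the
#' slow variable `D` by `f_D`; between spikes both relax exponentially back
#' to 1 with time constants `tau_d` (0.6 s) and `tau_D` (9 s). The
#' canonical conditions are High STD (`f_d = 0.4`, `f_D = 0.995`) and Low
#' STD (`f_d = 0.7`, `f_D = 0.999`). `filter_tau` is the time constant of
#' the exponential kernel used when amplitudes are turned into a continuous
#' signal ([amplitudes_to_signal()]).
#'
#' @param level `"high"` or `"low"`, selecting the canonical factor pairs;
#'   ignored when `f_d`/`f_D` are given explicitly.
#' @param f_d Per-spike factor for the fast variable, in `(0, 1]`.
#' @param f_D Per-spike factor for the slow variable, in `(0, 1]`.
#' @param tau_d,tau_D Recovery time constants in seconds.
#' @param filter_tau Output filter time constant in seconds.
#' @return An object of class `std_params`.
#' @export
#' @examples
#' std_params("high")
#' std_params(f_d = 0.5, f_D = 0.99)
std_params <- function(level = c("high", "low"), f_d = NULL, f_D = NULL,
                       tau_d = 0.6, tau_D = 9, filter_tau = 0.3) {
  if (is.null(f_d) || is.null(f_D)) {
    level <- match.arg(level)
    if (is.null(f_d)) f_d <- c(high = 0.4, low = 0.7)[[level]]
    if (is.null(f_D)) f_D <- c(high = 0.995, low = 0.999)[[level]]
  }
  if (f_d <= 0 || f_d > 1) stop("`f_d` must lie in (0, 1]")
  if (f_D <= 0 || f_D > 1) stop("`f_D` must lie in (0, 1]")
  if (tau_d <= 0 || tau_D <= 0 || filter_tau <= 0)
    stop("time constants must be positive (seconds)")
  structure(list(f_d = f_d, f_D = f_D, tau_d = tau_d, tau_D = tau_D,
                 filter_tau = filter_tau),
            class = "std_params")
}

#' Per-synapse depression state
#'
#' @param d Fast depression variable in `(0, 1]` (1 = fully recovered).
#' @param D Slow depression variable in `(0, 1]`.
#' @param t_last Time of the last spike in seconds (`-Inf` for a rested
#'   synapse).
#' @return An object of class `depression_state`.
#' @export
depression_state <- function(d = 1, D = 1, t_last = -Inf) {
  if (d <= 0 || d > 1 || D <= 0 || D > 1)
    stop("`d` and `D` must lie in (0, 1]")
  structure(list(d = d, D = D, t_last = t_last), class = "depression_state")
}

#' Advance a depressing synapse to the next spike
#'
#' Recovery first, then depression: over the interval since the previous
#' spike both variables relax toward 1,
#' `d_pre = 1 - (1 - d) * exp(-dt/tau_d)` (likewise `D` with `tau_D`); the
#' conductance amplitude released by the spike is `G = d_pre * D_pre`
#' (resources available at spike arrival, read before the spike's own
#' depression); the spike then depresses the variables to `f_d * d_pre`
#' and `f_D * D_pre`.
#'
#' @param state A [depression_state()].
#' @param spike_time Time of the incoming spike in seconds; must exceed
#'   `state$t_last`.
#' @param params An [std_params()] object.
#' @return A list with `pre` (state at spike arrival), `post` (state after
#'   depression), and `amplitude`.
#' @export
#' @examples
#' st <- depression_state()
#' propagate(st, 0, std_params("high"))$amplitude   # 1: rested synapse
propagate <- function(state, spike_time, params) {
  stopifnot(inherits(state, "depression_state"),
            inherits(params, "std_params"))
  if (spike_time <= state$t_last)
    stop("spike times must be strictly increasing")
  dt <- spike_time - state$t_last
  d_pre <- 1 - (1 - state$d) * exp(-dt / params$tau_d)
  D_pre <- 1 - (1 - state$D) * exp(-dt / params$tau_D)
  amp <- d_pre * D_pre
  list(pre = depression_state(d_pre, D_pre, state$t_last),
       post = depression_state(params$f_d * d_pre, params$f_D * D_pre,
                               spike_time),
       amplitude = amp)
}

#' Per-spike amplitude container
#'
#' @param times Spike times in seconds.
#' @param amplitudes Conductance amplitudes `G = d * D`, in `(0, 1]`, same
#'   length as `times`.
#' @return An object of class `amplitude_train`.
#' @export
amplitude_train <- function(times, amplitudes) {
  if (length(times) != length(amplitudes))
    stop("`times` and `amplitudes` must have the same length")
  if (length(times) > 1 && is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing")
  if (length(amplitudes) > 0 &&
      (any(amplitudes <= 0) || any(amplitudes > 1)))
    stop("`amplitudes` must lie in (0, 1]")
  structure(list(times = as.numeric(times),
                 amplitudes = as.numeric(amplitudes)),
            class = "amplitude_train")
}

#' Run a spike train through a depressing synapse
#'
#' Sequentially applies [propagate()] from the rested state
#' (`d = D = 1`), returning the conductance amplitude of every spike.
#' Amplitudes along a constant-rate train decrease monotonically to the
#' steady-state fixed point; lower depression factors (High STD) give
#' uniformly smaller amplitudes than higher ones (Low STD).
#'
#' @param params An [std_params()] object.
#' @param spikes A [spike_train()] (or numeric vector of times in
#'   seconds).
#' @return An [amplitude_train()].
#' @export
#' @examples
#' tr <- spike_train(seq(0.1, 2, by = 0.1), duration = 2)
#' run_train(std_params("high"), tr)$amplitudes
run_train <- function(params, spikes) {
  stopifnot(inherits(params, "std_params"))
  times <- if (inherits(spikes, "spike_train")) spikes$times
           else as.numeric(spikes)
  if (length(times) > 1 && is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  n <- length(times)
  amps <- numeric(n)
  # inlined propagate() recursion (hot path for long population runs)
  d <- 1; D <- 1; t_last <- -Inf
  for (i in seq_len(n)) {
    gap <- times[i] - t_last
    d <- 1 - (1 - d) * exp(-gap / params$tau_d)
    D <- 1 - (1 - D) * exp(-gap / params$tau_D)
    amps[i] <- d * D
    d <- params$f_d * d
    D <- params$f_D * D
    t_last <- times[i]
  }
  amplitude_train(times, amps)
}

#' Sum amplitude trains into a filtered continuous signal
#'
#' Places each amplitude as an impulse of height `G_i` at its spike time,
#' sums impulses across neurons, and convolves with the causal exponential
#' kernel `exp(-t/filter_tau)`. This summed, filtered synaptic amplitude
#' signal is the LFP proxy of the population model. The operation is linear
#' in its inputs: the signal of a union of trains equals the sum of the
#' individual signals.
#'
#' @param trains A single [amplitude_train()] or a list of them.
#' @param filter_tau Kernel time constant in seconds (default 0.3).
#' @param dt Output sample step in seconds (e.g. 0.005 for 200 Hz).
#' @param duration Output duration in seconds; all spikes must lie in
#'   `[0, duration]`.
#' @return A [sampled_signal()] on `seq(0, duration, by = dt)`.
#' @export
#' @examples
#' a <- amplitude_train(0, 1)
#' s <- amplitudes_to_signal(a, dt = 0.01, duration = 1)
#' all.equal(s$values, exp(-s$t / 0.3))
amplitudes_to_signal <- function(trains, filter_tau = 0.3, dt, duration) {
  if (inherits(trains, "amplitude_train")) trains <- list(trains)
  ok <- all(vapply(trains, inherits, logical(1), "amplitude_train"))
  if (!ok) stop("`trains` must be amplitude_train objects")
  if (dt <= 0 || duration <= 0) stop("`dt` and `duration` must be positive")
  n <- floor(duration / dt) + 1
  imp <- numeric(n)
  for (tr in trains) {
    if (length(tr$times) == 0) next
    if (any(tr$times < 0) || any(tr$times > duration))
      stop("spike times outside [0, duration]")
    idx <- pmin(floor(tr$times / dt) + 1, n)
    for (k in seq_along(idx)) imp[idx[k]] <- imp[idx[k]] + tr$amplitudes[k]
  }
  lam <- exp(-dt / filter_tau)
  out <- as.numeric(stats::filter(imp, lam, method = "recursive"))
  sampled_signal(seq(0, by = dt, length.out = n), out)
}
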