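---
title: "Multi-timescale adaptation, fractional dynamics, and the shape of field-potential spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-timescale adaptation, fractional dynamics, and the shape of field-potential spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(adaptfrac)
```

## The model

Neural circuits are saturated with negative feedback. Spike-frequency
adaptation (SFA) slows action-potential generation under sustained drive;
short-term synaptic depression (STD) weakens synapses that are used
heavily. Both are differentiators: they emphasize stimulus *change* and
attenuate steady state. `adaptfrac` implements a two-level account of how
such adaptation shapes the power spectral density (PSD) of field-potential
signals (LFP/EEG), whose generators are dominated by summed postsynaptic
potentials.

**Level 1 — linear filters.** A single adaptive mechanism is a first-order
high-pass stage

$$H(s) = g\,\frac{\tau s + 1}{\tau s + A}, \qquad A \ge 1,$$

with DC gain $g/A$ below the high-frequency gain $g$; membrane integration
is a low-pass stage $k/(\tau_m s + 1)$. Mechanisms in series multiply in
the frequency domain (`filter_cascade()`, `cascade_response()`). The SFA
rate model ($y = \gamma x - c\,a$, $\tau \dot a = -a + F y$) and the
small-signal linearization of depression ($y = \gamma x a$,
$\tau \dot a = 1 - a - xFa$) both reduce to this form (`sfa_transfer()`,
`std_linear_transfer()`); depression differs in one crucial way: its gain
carries the operating point, $\gamma/(1 + x_0 F)$, so more steady drive
means less gain. For $n$ identical depression timescales the DC output
power is $x_0\gamma^{2n}/(1 + x_0 F)^{4n}$ (`dc_output_power()`), which
rises, peaks at $x_0^\ast = 1/(4nF - F)$ (`dc_peak_input()`), and then
falls — the non-monotonicity behind "more input, less power".

**Level 2 — a conductance-based population.** Hodgkin–Huxley neurons with
three slow AHP currents (SFA) drive two-timescale depressing synapses; the
summed, exponentially filtered conductance amplitudes are the LFP proxy
(`run_network()`), analyzed with Welch PSDs (`welch_psd()`). The spiking
route reproduces the filter-level predictions without linearization.

## Why "fractional"

Biological adaptation never has one timescale. A power law $t^{-k}$ is a
balanced continuum of exponentials,
$t^{-k} = \Gamma(k)^{-1}\int_0^\infty \lambda^{k-1}e^{-\lambda t}
\,d\lambda$ (`gamma_superposition()`), and a system whose transfer
function is $(i\omega)^\alpha$ — a *fractional differentiator* of order
$\alpha$ — responds to a step with a power law. Its signature is a
frequency-independent phase advance $\alpha\pi/2$ (`frac_phase()`,
`frac_transfer()`). Three high-pass stages with well-separated timescales
(0.05, 0.5, 5 s) and balanced gain constants approximate this constant
phase over roughly 0.05–5 Hz; `fit_gains_constant_phase()` finds the gains
by Nelder–Mead minimization of the squared phase deviation. In the PSD,
the fractional cascade in front of a membrane low-pass turns the
Lorentzian $-2$ tail into a mid-band slope of approximately
$-(2 - 2\alpha)$ (`psd_slope()`): adaptation *flattens* low-frequency
spectra.

The time-domain operator itself is available as
`fractional_derivative()`, the Grünwald–Letnikov discretization of the
Riemann–Liouville integral. It is non-local — the output at $t$ weighs the
whole history since $t_0$ — which is the mechanistic content of "history
dependence".

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `taus` (fit) | 0.05, 0.5, 5 | s | adaptation timescales, one per decade |
| `band` (fit) | 0.05–5 | Hz | where the phase is held constant |
| `alpha` | 0–1 | — | fractional order; 0.1–0.5 is the physiological range |
| HH conductances | 120 / 36 / 0.3 | mS/cm² | standard squid-axon set, rest at −65 mV |
| AHP `taus` | 0.3, 1, 6 | s | slow K⁺ current decay times |
| AHP `g_ahp` | (0.05, 0.006, 0.004)·G_Leak | mS/cm² | ×1 = Low SFA, ×5 = High SFA |
| noise `sd` | condition-dependent | µA/cm² | SD of the filtered injected current |
| `tau_filter` | 1 | ms | stimulus autocorrelation time |
| STD `f_d`, `f_D` | 0.4, 0.995 (High); 0.7, 0.999 (Low) | — | per-spike depression factors |
| STD `tau_d`, `tau_D` | 0.6, 9 | s | recovery time constants |
| `filter_tau` | 0.3 | s | LFP-proxy smoothing kernel |
| Welch | 20 s Hann, 50 % overlap, 200 Hz | — | resolves 0.05 Hz; ≥14 segments at 300 s |

### The input calibration

The three input conditions are specified by nominal noise SDs of 10, 15,
and 20 µA/cm², and the no-adaptation neuron must fire at roughly 1, 10,
and 20 Hz under them. Injecting Ornstein–Uhlenbeck current with those SDs
literally drives the standard Hodgkin–Huxley neuron far harder than that
(tens of Hz even at the lowest level: with a 1 ms correlation time, a
10 µA/cm² SD produces ~10 mV voltage fluctuations against a ~10 mV
threshold distance). A single gain of 0.1 applied to the nominal SDs —
injected SDs of 1.0, 1.5, 2.0 µA/cm² — reproduces the target rates
(0.7 / 8.2 / 18.8 Hz at 100 s × 3 seeds), consistent with a tenfold units
convention in the nominal values. This calibration constant is exposed as
`condition_noise_sd(level, scale = 0.1)` and was fixed once, against the
printed rates, before any spectral experiment was run. Verified behavior
at this operating point: the lag-1 ms autocorrelation is $e^{-1}$, halving
`dt` changes 10-s spike counts by <2 %, and an independent `lsoda`
integration of the same equations reproduces the RK4 spike times.

### The depression recursion

The printed per-spike recursions for the depression variables are not
self-consistent (the slow-variable update drops its own previous value,
and taken literally both variables decay to zero rather than recovering
toward one). `adaptfrac` implements the canonical
multiplicative-depression model the prose describes: between spikes, `d`
and `D` relax exponentially *toward 1* with time constants 0.6 s and 9 s;
at each spike, the released amplitude is read *first* ($G = dD$, the
resources present at spike arrival) and the variables are then multiplied
by their per-spike factors. Reading the amplitude pre-depression (rather
than post) is the package's choice where the order is ambiguous; it makes
a rested synapse release amplitude 1 exactly.

## Numerical choices

* **Integration.** Fixed-step RK4 at dt = 0.05 ms, stimulus sampled on the
  grid and linearly interpolated at half steps (midpoint of the two
  bracketing samples). Gating variables are clamped to [0, 1] *inside* the
  derivative evaluation: below about −113 mV, $\beta_m$ exceeds the RK4
  stability limit at this step size, and unclamped mid-step stage values
  can leave the unit interval where $m^3$ fabricates an unphysical Na⁺
  current. Clamping bounds the right-hand side on the physical manifold
  and leaves the solution inside it untouched. Gating rate functions are
  tabulated at 0.01 mV resolution with linear interpolation (error ~1e−9,
  several-fold faster for population runs).
* **Spike handling.** Upward crossings of −10 mV separated by >2 ms; the
  earlier crossing wins. AHP increments are applied at the detection
  sample, once per spike.
* **Constant-phase fit.** 50 log-spaced frequencies on the band; objective
  is the summed squared phase deviation; the reported `residual` is the
  maximum absolute deviation. The substitution $A = 1 + e^u$ keeps the
  nominally unconstrained simplex search inside $A > 1$; initialization is
  $A_0 = 1 + \alpha$ (the small-$\alpha$ limit has $A \to 1$). The
  per-stage search starts from the shared optimum and the better solution
  by reported residual is kept, so per-stage never degrades on shared.
* **Fractional derivative.** Grünwald–Letnikov binomial weights, FFT
  convolution, signals assumed zero before their first sample. First-order
  accurate in the step; the semigroup identity
  $D^\alpha D^{1-\alpha} = D^1$ holds exactly in the discrete scheme.
* **Quadrature.** The superposition integral has an integrable endpoint
  singularity for $k < 1$; the substitution $\lambda = u^{1/k}$ removes it
  before adaptive quadrature (relative error ≲ 1e−10 across
  $k \in [0.1, 0.9]$, $t \in [0.1, 10]$).
* **Step responses.** Single stages use closed forms; cascades use exact
  zero-order-hold updates per stage on the uniform grid (exact for step
  inputs).
* **Welch.** Periodic Hann window, overall mean removed, DC bin dropped,
  one-sided density scaling; integrated power matches signal variance to
  within ~5 %.
* **Degenerate limits.** $F \to 0$, $c \to 0$, $x_0 \to 0$, $A \to 1$, and
  $\alpha \to 0$ all reduce to pure gains/identities and are tested
  explicitly.

## Design decisions that were genuinely open

* **One `F` per mechanism class.** The multi-timescale examples share a
  single adaptation fraction across timescales, matching the reference
  parameterizations; per-stage values remain available through explicit
  stage lists.
* **Shared-mode optimizer.** With one shared gain the fit is
  one-dimensional; Nelder–Mead is retained (with its 1-D caveat
  suppressed) for uniformity with the per-stage fit rather than switching
  algorithms between modes.
* **AHP reversal.** The adaptation currents are slow potassium currents,
  so their reversal is set to $E_K = -77$ mV.
* **Population wiring.** Purely feedforward, one depressing synapse per
  neuron, independent noise per neuron (seeds `base_seed + i`). A
  `shared_noise_frac` option mixes in a common source for correlation
  studies but defaults to 0, since no cross-neuron correlation is part of
  the reference configuration.
* **Crossing detection.** Condition PSDs are compared as band powers
  (0.01–1, 1–10, 30–50 Hz and a 0.01–50 Hz broadband); the crossing
  frequency is the first sign change of the (optionally smoothed) log
  power ratio.

## What the synthetic data does and does not emulate

Everything here is generated: OU currents, Poisson presynaptic trains,
and spiking populations. These capture the mechanisms under study —
noise-driven threshold crossing, spike-triggered adaptation, per-spike
depression — under stationary drive. They do **not** contain oscillatory
rhythms, up/down state transitions, measurement noise, volume conduction,
or non-stationary arousal effects, all present in clinical recordings.
Passing tests therefore demonstrate that the *mechanistic link* from
adaptation to spectral shape behaves as derived, not that any particular
recorded PSD is explained.

## Problem sizes

Module tests run seconds-scale simulations. The end-to-end spectral
checks use populations of 16 neurons for 300 s (10 s burn-in), three
seeds per condition, chosen as the smallest configuration that cleanly
resolves the 0.05–1 Hz band (≥14 Welch segments of 20 s) and the 9 s slow
depression timescale while keeping a full grid of conditions at desk
scale. Firing-rate calibrations use 100 s × 3 seeds. Because neurons are
independent, band-power *orderings* across conditions stabilize quickly
with population size; absolute powers scale with it.

## Known limitations

* The linearized STD filter is valid for small fluctuations about the
  operating point; large-signal behavior lives only in the spiking route.
* The GL fractional derivative is first-order accurate; very small
  $\alpha$ on short grids inherits the scheme's slow convergence near
  $t = 0$.
* The LFP proxy sums synaptic amplitudes directly; no postsynaptic
  membrane integration or dendritic filtering beyond the single
  exponential kernel.
* Fixed-step RK4 with online spike detection means spike times are
  quantized at dt = 0.05 ms.
* The conductance-based population is feedforward; recurrent excitation
  and inhibition, and hence network oscillations, are out of scope.
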