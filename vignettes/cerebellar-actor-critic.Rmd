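---
title: "A spiking cerebellar actor-critic: model, parameters, and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking cerebellar actor-critic: model, parameters, and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`cerac` implements the cerebellar cortical microcircuit as an
actor-critic reinforcement learner in continuous time, discretized at
1 ms. The mapping of circuit elements to algorithmic roles is:

| circuit element | count (defaults) | algorithmic role |
|---|---|---|
| parallel fibers (PF) | 32,400 (324 tiles × 100) | state encoding `s(t)` |
| stellate cells (SC) | 324 (1 per tile) | critic: `−V(t)` via population activity |
| basket cells (BC) | 324, 2 action groups | winner-take-all competition |
| Purkinje cells (PC) | 20, 2 action groups | actor: avoidance `h̄_α(t)` |
| deep nuclei (DCN) | 20, one per PC | action preference `h_α(t)`, argmax → action |
| climbing fiber (CF) | 1 | negative reward `CF(t) = −r̄·S_CF(t)` |

## State encoding

The 2-D state space is discretized into an `nx × ny` grid of tiles plus
a `margin`-tile frame. The PFs of the tile with responsible state
`o_ij` fire as an inhomogeneous Poisson generator with rate
`ρ_PF/(2πσ²)·exp(−‖o(t)−o_ij‖²/(2σ²))`. Distances are measured in
**tile units** (the observation is affinely mapped so one tile has unit
pitch per axis) — in raw task units a fixed `σ = 0.5` would make the
receptive field's extent depend on the axis scaling and degenerate for
the mountain-car velocity axis (range 0.14). A config switch records
this choice (`plane$receptive_field_units`).

The margin frame exists to keep the summed PF drive approximately
state-independent: without it the total rate at a corner of the state
range collapses to ~24% of its interior value; with one margin tile it
stays above 90%. Note that even on an infinite lattice the summed
Gaussian drive ripples by ~5.8% peak-to-peak at `σ = 0.5` tile units
(Poisson summation, `2·exp(−2π²σ²) ≈ 1.45%` per axis), so "constant
total drive" can only ever hold to that accuracy.

## Neurons and synapses

SC/BC/PC are leaky integrate-and-fire neurons,
`Cm·du/dt = −gL(u−EL) + I_syn + I_ext + I_noise`, threshold −55 mV,
spike-and-reset, no refractory period. The published parameter table
lists `gL` in mS; with `Cm` in pF that yields microsecond membrane time
constants, inconsistent with every other printed unit, so the package
reads nS (`τ_m = Cm/gL ≈ 46 ms`). The noise current follows
`dI/dt = −I/τ_noise + ζ·n(t)` with `n(t)` uniform on [−1,1], redrawn
every step; `τ_noise` is unpublished (default 10 ms).

A worthwhile detail: with the published `Iext = 30 pA` the SC/BC
subthreshold fixed point is `EL + Iext/gL = −55.069 mV` — 0.07 mV
*below* threshold. Baseline SC firing is therefore entirely
noise-driven; with `ζ = 5 pA` the spontaneous rate comes out at a few
tens of Hz at most, and the population-mean SC rate in a running
network is ~10 Hz, consistent with the published value baseline
(`V0/ν = 12.4 Hz`, see below).

Synaptic currents are exponentially filtered spike trains per
connection type, `I_syn = Σ_c s_c·w_ij·I_ij`, with the scaling factor's
sign deciding excitation/inhibition. The wiring follows the published
table (probabilities per candidate pair); BC–BC and PC–PC connect
*cross-group* only (the mutual "self-inhibition" of the two rings, with
no autapses), BC–PC and PC–BC *same-group* only, and each SC receives
PF input from its own tile row ±1 across the full width of the plane.
Current filters are maintained per (connection type, postsynaptic
neuron) — mathematically identical to per-synapse filters when `τ_c` is
shared within a type, and much cheaper.

## Plasticity without an explicit TD error

Each plastic synapse (PF–SC and PF–PC only) carries an STDP-window
trace `κ` (incremented by presynaptic spikes, decaying with
`τ_κ = 20 ms`, read out as the coincidence term `f = S_post·κ` and
reset at postsynaptic spikes) and an eligibility trace `z`
(`dz/dt = −z/τ_z + f`, `τ_z = 20 ms`). The episode weight change is

    PF–SC: d(Δw)/dt = +CF·z − c·V·z + V·f
    PF–PC: d(Δw)/dt = −CF·z + c·V·z − V·f,   c = (τr−τz)/(τr·τz) = 0.04/ms

applied once at episode end as `w ← clip(w + η·Δw, 0, 1)`. Integrating
by parts shows these are exactly eligibility-propagated TD rules: for
the actor, `Δw = ∫(R + V̇ − V/τ_r)·z dt − [V·z]`, i.e. the TD error
with discount time constant `τ_r` — but no circuit element ever
computes that error; it is absorbed into locally measurable quantities
(CF spikes, the instantaneous value readout `V`, and per-synapse
traces). The critic rule is the exact sign-flip because SCs represent
`−V`.

# Parameters and their provenance

Published values (used as-is): all LIF constants; the per-connection
scaling factors, decay constants and wiring probabilities; `ρ_PF = 50`,
`σ = 0.5`, grid 16×16, 100 PFs/tile; `ν = 200`, `V0 = 2.48`;
`τ_κ = τ_z = 20 ms`, `τ_r = 100 ms`; mountain car `F̄ = 0.001`,
`g = 0.0025`, `ν̄ = 5 Hz`, `r̄ = −5`, 10 runs × 1000 episodes,
`η = 0.4/0.4`, `w0 = 0.05/0.8`; eyeblink US at 500 ms, CR threshold
0.1, closing speed 0.01/ms, 10 runs × 500 episodes, `η = 0.05/0.3`,
`w0(PF–PC) = 0.8 (anticlose) / 0.7 (antiopen)`.

Package choices (unpublished; fixed once, config-exposed):

- **Value/actor readout filters, `τ_rise = 2 ms`, `τ_decay = 20 ms`.**
  The double-exponential activity filter is normalized so its
  steady-state mean equals the firing rate in 1/ms regardless of the
  taus (hence `V0 = 2.48 ⇔` mean SC rate 12.4 Hz is τ-independent, and
  the published calibration transfers). The *decay* constant, however,
  sets how stale the value estimate `V(t)` is when it enters the
  plasticity rules. The TD identity above treats `V` as instantaneous;
  empirically, a readout lag (50 ms) much longer than the printed
  eligibility timescale (20 ms) makes both tasks acquire and then lose
  their behavior, whereas matching the readout decay to `τ_z = τ_κ =
  20 ms` yields the stable acquisition the source describes. We
  consider 20 ms the only choice consistent with the published
  plasticity constants; it is the package default.
- **Margin width 1** — forced by the published SC count, 324 = (16+2)².
- **DCN dynamics** `τ_DCN = 10 ms`, baseline 1, scaling 1, rate
  equation `dDCN/dt = −(DCN−DCN0)/τ − ν·PC(t)`, floored at 0. Under
  group symmetry the argmax over DCN group means equals the argmin over
  PC avoidance at steady state (the fixed point is affine-decreasing in
  PC activity), so action selection is insensitive to these three
  numbers; the property is tested on randomized activity vectors.
- **Mountain car**: goal 0.5 and start (−0.5, 0) (classic values;
  unpublished); **eyeblink**: initial eyelid 1.0 (fully open),
  PF–SC `w0 = 0.05` (the mountain-car value; unpublished for this
  task); `τ_noise = 10 ms`.

Two printed formulas required correction against their own surrounding
text, both behind config switches: the mountain-car velocity equation
(printed with an unstable `+vx` term; implemented as the classic
discrete update `vx ← vx + F̄·a − g·cos(3px)` per 1-ms step) and the CF
rate (the printed form peaks *at the goal*, contradicting "fired when
the car was far from the goal and the speed was slow"; the default
`cf_rate_form = "text"` uses
`ν̄·((p_goal−px)/(p_goal−p_wall))·(1−|vx|/v_max)`, the printed literal
form remains available).

# Numerical conventions

- **Grid.** Forward Euler at `dt = 1 ms` for the membrane equation (as
  published); *exact* exponential decay factors (exponential
  integrator) for every linear filter and trace (`κ`, `z`, synaptic and
  activity filters, noise decay, DCN relaxation). For these linear
  systems the exponential factor is the analytically exact one-step
  map, so e.g. the double-exponential filter impulse response matches
  the closed form at machine precision at every sampled time.
- **Delta functions.** On the grid, CF·z and V·f enter `Δw` dt-free at
  spike steps (a CF spike contributes `(−r̄)·z`); the smooth `c·V·z`
  term carries `dt`. Within a step the order is: trace decay → presyn
  increments (a same-step pre spike is visible to a same-step post
  spike) → coincidence readout, `z += f`, κ reset → `Δw` accumulation
  with that step's `V` and CF. Spikes emitted at step `t` reach
  downstream synaptic currents from step `t+1`.
- **Dual-route integrity.** The per-step ("dense") R implementations of
  the traces, currents and environments define these semantics. The
  compiled engine integrates the same dynamics event-drivenly — per
  postsynaptic neuron it maintains epoch integrals
  `E = e^{−Δt/τz}`, `J = Σ g_k e^{−(k−t_spike)/τz}` and composes them
  lazily per synapse, touching a synapse only at its own pre/post spike
  events — and is required by the test suite to agree with the dense
  oracle to ≤1e−9 relative error on random spike trains (it agrees to
  ~1e−15), and to reproduce the R environments trajectory-for-
  trajectory.
- **Ties and clamps.** Action ties break toward the lowest action
  index. Observations are clamped to the state range before encoding;
  eyelid position to [0,1]; car position/velocity to their ranges, with
  a wall collision zeroing the velocity without any reward event.
  PF tiles whose per-step spike probability is below 1e−12 are skipped
  without consuming RNG draws.
- **Reproducibility.** All randomness flows through R's RNG, including
  inside the compiled engine; `(seed, config)` determines every
  adjacency, spike and weight bit-for-bit. Training derives
  counter-based per-run seeds so each run is independently
  re-executable.

# The episode protocol and success metrics

Each episode runs 200 ms of free dynamics with PFs encoding the initial
observation (traces and `Δw` start only afterwards, discarding onset
transients), a main phase of up to 1,000 ms (terminated early at the
mountain-car goal), and a 100 ms tail with PFs silenced during which
`Δw` keeps integrating; weights update once at the very end. Success is
goal-reached (mountain car) or `pe(500 ms) ≤ 0.1` (eyeblink). Learning
curves use a window-10 moving average per run, then the cross-run mean.

For the eyeblink ablation, two closing-time statistics are recorded:
`first_close`, the first down-crossing of the 0.1 threshold, and
`close_onset`, the onset of the final closed stretch that persists
through the US (NA if the lid is open at the US). The first crossing is
misleading for ablated runs, which close transiently and reopen before
the US — their first crossing is *earlier* than intact runs' while
their effective closure is delayed or absent, which is what
`close_onset` captures; the directional ablation check uses it, and
both are reported.

# What the synthetic tasks establish — and what they do not

Both environments are *stated worlds*: closed-form dynamics at the
published parameters, not recorded data. A green learning test
establishes that the full pipeline — Poisson encoding, LIF circuit
dynamics, trace-based plasticity, DCN action selection — solves the
tasks with the published protocol under this package's choices for the
unpublished constants. It does not establish biological parameter
realism (e.g. BC rates here run high), robustness to task
perturbations, or behavior outside the two-action discrete regime. The
acceptance suite runs a scaled-down replication (2–3 runs instead of
10) with the published episode counts and the published tolerance
bands; run-count reduction widens the sampling error of the measured
rates but leaves the bands untouched.

# Known limitations

- Two discrete actions only; no population-vector / continuous action
  coding (explicitly out of scope for this model).
- CF carries spikes with a fixed amplitude; no graded CF signaling.
- PFs are memoryless Poisson generators; no granule-layer dynamics,
  single CF/microzone, no conductance-based synapses, no refractoriness,
  no sub-step spike timing.
- The supplementary linear-track protocol of the source is not
  implemented (its equations are not in the available text).
- Long simulations keep all per-synapse traces in memory (~0.5M
  synapses at defaults, a few tens of MB); very large planes would need
  a sparser critic wiring.
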