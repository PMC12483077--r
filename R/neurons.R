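#' Leaky integrate-and-fire neuron parameters
#'
#' Validated constructor for one population's membrane constants.
#' Capacitance in pF, conductance in nS, potentials in mV, currents in pA,
#' time constants in ms, so that `tau_m = Cm / gL` is in ms.
#'
#' @param Cm membrane capacitance (pF).
#' @param gL leak conductance (nS).
#' @param EL resting potential (mV).
#' @param Uth spike threshold (mV).
#' @param Ureset post-spike reset potential (mV).
#' @param Iext constant external current (pA).
#' @param zeta noise-current amplitude (pA).
#' @param tau_noise noise-current relaxation time (ms).
#' @return list of class `lif_params`.
#' @export
lif_params <- function(Cm, gL, EL, Uth, Ureset, Iext = 0, zeta = 0,
                       tau_noise = 10) {
  stopifnot(Cm > 0, gL > 0, tau_noise > 0, Ureset < Uth)
  structure(list(Cm = Cm, gL = gL, EL = EL, Uth = Uth, Ureset = Ureset,
                 Iext = Iext, zeta = zeta, tau_noise = tau_noise),
            class = "lif_params")
}

#' @rdname lif_params
#' @param config a [cerac_config()].
#' @param population `"SC"`, `"BC"` or `"PC"`.
#' @export
lif_params_from_config <- function(config, population) {
  do.call(lif_params, config$neurons[[population]])
}

#' Initialize LIF population state
#'
#' @param n number of neurons.
#' @param params a [lif_params()] object.
#' @return list with `u` (membrane potentials, initialized at `EL`),
#'   `I_noise` (pA, zeros) and `spiked` (logical).
#' @export
lif_init <- function(n, params) {
  list(u = rep(params$EL, n), I_noise = rep(0, n), spiked = rep(FALSE, n))
}

#' One forward-Euler step of a LIF population
#'
#' Updates the membrane with leak, synaptic, external and noise currents;
#' neurons reaching threshold emit a spike and are reset to `Ureset` within
#' the same step (no refractory period: a neuron may fire on consecutive
#' steps). The noise current is advanced first via [step_noise()]. The
#' emitted spike is meant to contribute to downstream synaptic currents
#' from the *next* step.
#'
#' @param state a [lif_init()] state.
#' @param params a [lif_params()] object.
#' @param I_syn per-neuron synaptic current (pA).
#' @param dt time step (ms).
#' @return updated state; `state$spiked` flags this step's spikes.
#' @export
step_lif <- function(state, params, I_syn = 0, dt = 1) {
  stopifnot(dt > 0)
  n <- length(state$u)
  if (length(I_syn) == 1L) I_syn <- rep(I_syn, n)
  stopifnot(length(I_syn) == n)
  state$I_noise <- step_noise(state$I_noise, params, dt)
  du <- (-params$gL * (state$u - params$EL) + I_syn + params$Iext +
           state$I_noise) * dt / params$Cm
  u <- state$u + du
  if (any(!is.finite(u)))
    stop("LIF integration blow-up: non-finite membrane potential")
  sp <- u >= params$Uth
  u[sp] <- params$Ureset
  state$u <- u
  state$spiked <- sp
  state
}

#' Advance the Ornstein-Uhlenbeck-style noise current
#'
#' The noise current relaxes to zero with `tau_noise` (exact exponential
#' decay over the step) and receives a forcing `zeta * n(t) * dt` with
#' `n(t)` drawn fresh each step, uniform on `[-1, 1]`. Its long-run mean is
#' zero.
#'
#' @param I_noise per-neuron noise currents (pA).
#' @param params a [lif_params()] object.
#' @param dt time step (ms).
#' @param n optional noise draws (for deterministic testing); defaults to
#'   fresh uniforms on `[-1, 1]`.
#' @return updated noise currents.
#' @export
step_noise <- function(I_noise, params, dt = 1, n = NULL) {
  stopifnot(dt > 0)
  if (is.null(n)) n <- runif(length(I_noise), -1, 1)
  I_noise * exp(-dt / params$tau_noise) + params$zeta * n * dt
}

#' Poisson spike indicators for one step
#'
#' Each source spikes independently with probability `rate * dt / 1000`
#' (rates in Hz, dt in ms); at most one spike per source per step.
#'
#' @param rates per-source rates (Hz), all `>= 0`.
#' @param dt time step (ms).
#' @return logical vector of spike indicators.
#' @export
poisson_spikes <- function(rates, dt = 1) {
  stopifnot(all(rates >= 0))
  p <- rates * dt / 1000
  if (any(p > 1))
    stop("rate * dt exceeds 1: invalid Poisson step configuration")
  runif(length(rates)) < p
}

#' Double-exponential activity filter pair
#'
#' A pair of exponentially filtered spike-train accumulators with time
#' constants `tau_rise < tau_decay`; the read-out activity
#' `(decay_state - rise_state) / (tau_decay - tau_rise)` is the standard
#' normalized double-exponential trace whose impulse response is
#' `(exp(-t/tau_decay) - exp(-t/tau_rise)) / (tau_decay - tau_rise)`.
#' With this normalization the steady-state mean activity of a neuron
#' firing at rate r (spikes/ms) is exactly r, independent of the taus.
#'
#' @param n number of channels.
#' @param tau_rise,tau_decay time constants (ms), `tau_decay > tau_rise > 0`.
#' @return object of class `filter_pair`.
#' @export
filter_pair <- function(n, tau_rise, tau_decay) {
  if (!(tau_decay > tau_rise && tau_rise > 0))
    stop("degenerate filter pair: need tau_decay > tau_rise > 0")
  structure(list(rise = rep(0, n), decay = rep(0, n),
                 tau_rise = tau_rise, tau_decay = tau_decay),
            class = "filter_pair")
}

#' @rdname filter_pair
#' @param f a `filter_pair`.
#' @param spikes logical or 0/1 spike indicators (or counts) for this step.
#' @param dt time step (ms).
#' @export
step_filter_pair <- function(f, spikes, dt = 1) {
  f$rise  <- f$rise  * exp(-dt / f$tau_rise)  + as.numeric(spikes)
  f$decay <- f$decay * exp(-dt / f$tau_decay) + as.numeric(spikes)
  f
}

#' @rdname filter_pair
#' @export
read_activity <- function(f) {
  (f$decay - f$rise) / (f$tau_decay - f$tau_rise)
}
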