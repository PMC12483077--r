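#' Per-synapse plasticity state
#'
#' Holds, for a block of synapses, the spike-timing window trace kappa
#' (driven by presynaptic spikes, read and reset at postsynaptic spikes),
#' the eligibility trace z, and the episode-accumulated weight change dw,
#' along with the three time constants: tau_kappa (window decay), tau_z
#' (eligibility decay) and tau_r (reward discount). All traces start at 0
#' and are reset at the beginning of each episode's main phase.
#'
#' @param n_syn number of synapses.
#' @param tau_kappa,tau_z,tau_r time constants (ms); `tau_r > tau_z`.
#' @return list of class `plastic_state` with fields `kappa`, `z`, `dw`
#'   and the constants.
#' @export
plastic_state <- function(n_syn, tau_kappa = 20, tau_z = 20, tau_r = 100) {
  stopifnot(tau_kappa > 0, tau_z > 0, tau_r > tau_z)
  structure(list(kappa = numeric(n_syn), z = numeric(n_syn),
                 dw = numeric(n_syn),
                 tau_kappa = tau_kappa, tau_z = tau_z, tau_r = tau_r),
            class = "plastic_state")
}

#' One dense step of the kappa / z traces
#'
#' Canonical per-step semantics on the simulation grid (these definitions
#' are the package's discretization of the continuous-time rules, and the
#' compiled engine is required to reproduce them exactly):
#' \enumerate{
#'   \item kappa and z decay by their exact exponential factors;
#'   \item kappa increments by 1 for every presynaptic spike (same step
#'     pre spikes are therefore visible to a same-step postsynaptic
#'     spike);
#'   \item at synapses whose postsynaptic neuron spikes this step, the
#'     coincidence term `f = kappa` is read out, `z` increments by `f`,
#'     and kappa is reset to 0 (for *all* synapses onto that neuron);
#'   \item elsewhere `f = 0`.
#' }
#'
#' @param ps a [plastic_state()].
#' @param pre_spikes logical/0-1 vector per synapse: presynaptic spike.
#' @param post_spikes logical/0-1 vector per synapse: spike of the
#'   synapse's postsynaptic neuron.
#' @param dt step (ms).
#' @return `ps` updated, with the step's forcing term attached as
#'   `attr(, "f")`.
#' @export
step_traces <- function(ps, pre_spikes, post_spikes, dt = 1) {
  pre <- as.logical(pre_spikes); post <- as.logical(post_spikes)
  ps$kappa <- ps$kappa * exp(-dt / ps$tau_kappa)
  ps$z <- ps$z * exp(-dt / ps$tau_z)
  ps$kappa[pre] <- ps$kappa[pre] + 1
  f <- ifelse(post, ps$kappa, 0)
  ps$z <- ps$z + f
  ps$kappa[post] <- 0
  attr(ps, "f") <- f
  ps
}

#' Accumulate the episode weight change (critic rule, PF-SC)
#'
#' The PF-SC accumulation is
#' `d(dw) = CF * z - ((tau_r - tau_z)/(tau_r tau_z)) * V * z + V * f`,
#' with the delta-function terms integrated impulsively on the grid: a CF
#' spike at this step contributes `(-r_bar) * z` dt-free, the coincidence
#' term contributes `V * f` dt-free, and the smooth `V z` coupling term is
#' multiplied by dt. `V` is the instantaneous value estimate of the same
#' step, computed before the traces were updated.
#'
#' @param ps a [plastic_state()] (traces already stepped; `f` from
#'   [step_traces()]).
#' @param cf_amp CF impulse amplitude this step: `-r_bar` at CF spike
#'   steps, 0 otherwise.
#' @param V state-value estimate at this step.
#' @param f per-synapse forcing term of this step.
#' @param dt step (ms).
#' @return updated `ps`.
#' @export
accumulate_dw_sc <- function(ps, cf_amp, V, f, dt = 1) {
  cc <- (ps$tau_r - ps$tau_z) / (ps$tau_r * ps$tau_z)
  ps$dw <- ps$dw + cf_amp * ps$z - cc * V * ps$z * dt + V * f
  ps
}

#' Accumulate the episode weight change (actor rule, PF-PC)
#'
#' Exactly the sign-flipped PF-SC rule: conjunctive PF-CF activation
#' depresses PF-PC synapses (LTD).
#'
#' @inheritParams accumulate_dw_sc
#' @export
accumulate_dw_pc <- function(ps, cf_amp, V, f, dt = 1) {
  cc <- (ps$tau_r - ps$tau_z) / (ps$tau_r * ps$tau_z)
  ps$dw <- ps$dw - cf_amp * ps$z + cc * V * ps$z * dt - V * f
  ps
}

#' End-of-episode bounded weight update
#'
#' `w <- clip(w + eta * dw, 0, 1)`; called once per plastic group after
#' the post-episode phase.
#'
#' @param w per-synapse weights in `[0, 1]`.
#' @param dw accumulated per-synapse weight change for the episode.
#' @param eta learning rate.
#' @return updated weights, clipped to `[0, 1]`.
#' @export
apply_weights <- function(w, dw, eta) {
  if (any(!is.finite(dw)))
    stop("non-finite weight change: aborting (integration diagnostics ",
         "suggest a blow-up)")
  pmin(pmax(w + eta * dw, 0), 1)
}

#' Dense brute-force integration of the plasticity rules (oracle)
#'
#' Integrates kappa, z and dw over a whole episode with the per-step dense
#' loop of [step_traces()] and [accumulate_dw_sc()]. This is the
#' independent reference the compiled event-driven implementation
#' ([run_traces_event()]) must match to floating-point tolerance.
#'
#' @param pre T x n matrix (0/1): presynaptic spikes per step per synapse.
#' @param post T x n matrix (0/1): postsynaptic-neuron spikes mapped onto
#'   the synapses.
#' @param cf_amp length-T vector of CF impulse amplitudes per step.
#' @param V length-T vector of the per-step value estimate.
#' @param dt step (ms).
#' @param tau_kappa,tau_z,tau_r time constants (ms).
#' @param rule `"sc"` (critic signs) or `"pc"` (actor signs).
#' @return list with `dw`, `z`, `kappa` (per-synapse, end of episode).
#' @export
run_traces_dense <- function(pre, post, cf_amp, V, dt = 1,
                             tau_kappa = 20, tau_z = 20, tau_r = 100,
                             rule = c("sc", "pc")) {
  rule <- match.arg(rule)
  pre <- as.matrix(pre); post <- as.matrix(post)
  stopifnot(nrow(pre) == nrow(post), nrow(pre) == length(cf_amp),
            length(V) == length(cf_amp))
  ps <- plastic_state(ncol(pre), tau_kappa, tau_z, tau_r)
  acc <- if (rule == "sc") accumulate_dw_sc else accumulate_dw_pc
  for (t in seq_len(nrow(pre))) {
    ps <- step_traces(ps, pre[t, ], post[t, ], dt)
    ps <- acc(ps, cf_amp[t], V[t], attr(ps, "f"), dt)
  }
  list(dw = ps$dw, z = ps$z, kappa = ps$kappa)
}

#' Event-driven integration of the plasticity rules (engine pathway)
#'
#' Runs the same episode as [run_traces_dense()] through the compiled
#' event-driven tracer used by the episode engine: traces are only touched
#' at pre/post spike events, with analytic decay and per-postsynaptic
#' epoch integrals bridging the gaps. Results agree with the dense oracle
#' to near machine precision.
#'
#' @inheritParams run_traces_dense
#' @param post_neuron T x m matrix (0/1) of postsynaptic-neuron spikes.
#' @param post_of length-n integer: postsynaptic neuron (1..m) of each
#'   synapse.
#' @return list with `dw`, `z`, `kappa`.
#' @export
run_traces_event <- function(pre, post_neuron, post_of, cf_amp, V, dt = 1,
                             tau_kappa = 20, tau_z = 20, tau_r = 100,
                             rule = c("sc", "pc")) {
  rule <- match.arg(rule)
  out <- cpp_traces_event(as.matrix(pre) != 0,
                          as.matrix(post_neuron) != 0,
                          as.integer(post_of) - 1L,
                          as.numeric(cf_amp), as.numeric(V),
                          dt, tau_kappa, tau_z, tau_r)
  if (rule == "pc") {
    out$dw <- -out$dw
  }
  out
}
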