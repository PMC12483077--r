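#' State-value estimate from SC population activity
#'
#' The critic reads the sign-inverted state value off the stellate cells:
#' `-V(t) = nu * SC(t) - V0`, where `SC(t)` is the population mean of the
#' per-SC double-exponential activity ([read_activity()]). Hence
#' `V(t) = V0 - nu * SC(t)`: silent SCs give `V = V0`, activity above the
#' baseline `V0 / nu` makes `V` negative (a punishment-anticipating
#' state).
#'
#' @param sc_activity per-SC activity vector, or an already-averaged
#'   scalar.
#' @param nu scaling factor (default 200).
#' @param v0 baseline (default 2.48).
#' @return scalar `V(t)`.
#' @export
value_estimate <- function(sc_activity, nu = 200, v0 = 2.48) {
  v0 - nu * mean(sc_activity)
}

#' Calibrate the value baseline V0
#'
#' Reproduces the published calibration procedure: run one episode with
#' plasticity disabled and set `V0 = nu * mean(SC(t))` over the latter
#' half of the episode's main phase. The packaged default `V0 = 2.48` was
#' checked against this procedure (it lands in the same range); the
#' calibration is exposed so users who change filter constants or drive
#' can re-derive a consistent baseline.
#'
#' @param config a [cerac_config()].
#' @param seed integer seed for the calibration episode.
#' @return scalar V0 (with the SC-activity trace as attribute `"sc_trace"`).
#' @export
calibrate_v0 <- function(config, seed = 1L) {
  config$plasticity$pf_sc$enabled <- FALSE
  config$plasticity$pf_pc$enabled <- FALSE
  net <- build_network(config, seed = seed)
  w <- initial_weights(net)
  rec <- run_episode(net, w, learn = FALSE)
  scb <- rec$sc_activity
  half <- scb[seq.int(floor(length(scb) / 2) + 1L, length(scb))]
  v0 <- config$readout$nu * mean(half)
  if (all(scb == 0)) warning("no SC activity during calibration; V0 = 0")
  attr(v0, "sc_trace") <- scb
  v0
}

#' Advance the DCN preference dynamics
#'
#' Each DCN cell relaxes toward its baseline with time constant `tau` and
#' is pushed down by `nu` times its counterpart PC's activity
#' (`dDCN/dt = -(DCN - DCN0)/tau - nu * PC`), floored at 0 since the
#' quantity stands for a firing rate. The relaxation uses the exact
#' exponential factor; the PC drive enters as `-nu * PC * dt`.
#'
#' @param dcn per-cell DCN activities.
#' @param pc_activity per-PC activities (counterpart order).
#' @param dt step (ms).
#' @param tau,baseline,nu DCN constants (defaults 10 ms, 1, 1).
#' @return updated DCN activity vector.
#' @export
step_dcn <- function(dcn, pc_activity, dt = 1, tau = 10, baseline = 1,
                     nu = 1) {
  stopifnot(length(dcn) == length(pc_activity))
  dcn <- baseline + (dcn - baseline) * exp(-dt / tau) -
    nu * pc_activity * dt
  pmax(dcn, 0)
}

#' DCN steady state under constant PC drive
#'
#' Closed form of the relaxation fixed point,
#' `DCN0 - nu * tau * PC`, floored at 0.
#'
#' @inheritParams step_dcn
#' @export
dcn_fixed_point <- function(pc_activity, tau = 10, baseline = 1, nu = 1) {
  pmax(baseline - nu * tau * pc_activity, 0)
}

#' Select the action from DCN group preferences
#'
#' The preference of action `a` is the mean activity of DCN group `a`
#' (whose cells are the counterparts of the PCs in the group avoiding
#' `a`); the taken action is the argmax, with deterministic tie-breaking
#' toward the lowest action index. At the DCN fixed point this argmax
#' coincides with the argmin of PC group avoidance.
#'
#' @param dcn per-cell DCN activities.
#' @param groups integer group label (1..n_groups) per DCN cell.
#' @return integer action index in `1..n_groups`.
#' @export
select_action <- function(dcn, groups) {
  h <- tapply(dcn, groups, mean)
  as.integer(which.max(h))  # which.max breaks ties toward lowest index
}

#' PC group avoidance readout
#'
#' Mean PC activity per action group: the avoidance `h_bar` of each
#' action. The least avoided action is `which.min` of this.
#'
#' @param pc_activity per-PC activities.
#' @param groups integer group labels per PC.
#' @return named numeric vector of group means.
#' @export
pc_avoidance <- function(pc_activity, groups) {
  tapply(pc_activity, groups, mean)
}
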