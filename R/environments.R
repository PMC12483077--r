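#' Mountain car: initial state
#'
#' The car starts at rest at the bottom of the valley (`px = -0.5`,
#' `vx = 0` by default, both config-exposed).
#'
#' @param env the `env` section of a mountain-car [cerac_config()].
#' @return list of class `mc_state` with `px`, `vx`, `t` (ms), `done`,
#'   `success`.
#' @export
mc_reset <- function(env = cerac_config("mountain_car")$env) {
  structure(list(px = env$start[1], vx = env$start[2], t = 0,
                 done = FALSE, success = FALSE, env = env),
            class = "mc_state")
}

#' Mountain car: one control step
#'
#' Applies the classic discrete mountain-car update once per step:
#' `vx <- vx + (F_bar * a - g * cos(3 px)) * dt`, then `px <- px + vx * dt`
#' (dt in units of one 1-ms step). Velocity and position are clamped to
#' their ranges; hitting the left wall zeroes the velocity with no reward
#' consequence. The episode ends in success when `px >= p_goal`, or in
#' failure when the elapsed main-phase time exceeds `t_max` (handled by
#' the caller's step budget).
#'
#' @param s an `mc_state`.
#' @param a action in `{-1, +1}` (push left / right).
#' @param dt step (ms); the dynamics are per-step, so `dt` rescales the
#'   update for convergence experiments only.
#' @return updated `mc_state`.
#' @export
mc_step <- function(s, a, dt = 1) {
  stopifnot(a %in% c(-1, 1))
  e <- s$env
  vx <- s$vx + (e$F_bar * a - e$g * cos(3 * s$px)) * dt
  vx <- min(max(vx, -e$v_max), e$v_max)
  px <- s$px + vx * dt
  if (px <= e$x_range[1]) {  # wall collision: stop, no punishment
    px <- e$x_range[1]
    vx <- 0
  }
  if (px >= e$x_range[2]) px <- e$x_range[2]
  s$px <- px; s$vx <- vx; s$t <- s$t + dt
  if (px >= e$p_goal) {
    s$done <- TRUE; s$success <- TRUE
  }
  s
}

#' Mountain car: climbing-fiber rate
#'
#' The CF carries punishment: it fires when the car is far from the goal
#' and slow. The default (`cf_rate_form = "text"`) is
#' `nu_bar * ((p_goal - px) / (p_goal - p_wall)) * (1 - |vx| / v_max)`,
#' which is maximal at the wall at rest and zero at the goal or at top
#' speed. `cf_rate_form = "literal"` swaps in the complementary distance
#' factor `1 - (p_goal - px)/(p_goal - p_wall)` (maximal at the goal),
#' kept only for comparison. Rates are clamped to `[0, nu_bar]`.
#'
#' @param s an `mc_state`.
#' @return CF rate in Hz.
#' @export
mc_cf_rate <- function(s) {
  e <- s$env
  dfrac <- (e$p_goal - s$px) / (e$p_goal - e$p_wall)
  dterm <- if (identical(e$cf_rate_form, "literal")) 1 - dfrac else dfrac
  r <- e$nu_bar * dterm * (1 - abs(s$vx) / e$v_max)
  min(max(r, 0), e$nu_bar)
}

#' @rdname mc_reset
#' @param s an `mc_state`.
#' @export
mc_observation <- function(s) c(s$px, s$vx)

#' Delay eyeblink conditioning: initial state
#'
#' @param env the `env` section of an eyeblink [cerac_config()].
#' @return list of class `eb_state` with eyelid position `pe` (1 = fully
#'   open), time `t` (ms), `done`, `success`.
#' @export
eb_reset <- function(env = cerac_config("eyeblink")$env) {
  structure(list(pe = env$pe0, t = 0, done = FALSE, success = NA,
                 pe_us = NA_real_, env = env),
            class = "eb_state")
}

#' Delay eyeblink conditioning: one control step
#'
#' `pe <- pe + close_speed * a * dt`, clamped to `[0, 1]`; action -1
#' closes, +1 opens. The observation is `(t, pe)`. At the US onset
#' (t = 500 ms) the eyelid position is latched and the episode's success
#' flag becomes `pe(500) <= 0.1`; the episode runs to 1000 ms regardless.
#'
#' @param s an `eb_state`.
#' @param a action in `{-1, +1}` (close / open).
#' @param dt step (ms).
#' @return updated `eb_state`.
#' @export
eb_step <- function(s, a, dt = 1) {
  stopifnot(a %in% c(-1, 1))
  e <- s$env
  s$pe <- min(max(s$pe + e$close_speed * a * dt, 0), 1)
  s$t <- s$t + dt
  if (is.na(s$pe_us) && s$t >= e$t_us) {
    s$pe_us <- s$pe
    s$success <- s$pe_us <= e$cr_threshold
  }
  if (s$t >= diff(range(e$t_range))) s$done <- TRUE
  s
}

#' Delay eyeblink conditioning: climbing-fiber spike
#'
#' The CF fires exactly once per episode, deterministically at the US
#' onset, and only if the eyelid is still open (`pe(t_us) > 0.1`); a
#' sufficiently closed eyelid (the conditioned response) suppresses the
#' punishment entirely.
#'
#' @param s an `eb_state` (after stepping through the US onset).
#' @param t current main-phase time (ms).
#' @return logical: CF spike at this step.
#' @export
eb_cf_spike <- function(s, t) {
  e <- s$env
  isTRUE(t == e$t_us) && isTRUE(s$pe_us > e$cr_threshold)
}

#' @rdname eb_reset
#' @param s an `eb_state`.
#' @export
eb_observation <- function(s) c(s$t, s$pe)

#' Hand-coded mountain-car policies (task solvability references)
#'
#' `mc_constant_policy(dir)` always pushes one way;
#' `mc_pumping_policy()` pushes in the direction of motion (energy
#' pumping), which solves the task without any learning. Both are used to
#' establish, independently of the network, that the task is impossible
#' by brute force but solvable.
#'
#' @param dir +1 or -1.
#' @return function(state) -> action.
#' @export
mc_constant_policy <- function(dir = 1) function(s) dir

#' @rdname mc_constant_policy
#' @export
mc_pumping_policy <- function() function(s) if (s$vx >= 0) 1 else -1

#' Roll out a policy on the mountain car
#'
#' @param policy function mapping `mc_state` to an action.
#' @param env env config section.
#' @param t_max step budget (ms).
#' @return list with `success`, `steps`, and the position trace.
#' @export
mc_rollout <- function(policy, env = cerac_config("mountain_car")$env,
                       t_max = 1000) {
  s <- mc_reset(env)
  px <- numeric(0)
  for (k in seq_len(t_max)) {
    s <- mc_step(s, policy(s))
    px[k] <- s$px
    if (s$done) break
  }
  list(success = isTRUE(s$success), steps = length(px), px = px)
}
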