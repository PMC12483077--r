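#' Default simulation configuration
#'
#' Builds the full nested configuration for one task with every model
#' parameter embedded at its published default. Any entry can be overridden
#' through `...` with nested lists, e.g.
#' `cerac_config("mountain_car", plasticity = list(pf_sc = list(enabled = FALSE)))`.
#'
#' Membrane and synaptic constants: SC/BC/PC share Cm = 107 pF and
#' gL = 2.32 nS (so tau_m ~ 46 ms); SC/BC rest at -68 mV, PCs at -65 mV;
#' threshold -55 mV; reset -70 mV (SC/BC) or -66 mV (PC); tonic drive
#' Iext = 30 pA; noise amplitude zeta = 5 pA (SC, PC) or 1 pA (BC).
#' Connection scaling factors, decay constants and wiring probabilities are
#' per connection type (PF-SC 200/8.3 ms/p=0.1 plastic; PF-BC 10/8.3/0.5;
#' PF-PC 5/8.3/0.5 plastic; SC-PC -0.05/10/0.5 w=0.03; BC-BC -2/10/0.3;
#' BC-PC -1/10/0.3; PC-BC -2/10/0.8; PC-PC -19.8/5/1.0). Plasticity time
#' constants are tau_kappa = tau_z = 20 ms and tau_r = 100 ms.
#'
#' Task defaults: mountain car trains 10 runs x 1000 episodes with
#' eta_SC = eta_PC = 0.4, initial weights 0.05 (PF-SC) and 0.8 (PF-PC);
#' eyeblink trains 10 runs x 500 episodes with eta_SC = 0.05, eta_PC = 0.3
#' and per-group PF-PC initial weights 0.8 (anticlose) / 0.7 (antiopen).
#'
#' A few constants are not published and are package choices (see the
#' methods vignette): tau_noise = 10 ms; activity-filter rise/decay
#' 2/20 ms for both the SC value readout and the PC readout (the decay is
#' matched to the printed eligibility/window constant of 20 ms -- a
#' slower readout lags the value estimate relative to the timescale the
#' eligibility traces integrate and destabilizes learning); DCN
#' relaxation tau = 10 ms with baseline 1 and scaling 1; mountain-car
#' goal 0.5 and start -0.5; eyeblink initial eyelid 1.0.
#'
#' @param task `"mountain_car"` or `"eyeblink"`.
#' @param ... nested named lists merged over the defaults.
#' @return A nested list of class `cerac_config`.
#' @export
#' @examples
#' cfg <- cerac_config("eyeblink", run = list(n_runs = 2))
#' cfg$plasticity$pf_pc$eta
cerac_config <- function(task = c("mountain_car", "eyeblink"), ...) {
  task <- match.arg(task)
  base <- list(
    task = task,
    dt = 1.0,
    plane = list(
      nx = 16L, ny = 16L, margin = 1L, pfs_per_tile = 100L,
      rho_pf = 50, sigma = 0.5, receptive_field_units = "tile"
    ),
    neurons = list(
      SC = list(Cm = 107, gL = 2.32, EL = -68, Uth = -55, Ureset = -70,
                Iext = 30, zeta = 5, tau_noise = 10),
      BC = list(Cm = 107, gL = 2.32, EL = -68, Uth = -55, Ureset = -70,
                Iext = 30, zeta = 1, tau_noise = 10),
      PC = list(Cm = 107, gL = 2.32, EL = -65, Uth = -55, Ureset = -66,
                Iext = 30, zeta = 5, tau_noise = 10)
    ),
    populations = list(n_pc = 20L, n_groups = 2L),
    connectivity = list(
      pf_sc = list(sc = 200,   tau_c = 8.3, p = 0.1, plastic = TRUE),
      pf_bc = list(sc = 10,    tau_c = 8.3, p = 0.5, w = 1.0),
      pf_pc = list(sc = 5,     tau_c = 8.3, p = 0.5, plastic = TRUE),
      sc_pc = list(sc = -0.05, tau_c = 10,  p = 0.5, w = 0.03),
      bc_bc = list(sc = -2,    tau_c = 10,  p = 0.3, w = 1.0),
      bc_pc = list(sc = -1,    tau_c = 10,  p = 0.3, w = 1.0),
      pc_bc = list(sc = -2,    tau_c = 10,  p = 0.8, w = 1.0),
      pc_pc = list(sc = -19.8, tau_c = 5,   p = 1.0, w = 1.0)
    ),
    readout = list(
      nu = 200, v0 = 2.48,
      sc_tau_rise = 2, sc_tau_decay = 20,
      pc_tau_rise = 2, pc_tau_decay = 20,
      dcn = list(tau = 10, baseline = 1, nu = 1)
    ),
    plasticity = list(
      tau_kappa = 20, tau_z = 20, tau_r = 100,
      pf_sc = list(enabled = TRUE, eta = 0.4, w0 = 0.05),
      pf_pc = list(enabled = TRUE, eta = 0.4, w0 = 0.8)
    ),
    run = list(n_runs = 10L, n_episodes = 1000L,
               pre_ms = 200L, post_ms = 100L, t_max = 1000L)
  )

  if (task == "mountain_car") {
    base$env <- list(
      x_range = c(-1.2, 0.6), v_range = c(-0.07, 0.07),
      F_bar = 0.001, g = 0.0025,
      p_goal = 0.5, p_wall = -1.2, v_max = 0.07,
      nu_bar = 5, r_bar = -5,
      start = c(-0.5, 0),
      cf_rate_form = "text"
    )
  } else {
    base$env <- list(
      t_range = c(0, 1000), pe_range = c(0, 1),
      close_speed = 0.01, t_us = 500, cr_threshold = 0.1,
      pe0 = 1.0, r_bar = -5
    )
    base$run$n_episodes <- 500L
    base$plasticity$pf_sc$eta <- 0.05
    base$plasticity$pf_pc$eta <- 0.3
    # per-action-group initial PF-PC weights: group 1 = anticlose (pairs
    # with the "close" DCN group), group 2 = antiopen
    base$plasticity$pf_pc$w0 <- c(0.8, 0.7)
  }

  cfg <- merge_config(base, list(...))
  class(cfg) <- c("cerac_config", "list")
  validate_config(cfg)
  cfg
}

# recursive list merge: values in `over` replace values in `base`
merge_config <- function(base, over) {
  if (length(over) == 0L) return(base)
  stopifnot(is.list(over))
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$dt > 0,
    cfg$plane$nx >= 1L, cfg$plane$ny >= 1L, cfg$plane$margin >= 0L,
    cfg$plane$pfs_per_tile >= 1L, cfg$plane$sigma > 0,
    cfg$populations$n_pc %% cfg$populations$n_groups == 0L
  )
  for (nm in names(cfg$neurons)) {
    p <- cfg$neurons[[nm]]
    if (!(p$Ureset < p$Uth && p$Cm > 0 && p$gL > 0 && p$tau_noise > 0))
      stop("invalid neuron parameters for ", nm)
  }
  with(cfg$plasticity, stopifnot(tau_kappa > 0, tau_z > 0, tau_r > tau_z))
  invisible(cfg)
}

#' @export
print.cerac_config <- function(x, ...) {
  cat("<cerac_config> task:", x$task, "\n")
  cat("  plane: ", x$plane$nx, "x", x$plane$ny, " +", x$plane$margin,
      " margin, ", x$plane$pfs_per_tile, " PFs/tile\n", sep = "")
  cat("  run:   ", x$run$n_runs, " runs x ", x$run$n_episodes,
      " episodes, dt = ", x$dt, " ms\n", sep = "")
  cat("  eta:   PF-SC ", x$plasticity$pf_sc$eta,
      " (enabled: ", x$plasticity$pf_sc$enabled, "), PF-PC ",
      x$plasticity$pf_pc$eta,
      " (enabled: ", x$plasticity$pf_pc$enabled, ")\n", sep = "")
  invisible(x)
}
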