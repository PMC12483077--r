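#' Run one episode through the compiled engine
#'
#' The episode protocol has three phases:
#' \enumerate{
#'   \item a 200 ms free run with the PFs encoding the initial
#'     observation, to discard transient activity; no weight-change
#'     accumulation (all plasticity traces start at zero at the end of
#'     this phase);
#'   \item the main phase (up to `t_max` = 1000 ms, or until the
#'     environment terminates) with full dynamics, CF reward spikes and
#'     trace/weight-change accumulation;
#'   \item a 100 ms tail with PF firing suppressed, during which the
#'     weight-change accumulation continues.
#' }
#' The caller applies the accumulated `dw` with [apply_weights()]
#' afterwards (done automatically by [run_training()]).
#'
#' @param net a [build_network()] object.
#' @param weights list with `pf_sc`, `pf_pc` weight vectors (see
#'   [initial_weights()]).
#' @param learn logical; `FALSE` freezes both plastic groups (used e.g.
#'   by [calibrate_v0()]). Per-group switches come from
#'   `config$plasticity$*$enabled`.
#' @param record_spikes logical; when `TRUE` the main-phase spike raster
#'   of SC/BC/PC is returned (neuron ids SC 0-323, BC 324-647,
#'   PC 648-667 at default sizes).
#' @return an `episode_record`: `success`, `n_main` (main-phase steps),
#'   `dw_pfsc`, `dw_pfpc`, `v` (V(t), main phase), `sc_activity`,
#'   `action` (selected action index per step), `traj` (n_main x 2
#'   observations), `cf_steps`, task summaries (`t_goal` or
#'   `pe_us`/`first_close`), `pc_window_rates`, optionally `spikes`.
#' @export
run_episode <- function(net, weights, learn = TRUE, record_spikes = FALSE) {
  cfg <- net$config
  ctrl <- list(
    dt = cfg$dt,
    pre_steps = as.integer(round(cfg$run$pre_ms / cfg$dt)),
    max_steps = as.integer(round(cfg$run$t_max / cfg$dt)),
    post_steps = as.integer(round(cfg$run$post_ms / cfg$dt)),
    learn_sc = isTRUE(learn) && isTRUE(cfg$plasticity$pf_sc$enabled),
    learn_pc = isTRUE(learn) && isTRUE(cfg$plasticity$pf_pc$enabled),
    record_spikes = isTRUE(record_spikes),
    tau_kappa = cfg$plasticity$tau_kappa,
    tau_z = cfg$plasticity$tau_z,
    tau_r = cfg$plasticity$tau_r,
    nu = cfg$readout$nu, v0 = cfg$readout$v0,
    sc_tau_rise = cfg$readout$sc_tau_rise,
    sc_tau_decay = cfg$readout$sc_tau_decay,
    pc_tau_rise = cfg$readout$pc_tau_rise,
    pc_tau_decay = cfg$readout$pc_tau_decay,
    dcn_tau = cfg$readout$dcn$tau,
    dcn_baseline = cfg$readout$dcn$baseline,
    dcn_nu = cfg$readout$dcn$nu
  )
  task <- c(list(type = if (cfg$task == "mountain_car") 0L else 1L),
            cfg$env)
  rec <- cpp_run_episode(net$engine, weights$pf_sc, weights$pf_pc,
                         task, ctrl)
  class(rec) <- c("episode_record", "list")
  rec
}

#' @export
print.episode_record <- function(x, ...) {
  cat("<episode_record> ", x$n_main, " main steps, success: ",
      x$success, ", CF spikes: ", length(x$cf_steps), "\n", sep = "")
  invisible(x)
}

#' Window moving average of a success sequence
#'
#' Right-aligned moving mean with window `window`; the first
#' `window - 1` entries average over the episodes available so far.
#'
#' @param x numeric 0/1 success sequence.
#' @param window window size (episodes), default 10.
#' @return numeric vector, same length as `x`.
#' @export
moving_average <- function(x, window = 10L) {
  n <- length(x)
  cs <- cumsum(x)
  lo <- pmax(seq_len(n) - window, 0L)
  (cs - c(0, cs)[lo + 1L]) / (seq_len(n) - lo)
}

#' Derive an independent per-run seed from the master seed
#'
#' Counter-based so every run is individually re-executable; kept below
#' 2^31.
#'
#' @param seed master seed (integer).
#' @param run run counter (1-based).
#' @return integer seed.
#' @export
derive_run_seed <- function(seed, run) {
  as.integer((as.double(seed %% 65536L) * 20011 + run * 7919) %% 2147483629)
}

#' Train the model on a task
#'
#' Executes `n_runs` independent runs of `n_episodes` episodes each. Every
#' run rebuilds the network (its own connectivity realization) from a
#' per-run seed derived from `seed`, loops episodes through
#' [run_episode()], applies the bounded weight update at each episode end,
#' and records the per-episode success together with task-specific
#' diagnostics (time-to-goal for mountain car; eyelid position at the US,
#' first eyelid-closing time, value-ramp amplitude and PC-group
#' pre-US firing rates for eyeblink).
#'
#' @param config a [cerac_config()].
#' @param n_runs,n_episodes override the config's run section.
#' @param seed master seed.
#' @param progress print one line per run.
#' @return object of class `cerac_training`: `episodes` (a long
#'   data.frame), `ma` (episode x run matrix of window-10 moving-average
#'   success), `mean_curve` (cross-run mean of `ma`), `final_weights`
#'   (per run), `seeds`, `config`.
#' @export
run_training <- function(config, n_runs = config$run$n_runs,
                         n_episodes = config$run$n_episodes,
                         seed = 1L, progress = FALSE) {
  eb <- config$task == "eyeblink"
  rows <- vector("list", n_runs)
  final_weights <- vector("list", n_runs)
  seeds <- vapply(seq_len(n_runs), function(r) derive_run_seed(seed, r), 1L)

  for (r in seq_len(n_runs)) {
    set.seed(seeds[r])
    net <- build_network(config)
    w <- initial_weights(net)
    eta_sc <- config$plasticity$pf_sc$eta
    eta_pc <- config$plasticity$pf_pc$eta
    res <- data.frame(run = r, episode = seq_len(n_episodes),
                      success = NA, t_goal = NA_real_,
                      pe_us = NA_real_, first_close = NA_real_,
                      close_onset = NA_real_, v_ramp = NA_real_,
                      pc_preus_g1 = NA_real_, pc_preus_g2 = NA_real_,
                      pc_base_g1 = NA_real_, pc_base_g2 = NA_real_)
    for (ep in seq_len(n_episodes)) {
      rec <- run_episode(net, w)
      if (config$plasticity$pf_sc$enabled)
        w$pf_sc <- apply_weights(w$pf_sc, rec$dw_pfsc, eta_sc)
      if (config$plasticity$pf_pc$enabled)
        w$pf_pc <- apply_weights(w$pf_pc, rec$dw_pfpc, eta_pc)
      res$success[ep] <- rec$success
      if (eb) {
        res$pe_us[ep] <- rec$pe_us
        res$first_close[ep] <- rec$first_close
        res$close_onset[ep] <- rec$close_onset
        nv <- -rec$v
        res$v_ramp[ep] <- mean(nv[400:500]) - mean(nv[1:100])
        res$pc_preus_g1[ep] <- rec$pc_window_rates[1, 2]
        res$pc_preus_g2[ep] <- rec$pc_window_rates[2, 2]
        res$pc_base_g1[ep] <- rec$pc_window_rates[1, 1]
        res$pc_base_g2[ep] <- rec$pc_window_rates[2, 1]
      } else {
        res$t_goal[ep] <- if (rec$success) rec$n_main * config$dt else NA_real_
      }
    }
    rows[[r]] <- res
    final_weights[[r]] <- w
    if (progress)
      message(sprintf("run %d/%d: success rate (last 100) = %.2f",
                      r, n_runs, mean(tail(res$success, 100))))
  }

  episodes <- do.call(rbind, rows)
  ma <- vapply(rows, function(d) moving_average(as.numeric(d$success)),
               numeric(n_episodes))
  structure(list(
    episodes = episodes,
    ma = ma,
    mean_curve = rowMeans(ma),
    final_weights = final_weights,
    seeds = seeds,
    config = config
  ), class = "cerac_training")
}

#' Eyeblink training without PF-SC plasticity (ablation)
#'
#' Reruns the eyeblink protocol with `plasticity$pf_sc$enabled = FALSE`
#' (PF-SC weights then stay bit-identical across episodes), for
#' comparison of closing-time statistics and conditioned-response
#' stability against the intact model.
#'
#' @param config an eyeblink [cerac_config()].
#' @param ... passed to [run_training()].
#' @export
ablate_pf_sc <- function(config, ...) {
  stopifnot(config$task == "eyeblink")
  config$plasticity$pf_sc$enabled <- FALSE
  run_training(config, ...)
}

#' @export
print.cerac_training <- function(x, ...) {
  n_ep <- nrow(x$ma); n_runs <- ncol(x$ma)
  cat("<cerac_training> task:", x$config$task, "-", n_runs, "runs x",
      n_ep, "episodes\n")
  last <- max(1L, n_ep - 99L):n_ep
  cat(sprintf("  final-100-episode success: %.3f (cross-run mean)\n",
              mean(x$ma[last, ])))
  invisible(x)
}

#' Serialize a training summary to plain-text files
#'
#' Writes `episodes.csv` (per-episode long table), `curve.csv`
#' (per-episode moving-average success per run and mean), and
#' `manifest.json` (task, seeds, key parameters) into `dir`.
#'
#' @param training a `cerac_training`.
#' @param dir output directory (created if needed).
#' @export
write_training <- function(training, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(training$episodes, file.path(dir, "episodes.csv"),
                   row.names = FALSE)
  curve <- data.frame(episode = seq_len(nrow(training$ma)),
                      training$ma, mean = training$mean_curve)
  names(curve)[1 + seq_len(ncol(training$ma))] <-
    paste0("run", seq_len(ncol(training$ma)))
  utils::write.csv(curve, file.path(dir, "curve.csv"), row.names = FALSE)
  manifest <- list(
    task = training$config$task,
    n_runs = ncol(training$ma), n_episodes = nrow(training$ma),
    seeds = training$seeds,
    eta = c(pf_sc = training$config$plasticity$pf_sc$eta,
            pf_pc = training$config$plasticity$pf_pc$eta),
    pf_sc_enabled = training$config$plasticity$pf_sc$enabled,
    package_version = as.character(utils::packageVersion("cerac"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
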