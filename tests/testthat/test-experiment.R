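test_that("moving average reproduces hand-computed windows", {
  expect_equal(moving_average(rep(1, 30)), rep(1, 30))
  alt <- rep(c(1, 0), 20)
  ma <- moving_average(alt)
  expect_true(all(abs(ma[10:40] - 0.5) <= 0.05 + 1e-12))
  # hand-computed partial and full windows
  x <- c(1, 0, 0, 1, 1, 1, 0, 1, 1, 1, 0, 0)
  expect_equal(moving_average(x, 4)[2], 0.5)
  expect_equal(moving_average(x, 4)[6], mean(x[3:6]))
  expect_equal(moving_average(x, 10)[12], mean(x[3:12]))
})

test_that("per-run seeds are distinct and reproducible", {
  s <- vapply(1:50, function(r) derive_run_seed(123, r), 1L)
  expect_identical(length(unique(s)), 50L)
  expect_identical(s, vapply(1:50, function(r) derive_run_seed(123, r), 1L))
})

test_that("identical seed and config give a bit-identical episode", {
  cfg <- tiny_config("mountain_car")
  run_once <- function() {
    set.seed(99)
    net <- build_network(cfg)
    run_episode(net, initial_weights(net), record_spikes = TRUE)
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$v, b$v)
  expect_identical(a$traj, b$traj)
  expect_identical(a$dw_pfsc, b$dw_pfsc)
  expect_identical(a$dw_pfpc, b$dw_pfpc)
  expect_identical(a$spikes, b$spikes)
})

test_that("all plasticity disabled leaves weights identical", {
  cfg <- tiny_config("eyeblink",
                     plasticity = list(pf_sc = list(enabled = FALSE),
                                       pf_pc = list(enabled = FALSE)))
  tr <- run_training(cfg, n_runs = 1, n_episodes = 2, seed = 4)
  w <- tr$final_weights[[1]]
  expect_identical(w$pf_sc, rep(cfg$plasticity$pf_sc$w0, length(w$pf_sc)))
  expect_identical(unique(w$pf_pc), cfg$plasticity$pf_pc$w0)
})

test_that("weight updates keep every weight in [0,1] (conservation)", {
  cfg <- tiny_config("mountain_car")
  tr <- run_training(cfg, n_runs = 1, n_episodes = 5, seed = 8)
  w <- tr$final_weights[[1]]
  net <- build_network(cfg, seed = derive_run_seed(8, 1))
  # one applied delta per plastic synapse
  expect_identical(length(w$pf_sc), length(net$conn$pf_sc$pre))
  expect_identical(length(w$pf_pc), length(net$conn$pf_pc$pre))
  expect_true(all(w$pf_sc >= 0 & w$pf_sc <= 1))
  expect_true(all(w$pf_pc >= 0 & w$pf_pc <= 1))
})

test_that("the 100 ms post-episode phase contributes to the update", {
  cfg <- tiny_config("mountain_car")
  run_with_post <- function(post_ms) {
    cfg$run$post_ms <- post_ms
    set.seed(31)
    net <- build_network(cfg)
    run_episode(net, initial_weights(net))
  }
  with_post <- run_with_post(50L)
  no_post <- run_with_post(0L)
  # the main phase consumed identical RNG draws, so any difference in dw
  # comes from accumulation during the PF-silenced tail
  expect_identical(with_post$v, no_post$v)
  expect_false(identical(with_post$dw_pfsc, no_post$dw_pfsc))
})

test_that("episode record layout matches the population index scheme", {
  cfg <- cerac_config("mountain_car", run = list(t_max = 150L))
  set.seed(12)
  net <- build_network(cfg)
  rec <- run_episode(net, initial_weights(net), record_spikes = TRUE)
  ids <- rec$spikes[, 2]
  expect_true(all(ids >= 0 & ids <= 667))   # SC 0-323, BC 324-647, PC 648-667
  expect_true(any(ids <= 323) && any(ids >= 324 & ids <= 647))
  expect_true(all(rec$spikes[, 1] >= 1 & rec$spikes[, 1] <= rec$n_main))
  expect_identical(nrow(rec$traj), rec$n_main)
  expect_identical(length(rec$v), rec$n_main)
})

test_that("engine environment matches the R reference step-for-step", {
  # mountain car: replay the engine's action trace through mc_step()
  cfg <- tiny_config("mountain_car")
  set.seed(55)
  net <- build_network(cfg)
  rec <- run_episode(net, initial_weights(net))
  s <- mc_reset(cfg$env)
  for (k in seq_len(rec$n_main)) {
    a <- if (rec$action[k] == 1) -1 else 1
    s <- mc_step(s, a)
    expect_equal(s$px, rec$traj[k, 1], tolerance = 1e-12)
    expect_equal(s$vx, rec$traj[k, 2], tolerance = 1e-12)
  }
  expect_identical(s$success, rec$success)

  # eyeblink: same replay, checking pe and the US latch
  cfge <- tiny_config("eyeblink")
  cfge$run$t_max <- 1000L
  set.seed(56)
  nete <- build_network(cfge)
  rece <- run_episode(nete, initial_weights(nete))
  se <- eb_reset(cfge$env)
  for (k in seq_len(rece$n_main)) {
    a <- if (rece$action[k] == 1) -1 else 1
    se <- eb_step(se, a)
    expect_equal(se$pe, rece$traj[k, 2], tolerance = 1e-12)
  }
  expect_equal(se$pe_us, rece$pe_us)
  expect_identical(se$success, rece$success)
})

test_that("training summary serializes to plain-text files", {
  cfg <- tiny_config("mountain_car")
  tr <- run_training(cfg, n_runs = 2, n_episodes = 3, seed = 2)
  d <- withr::local_tempdir()
  write_training(tr, d)
  expect_true(file.exists(file.path(d, "episodes.csv")))
  ep <- utils::read.csv(file.path(d, "episodes.csv"))
  expect_identical(nrow(ep), 6L)
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_identical(man$task, "mountain_car")
  expect_identical(length(man$seeds), 2L)
})
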