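sc_pars <- function(zeta = 0) {
  lif_params(Cm = 107, gL = 2.32, EL = -68, Uth = -55, Ureset = -70,
             Iext = 30, zeta = zeta, tau_noise = 10)
}

test_that("subthreshold LIF relaxes to the closed-form fixed point", {
  # raise the threshold so the SC drive can be observed subthreshold
  p <- lif_params(Cm = 107, gL = 2.32, EL = -68, Uth = 0, Ureset = -70,
                  Iext = 30, zeta = 0, tau_noise = 10)
  st <- lif_init(3, p)
  for (k in 1:3000) st <- step_lif(st, p, I_syn = 0, dt = 1)
  u_inf <- p$EL + p$Iext / p$gL
  expect_equal(u_inf, -55.069, tolerance = 1e-4)
  expect_equal(st$u, rep(u_inf, 3), tolerance = 1e-6)

  # trajectory matches exponential relaxation within O(dt) Euler error
  p2 <- lif_params(Cm = 107, gL = 2.32, EL = -68, Uth = 0, Ureset = -70,
                   Iext = 0, zeta = 0, tau_noise = 10)
  st <- lif_init(1, p2); st$u <- -60
  tau_m <- p2$Cm / p2$gL
  for (k in 1:50) st <- step_lif(st, p2, 0, dt = 1)
  exact <- p2$EL + (-60 - p2$EL) * exp(-50 / tau_m)
  expect_equal(st$u, exact, tolerance = 1e-2)
})

test_that("SC baseline firing: fixed point 0.07 mV under threshold, noise-driven", {
  # u_inf = EL + Iext/gL = -55.069 mV sits just *below* Uth = -55, so the
  # deterministic SC never fires...
  p0 <- sc_pars(zeta = 0)
  st <- lif_init(1, p0)
  spikes <- 0L
  for (k in 1:2000) {
    st <- step_lif(st, p0, 0, dt = 1)
    spikes <- spikes + sum(st$spiked)
  }
  expect_identical(spikes, 0L)
  expect_lt(st$u, p0$Uth)
  # ...but the published noise amplitude (zeta = 5 pA) carries it across
  # the 0.07 mV gap: SCs fire at a low spontaneous rate
  set.seed(202)
  p5 <- sc_pars(zeta = 5)
  st <- lif_init(10, p5)
  spikes <- 0L
  for (k in 1:2000) {
    st <- step_lif(st, p5, 0, dt = 1)
    spikes <- spikes + sum(st$spiked)
  }
  rate_hz <- spikes / 10 / 2
  expect_gt(rate_hz, 0.5)
  expect_lt(rate_hz, 60)
})

test_that("threshold crossing emits a spike and resets exactly", {
  p <- sc_pars()
  st <- lif_init(2, p)
  st$u <- c(p$Uth, p$EL)
  # cancel leak and external drive on neuron 1 so it sits at threshold
  I <- c(p$gL * (p$Uth - p$EL) - p$Iext, 0)
  st <- step_lif(st, p, I, dt = 1)
  expect_identical(st$spiked, c(TRUE, FALSE))
  expect_identical(st$u[1], -70)

  # at rest with no input the membrane stays at EL forever
  p0 <- lif_params(Cm = 107, gL = 2.32, EL = -68, Uth = -55,
                   Ureset = -70, Iext = 0, zeta = 0, tau_noise = 10)
  st <- lif_init(5, p0)
  for (k in 1:100) st <- step_lif(st, p0, 0)
  expect_equal(st$u, rep(-68, 5))
  # recorded u never exceeds Uth after processing
  expect_true(all(st$u < p0$Uth))
})

test_that("noise current: homogeneous decay and stationary statistics", {
  p <- sc_pars(zeta = 0)
  x <- 12
  for (k in 1:40) x <- step_noise(x, p, dt = 1)
  expect_equal(x, 12 * exp(-40 / 10), tolerance = 1e-12)

  # zeta = 5: stationary variance of the recursion x' = a x + zeta dt n,
  # n ~ U[-1,1]: var = (zeta dt)^2 (1/3) / (1 - a^2); brute-force check
  set.seed(101)
  p5 <- sc_pars(zeta = 5)
  a <- exp(-1 / p5$tau_noise)
  n_neur <- 2000L
  x <- rep(0, n_neur)
  burn <- 200L; keep <- 300L
  acc <- numeric(0)
  for (k in seq_len(burn + keep)) {
    x <- step_noise(x, p5, dt = 1)
    if (k > burn) acc <- c(acc, var(x))
  }
  v_emp <- mean(acc)
  v_th <- (5 * 1)^2 * (1 / 3) / (1 - a^2)
  expect_equal(v_emp, v_th, tolerance = 0.1)

  # long-run mean ~ 0, shrinking like 1/sqrt(T)
  set.seed(102)
  x <- 0; s <- 0; T <- 1e5
  for (k in 1:T) { x <- step_noise(x, p5, 1); s <- s + x }
  expect_lt(abs(s / T), 4 * sqrt(v_th / T))
})

test_that("poisson_spikes honors rates and rejects invalid steps", {
  set.seed(7)
  expect_false(any(poisson_spikes(rep(0, 100), 1)))
  r <- c(0, 0, 80, 0)
  hits <- replicate(2000, poisson_spikes(r, 1))
  expect_true(all(rowSums(hits)[c(1, 2, 4)] == 0))
  expect_gt(rowSums(hits)[3], 0)

  # empirical rate within 4 sigma binomial bounds over 1e5 draws
  n <- 1e5; p <- 50 / 1000
  k <- sum(poisson_spikes(rep(50, n), 1))
  expect_lt(abs(k - n * p), 4 * sqrt(n * p * (1 - p)))

  expect_error(poisson_spikes(2000, dt = 1), "exceeds 1")
  expect_error(poisson_spikes(-1, 1))
})

test_that("filter pair reproduces the analytic double exponential", {
  tr <- 5; td <- 50
  f <- filter_pair(1, tr, td)
  f <- step_filter_pair(f, 1, dt = 1)       # spike at t0
  expect_equal(read_activity(f), 0)         # both states equal at t0
  err_at_dt <- function(dt) {
    f <- filter_pair(1, tr, td)
    steps <- round(30 / dt)
    f <- step_filter_pair(f, 1, dt)
    worst <- 0
    for (k in seq_len(steps)) {
      f <- step_filter_pair(f, 0, dt)
      tt <- k * dt
      exact <- (exp(-tt / td) - exp(-tt / tr)) / (td - tr)
      worst <- max(worst, abs(read_activity(f) - exact))
    }
    worst
  }
  # exact exponential-integrator decay: error at machine precision, and
  # certainly non-increasing as dt halves
  e1 <- err_at_dt(1); e05 <- err_at_dt(0.5)
  expect_lt(e1, 1e-12)
  expect_lte(e05, e1 + 1e-14)

  # no spikes: activity identically zero and states decay to zero
  f <- filter_pair(4, tr, td)
  for (k in 1:100) f <- step_filter_pair(f, rep(0, 4), 1)
  expect_equal(read_activity(f), rep(0, 4))
  expect_true(all(read_activity(step_filter_pair(f, c(1, 0, 1, 0), 1)) >= 0))

  expect_error(filter_pair(1, 10, 10), "degenerate")
})
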