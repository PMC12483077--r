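test_that("PF plane geometry matches the published counts", {
  pl <- build_pf_plane(cerac_config("mountain_car"))
  expect_identical(pl$n_tiles, 324L)      # (16 + 2)^2
  expect_identical(pl$n_pf, 32400L)
  expect_equal(unname(pl$delta_s), c(1.8 / 16, 0.14 / 16), tolerance = 1e-12)

  expect_identical(build_pf_plane(NULL, nx = 2, ny = 3, margin = 1,
                                  pfs_per_tile = 5)$n_tiles, 20L)
  p1 <- build_pf_plane(NULL, nx = 1, ny = 1, margin = 0, pfs_per_tile = 1)
  expect_identical(p1$n_tiles, 1L)
  expect_equal(unname(p1$centers[1, ]), c(0.5, 0.5))

  expect_error(build_pf_plane(NULL, state_ranges = list(x = c(1, 0),
                                                        y = c(0, 1))),
               "degenerate")
})

test_that("pf_rates: Gaussian receptive fields in tile units", {
  cfg <- cerac_config("mountain_car")
  pl <- build_pf_plane(cfg)
  # observation exactly at a tile center: rate = rho / (2 pi sigma^2)
  obs <- c(pl$state_ranges$x[1] + 3.5 * pl$delta_s["x"],
           pl$state_ranges$y[1] + 7.5 * pl$delta_s["y"])
  r <- pf_rates(pl, obs)
  expect_equal(max(r), 50 / (2 * pi * 0.25), tolerance = 1e-9)  # 31.83 Hz
  # nearest tile attains the maximum; all rates strictly positive
  d2 <- (pl$centers[, 1] - 3.5)^2 + (pl$centers[, 2] - 7.5)^2
  expect_identical(which.max(r), which.min(d2))
  expect_true(all(r > 0))

  # distance ratio follows exp(-d^2 / (2 sigma^2))
  i0 <- which.max(r)
  j <- which(pl$centers[, 1] == pl$centers[i0, 1] + 2 &
               pl$centers[, 2] == pl$centers[i0, 2])
  expect_equal(r[j] / r[i0], exp(-4 / (2 * 0.25)), tolerance = 1e-9)

  # per-fiber expansion shares the tile rate
  rf <- pf_rates(pl, obs, per_fiber = TRUE)
  expect_identical(length(rf), pl$n_pf)
  expect_equal(rf[(i0 - 1) * 100 + 1:100], rep(r[i0], 100))
})

test_that("margin frame keeps total PF drive near-constant", {
  # intrinsic Gaussian-lattice ripple at sigma = 0.5 tiles is ~5.8%
  # peak-to-peak (Poisson summation: 2 exp(-2 pi^2 sigma^2) per axis), so
  # the sweep bound is 8%; the margin's purpose shows in the comparison
  # against a frame-less plane, whose corner drive collapses to ~24%.
  pl <- build_pf_plane(cerac_config("mountain_car"))
  xs <- seq(pl$state_ranges$x[1], pl$state_ranges$x[2], length.out = 13)
  ys <- seq(pl$state_ranges$y[1], pl$state_ranges$y[2], length.out = 13)
  tot <- sapply(xs, function(x) sapply(ys, function(y)
    sum(pf_rates(pl, c(x, y)))))
  expect_lt((max(tot) - min(tot)) / mean(tot), 0.08)

  pl0 <- build_pf_plane(NULL, nx = 16, ny = 16, margin = 0,
                        pfs_per_tile = 100, rho_pf = 50, sigma = 0.5,
                        state_ranges = pl$state_ranges)
  corner <- c(pl$state_ranges$x[1], pl$state_ranges$y[1])
  mid <- c(mean(pl$state_ranges$x), mean(pl$state_ranges$y))
  expect_gt(sum(pf_rates(pl, corner)) / sum(pf_rates(pl, mid)), 0.9)
  expect_lt(sum(pf_rates(pl0, corner)) / sum(pf_rates(pl0, mid)), 0.5)
})

test_that("pf_rates is translation-covariant on the interior lattice", {
  pl <- build_pf_plane(cerac_config("mountain_car"))
  o1 <- c(pl$state_ranges$x[1] + 5.3 * pl$delta_s["x"],
          pl$state_ranges$y[1] + 8.1 * pl$delta_s["y"])
  o2 <- o1 + c(pl$delta_s["x"], 0)  # shift by one tile pitch in x
  r1 <- pf_rates(pl, o1); r2 <- pf_rates(pl, o2)
  # tile (i+1, j) under o2 sees what tile (i, j) saw under o1
  for (iy in c(3, 9, 15)) for (ix in c(3, 8, 14)) {
    t1 <- which(pl$centers[, 1] == ix - 0.5 & pl$centers[, 2] == iy - 0.5)
    t2 <- which(pl$centers[, 1] == ix + 0.5 & pl$centers[, 2] == iy - 0.5)
    expect_equal(r2[t2], r1[t1], tolerance = 1e-9)
  }
})

test_that("connectivity respects the per-type wiring rules", {
  cfg <- cerac_config("mountain_car")
  pl <- build_pf_plane(cfg)
  set.seed(33)
  conn <- build_connectivity(pl, n_pc = 20L, n_groups = 2L,
                             cfg$connectivity)
  bc_g <- attr(conn, "bc_group"); pc_g <- attr(conn, "pc_group")

  # PC-PC: exactly the 2 * 10 * 10 cross-group edges, none within group
  expect_identical(length(conn$pc_pc$pre), 200L)
  expect_true(all(pc_g[conn$pc_pc$pre] != pc_g[conn$pc_pc$post]))
  # group restrictions hold exactly
  expect_true(all(bc_g[conn$bc_bc$pre] != bc_g[conn$bc_bc$post]))
  expect_true(all(bc_g[conn$bc_pc$pre] == pc_g[conn$bc_pc$post]))
  expect_true(all(pc_g[conn$pc_bc$pre] == bc_g[conn$pc_bc$post]))
  # no autapses in the recurrent rings
  expect_false(any(conn$bc_bc$pre == conn$bc_bc$post))

  # binomial expectations within 4 sigma (counts over all edges)
  check_count <- function(g, n_cand, p) {
    mu <- n_cand * p
    expect_lt(abs(length(g$pre) - mu), 4 * sqrt(mu * (1 - p)))
  }
  check_count(conn$pf_bc, 32400 * 324, 0.5)
  check_count(conn$pf_pc, 32400 * 20, 0.5)
  check_count(conn$sc_pc, 324 * 20, 0.5)
  check_count(conn$bc_bc, 162 * 162 * 2, 0.3)
  check_count(conn$pc_bc, 10 * 162 * 2, 0.8)
  # PF-SC receptive window: 3 tile rows x full width (2 rows at the
  # frame edges), p = 0.1
  n_cand_pfsc <- sum(vapply(seq_len(324), function(j) {
    iy <- (j - 1) %/% 18 + 1
    length(max(1, iy - 1):min(18, iy + 1)) * 18 * 100
  }, 1))
  check_count(conn$pf_sc, n_cand_pfsc, 0.1)
  # and every PF-SC edge lies inside the stated row window
  sc_row <- (conn$pf_sc$post - 1) %/% 18 + 1
  pf_row <- ((conn$pf_sc$pre - 1) %/% 100) %/% 18 + 1
  expect_true(all(abs(sc_row - pf_row) <= 1))
})

test_that("same seed reproduces identical adjacency; PC-DCN is identity", {
  cfg <- cerac_config("eyeblink")
  n1 <- build_network(cfg, seed = 5)
  n2 <- build_network(cfg, seed = 5)
  for (nm in names(n1$conn)) {
    expect_identical(n1$conn[[nm]]$pre, n2$conn[[nm]]$pre)
    expect_identical(n1$conn[[nm]]$post, n2$conn[[nm]]$post)
  }
  expect_identical(unname(n1$pc_dcn[, "pc"]), unname(n1$pc_dcn[, "dcn"]))
  expect_identical(nrow(n1$pc_dcn), 20L)
})

test_that("synaptic current filter: jump, decay, sign and zero cases", {
  g <- list(name = "pf_pc", pre_pop = "PF", post_pop = "PC",
            n_pre = 3L, n_post = 2L, pre = c(1L, 2L), post = c(1L, 2L),
            w = NULL, sc = 5.0, tau_c = 8.3, plastic = TRUE)
  class(g) <- "synapse_group"
  groups <- list(pf_pc = g)
  fl <- init_current_filters(groups)
  w <- list(pf_pc = c(0.8, 0.4))
  # spike on edge 1 (pre 1 -> post 1, w = 0.8)
  st <- step_synaptic_currents(groups, fl, list(PF = c(TRUE, FALSE, FALSE)),
                               1, w)
  expect_equal(st$I$PC, 5.0 * c(0.8, 0))
  for (k in 1:10)
    st <- step_synaptic_currents(groups, st$filters,
                                 list(PF = rep(FALSE, 3)), 1, w)
  expect_equal(st$I$PC[1], 5.0 * 0.8 * exp(-10 / 8.3), tolerance = 1e-12)

  # all weights zero -> no current; inhibitory sc only decreases I
  st0 <- step_synaptic_currents(groups, fl, list(PF = c(TRUE, TRUE, FALSE)),
                                1, list(pf_pc = c(0, 0)))
  expect_equal(st0$I$PC, c(0, 0))
  gi <- g; gi$sc <- -1; gi$plastic <- FALSE; gi$w <- 1
  sti <- step_synaptic_currents(list(pf_pc = gi), fl,
                                list(PF = c(TRUE, TRUE, FALSE)), 1)
  expect_true(all(sti$I$PC <= 0))
})
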