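#' Build the parallel-fiber plane
#'
#' Discretizes a rectangular 2-D state space into an `nx` x `ny` grid of
#' tiles plus a frame of `margin` tiles on every side, each tile holding
#' `pfs_per_tile` Poisson parallel-fiber generators with a shared Gaussian
#' receptive field centered on the tile. The margin frame keeps the summed
#' PF drive approximately constant when the observation sits at the edge of
#' the state range.
#'
#' Tile centers live on the half-integer lattice in *tile units*: interior
#' tile (i, j), i in 1..nx, is centered at (i - 0.5, j - 0.5); margin tiles
#' extend the lattice beyond [0, nx] x [0, ny]. An observation is mapped to
#' tile units as `(obs - s_min) / delta_s` with `delta_s = (s_max - s_min) / n`
#' per axis, after clamping to the state range.
#'
#' @param config a [cerac_config()] (its `plane` and `env` sections are
#'   used), or `NULL` to pass the geometry explicitly.
#' @param nx,ny,margin,pfs_per_tile,rho_pf,sigma,state_ranges explicit
#'   geometry, used when `config` is `NULL`. `state_ranges` is
#'   `list(x = c(min, max), y = c(min, max))`.
#' @return An object of class `pf_plane` with fields `nx, ny, margin, wx,
#'   wy, n_tiles, n_pf, pfs_per_tile, centers` (n_tiles x 2 matrix, tile
#'   units), `delta_s`, `state_ranges`, `rho_pf`, `sigma`.
#' @export
#' @examples
#' pl <- build_pf_plane(cerac_config("mountain_car"))
#' pl$n_tiles   # 324
#' pl$n_pf      # 32400
build_pf_plane <- function(config = NULL, nx = 16L, ny = 16L, margin = 1L,
                           pfs_per_tile = 100L, rho_pf = 50, sigma = 0.5,
                           state_ranges = list(x = c(0, 1), y = c(0, 1))) {
  if (!is.null(config)) {
    p <- config$plane
    nx <- p$nx; ny <- p$ny; margin <- p$margin
    pfs_per_tile <- p$pfs_per_tile; rho_pf <- p$rho_pf; sigma <- p$sigma
    state_ranges <- task_state_ranges(config)
  }
  nx <- as.integer(nx); ny <- as.integer(ny); margin <- as.integer(margin)
  stopifnot(nx >= 1L, ny >= 1L, margin >= 0L, pfs_per_tile >= 1L)
  if (diff(state_ranges$x) <= 0 || diff(state_ranges$y) <= 0)
    stop("degenerate state range: max must exceed min on both axes")

  wx <- nx + 2L * margin
  wy <- ny + 2L * margin
  # tile id = (row - 1) * wx + col, row-major over y; centers in tile units
  col <- rep(seq_len(wx), times = wy)
  row <- rep(seq_len(wy), each = wx)
  centers <- cbind(x = col - margin - 0.5, y = row - margin - 0.5)

  delta_s <- c(x = diff(state_ranges$x) / nx, y = diff(state_ranges$y) / ny)

  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), margin = as.integer(margin),
    wx = wx, wy = wy,
    n_tiles = wx * wy, pfs_per_tile = as.integer(pfs_per_tile),
    n_pf = wx * wy * as.integer(pfs_per_tile),
    centers = centers, delta_s = delta_s, state_ranges = state_ranges,
    rho_pf = rho_pf, sigma = sigma
  ), class = "pf_plane")
}

task_state_ranges <- function(config) {
  if (config$task == "mountain_car") {
    list(x = config$env$x_range, y = config$env$v_range)
  } else {
    list(x = config$env$t_range, y = config$env$pe_range)
  }
}

#' Map a raw observation to tile-unit coordinates
#'
#' Clamps to the state range first, then rescales each axis by its tile
#' pitch so that the interior spans `[0, nx] x [0, ny]`.
#'
#' @param plane a [build_pf_plane()] object.
#' @param observation numeric length-2 vector in task units.
#' @return numeric length-2 vector in tile units.
#' @export
pf_tile_coords <- function(plane, observation) {
  stopifnot(length(observation) == 2L, all(is.finite(observation)))
  x <- min(max(observation[1], plane$state_ranges$x[1]), plane$state_ranges$x[2])
  y <- min(max(observation[2], plane$state_ranges$y[1]), plane$state_ranges$y[2])
  c((x - plane$state_ranges$x[1]) / plane$delta_s["x"],
    (y - plane$state_ranges$y[1]) / plane$delta_s["y"])
}

#' Per-tile parallel-fiber firing rates for an observation
#'
#' Each tile fires as an inhomogeneous Poisson generator at
#' `rho_pf / (2 pi sigma^2) * exp(-d^2 / (2 sigma^2))` where `d` is the
#' distance from the (clamped) observation to the tile center, measured in
#' tile units. All `pfs_per_tile` fibers of one tile share the tile's rate.
#'
#' @param plane a [build_pf_plane()] object.
#' @param observation numeric length-2 vector in task units.
#' @param per_fiber if `TRUE`, return the rate of every fiber
#'   (length `n_pf`, tiles blocked consecutively) instead of per tile.
#' @return numeric vector of rates in Hz (length `n_tiles`, or `n_pf`).
#' @export
#' @examples
#' pl <- build_pf_plane(cerac_config("mountain_car"))
#' max(pf_rates(pl, c(-0.5, 0)))  # ~ 50 / (2 * pi * 0.25) = 31.83 Hz
pf_rates <- function(plane, observation, per_fiber = FALSE) {
  o <- pf_tile_coords(plane, observation)
  d2 <- (plane$centers[, 1] - o[1])^2 + (plane$centers[, 2] - o[2])^2
  r <- plane$rho_pf / (2 * pi * plane$sigma^2) * exp(-d2 / (2 * plane$sigma^2))
  if (per_fiber) rep(r, each = plane$pfs_per_tile) else r
}

#' @export
print.pf_plane <- function(x, ...) {
  cat("<pf_plane> ", x$nx, "x", x$ny, " interior + margin ", x$margin,
      " -> ", x$n_tiles, " tiles, ", x$n_pf, " PFs\n", sep = "")
  invisible(x)
}
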