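#' Build all synapse groups of the microcircuit
#'
#' Realizes the wiring scheme stochastically, one connection type at a
#' time, using the current RNG state (seed with [set.seed()] for
#' reproducible adjacency):
#' \itemize{
#'  \item PF-SC: the SC sitting on tile (i, j) can receive from PFs on any
#'    column of the plane and on tile rows j-1..j+1 (clipped at the frame);
#'    each candidate edge is realized with p = 0.1. Plastic.
#'  \item PF-BC and PF-PC: from all tiles with p = 0.5; PF-BC weights are
#'    fixed at 1.0, PF-PC is plastic.
#'  \item SC-PC: all-to-all candidates with p = 0.5, fixed weight 0.03.
#'  \item BC-BC (p = 0.3) and PC-PC (p = 1.0): *cross-group* pairs only
#'    (the mutual "self-inhibition" of the two molecular-layer rings);
#'    no autapses exist because own-group pairs are excluded.
#'  \item BC-PC (p = 0.3) and PC-BC (p = 0.8): *same-group* pairs only.
#'  \item PC-DCN: deterministic one-to-one counterpart inhibition,
#'    realized through the DCN rate dynamics (see [step_dcn()]); the edge
#'    set is exposed as `pc_dcn` for inspection.
#' }
#' Scaling factors and current decay constants per connection type come
#' from the config (defaults per the published table). Edges of plastic
#' groups are stored sorted by (postsynaptic, presynaptic) index; this is
#' the canonical per-synapse order used by the plasticity state and the
#' returned weight deltas.
#'
#' @param plane a [build_pf_plane()] object.
#' @param n_pc number of Purkinje cells (DCN size equals it).
#' @param n_groups number of action groups (BC/PC/DCN are split evenly).
#' @param conn the `connectivity` section of a [cerac_config()].
#' @return named list of `synapse_group` lists with fields
#'   `name, pre_pop, post_pop, n_pre, n_post, pre, post, w, sc, tau_c,
#'   plastic`; `w` is a scalar for non-plastic groups.
#' @export
build_connectivity <- function(plane, n_pc = 20L, n_groups = 2L,
                               conn = cerac_config("mountain_car")$connectivity) {
  n_sc <- plane$n_tiles
  n_bc <- n_sc
  n_pf <- plane$n_pf
  npf_tile <- plane$pfs_per_tile
  bc_group <- group_labels(n_bc, n_groups)
  pc_group <- group_labels(n_pc, n_groups)

  groups <- list()

  # --- PF-SC: row-banded receptive window, by post (SC = its tile) ------
  pre_l <- vector("list", n_sc)
  for (j in seq_len(n_sc)) {
    iy <- (j - 1L) %/% plane$wx + 1L
    rows <- max(1L, iy - 1L):min(plane$wy, iy + 1L)
    tiles <- as.integer(outer(seq_len(plane$wx), (rows - 1L) * plane$wx, `+`))
    cand <- rep((tiles - 1L) * npf_tile, each = npf_tile) +
      seq_len(npf_tile)
    cand <- sort(cand)
    pre_l[[j]] <- cand[runif(length(cand)) < conn$pf_sc$p]
  }
  len <- lengths(pre_l)
  groups$pf_sc <- synapse_group("pf_sc", "PF", "SC", n_pf, n_sc,
                               pre = unlist(pre_l),
                               post = rep(seq_len(n_sc), len),
                               w = NULL, cfg = conn$pf_sc)

  # --- PF-BC: dense Bernoulli, generated presynaptic-major --------------
  groups$pf_bc <- bernoulli_group("pf_bc", "PF", "BC", n_pf, n_bc,
                                  conn$pf_bc, by = "pre")

  # --- PF-PC: plastic, canonical (post, pre) order ----------------------
  groups$pf_pc <- bernoulli_group("pf_pc", "PF", "PC", n_pf, n_pc,
                                  conn$pf_pc, by = "post")

  # --- SC-PC: all-to-all candidates (grouping ignored) ------------------
  groups$sc_pc <- bernoulli_group("sc_pc", "SC", "PC", n_sc, n_pc,
                                  conn$sc_pc, by = "post")

  # --- grouped molecular-layer rings ------------------------------------
  groups$bc_bc <- pair_group("bc_bc", "BC", "BC", bc_group, bc_group,
                             conn$bc_bc, same_group = FALSE)
  groups$bc_pc <- pair_group("bc_pc", "BC", "PC", bc_group, pc_group,
                             conn$bc_pc, same_group = TRUE)
  groups$pc_bc <- pair_group("pc_bc", "PC", "BC", pc_group, bc_group,
                             conn$pc_bc, same_group = TRUE)
  groups$pc_pc <- pair_group("pc_pc", "PC", "PC", pc_group, pc_group,
                             conn$pc_pc, same_group = FALSE)

  if (length(groups$pf_pc$pre) == 0L || any(tabulate(groups$pf_pc$post, n_pc) == 0L))
    warning("a PC has zero PF inputs; consider rebuilding with another seed")

  attr(groups, "bc_group") <- bc_group
  attr(groups, "pc_group") <- pc_group
  groups
}

group_labels <- function(n, n_groups) {
  stopifnot(n %% n_groups == 0L)
  rep(seq_len(n_groups), each = n %/% n_groups)
}

synapse_group <- function(name, pre_pop, post_pop, n_pre, n_post,
                          pre, post, w, cfg) {
  plastic <- isTRUE(cfg$plastic)
  structure(list(
    name = name, pre_pop = pre_pop, post_pop = post_pop,
    n_pre = as.integer(n_pre), n_post = as.integer(n_post),
    pre = as.integer(pre), post = as.integer(post),
    w = if (plastic) w else cfg$w,
    sc = cfg$sc, tau_c = cfg$tau_c, plastic = plastic
  ), class = "synapse_group")
}

# dense Bernoulli wiring over the full pre x post rectangle.
# by = "pre":  edges emitted presynaptic-major (pre ascending),
# by = "post": canonical (post, pre) order for plastic groups.
bernoulli_group <- function(name, pre_pop, post_pop, n_pre, n_post, cfg, by) {
  hits <- which(runif(n_pre * n_post) < cfg$p) - 1L
  if (by == "pre") {
    pre  <- hits %/% n_post + 1L
    post <- hits %%  n_post + 1L
  } else {
    post <- hits %/% n_pre + 1L
    pre  <- hits %%  n_pre + 1L
  }
  synapse_group(name, pre_pop, post_pop, n_pre, n_post, pre, post, NULL, cfg)
}

# wiring restricted to same-group or cross-group (pre, post) pairs
pair_group <- function(name, pre_pop, post_pop, pre_groups, post_groups,
                       cfg, same_group) {
  n_pre <- length(pre_groups); n_post <- length(post_groups)
  ok <- outer(post_groups, pre_groups,
              if (same_group) `==` else `!=`)  # n_post x n_pre
  if (identical(pre_pop, post_pop)) {
    diag_idx <- cbind(seq_len(n_post), seq_len(n_pre))
    ok[diag_idx] <- FALSE  # never an autapse (redundant for cross-group)
  }
  cand <- which(ok)  # column-major: post fast, pre slow
  sel <- cand[runif(length(cand)) < cfg$p] - 1L
  post <- sel %% n_post + 1L
  pre  <- sel %/% n_post + 1L
  o <- order(post, pre)
  synapse_group(name, pre_pop, post_pop, n_pre, n_post,
                pre[o], post[o], NULL, cfg)
}

#' @export
print.synapse_group <- function(x, ...) {
  cat("<synapse_group> ", x$name, ": ", length(x$pre), " edges ",
      x$pre_pop, "->", x$post_pop,
      ", sc = ", x$sc, ", tau_c = ", x$tau_c,
      if (x$plastic) ", plastic" else "", "\n", sep = "")
  invisible(x)
}

#' Reference synaptic-current step
#'
#' Pure-R implementation of the exponentially filtered synaptic currents:
#' each group keeps one filtered current per postsynaptic neuron; on every
#' step the filter decays with `tau_c` (exact exponential factor) and then
#' receives the summed weights of this step's presynaptic spikes; the
#' current read by a neuron is `sc * filter`. Spikes injected at step t
#' therefore affect the current from step t+1 on. This is the dense oracle
#' for the compiled engine's current pathway.
#'
#' @param groups list of `synapse_group`s.
#' @param filters named list of per-group numeric vectors (length
#'   `n_post`); create with [init_current_filters()].
#' @param spikes_by_pop named list of logical spike vectors keyed by
#'   population (`PF`, `SC`, `BC`, `PC`) for this step.
#' @param dt time step (ms).
#' @param weights named list of per-edge weights for plastic groups.
#' @return list with updated `filters` and `I` (named list of per-neuron
#'   current vectors per postsynaptic population).
#' @export
step_synaptic_currents <- function(groups, filters, spikes_by_pop, dt = 1,
                                   weights = list()) {
  I <- list()
  for (g in groups) {
    f <- filters[[g$name]] * exp(-dt / g$tau_c)
    sp <- spikes_by_pop[[g$pre_pop]]
    if (!is.null(sp) && any(sp)) {
      hit <- which(sp[g$pre])
      if (length(hit)) {
        ww <- if (g$plastic) weights[[g$name]][hit] else rep(g$w, length(hit))
        acc <- rowsum(ww, group = g$post[hit])
        inc <- numeric(g$n_post)
        inc[as.integer(rownames(acc))] <- acc[, 1]
        f <- f + inc
      }
    }
    filters[[g$name]] <- f
    contrib <- g$sc * f
    I[[g$post_pop]] <- if (is.null(I[[g$post_pop]])) contrib
                       else I[[g$post_pop]] + contrib
  }
  list(filters = filters, I = I)
}

#' @rdname step_synaptic_currents
#' @export
init_current_filters <- function(groups) {
  f <- lapply(groups, function(g) rep(0, g$n_post))
  names(f) <- vapply(groups, `[[`, "", "name")
  f
}
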