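#' Build the full cerebellar network for one task
#'
#' Assembles the PF plane, the SC/BC/PC/DCN populations with their action
#' groups, and every synapse group, and precomputes the presynaptic-major
#' index structures consumed by the compiled episode engine. With the
#' default 16 x 16 grid and margin 1 this yields 324 SCs, 324 BCs, 20 PCs,
#' 20 DCN cells and 32,400 PFs.
#'
#' @param config a [cerac_config()].
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first so the adjacency is reproducible bit-for-bit.
#' @return object of class `cerac_network`.
#' @export
#' @examples
#' net <- build_network(cerac_config("mountain_car"), seed = 1)
#' net$n_sc; net$n_pc
build_network <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  plane <- build_pf_plane(config)
  n_pc <- as.integer(config$populations$n_pc)
  n_groups <- as.integer(config$populations$n_groups)
  conn <- build_connectivity(plane, n_pc, n_groups, config$connectivity)

  net <- structure(list(
    config = config,
    plane = plane,
    n_sc = plane$n_tiles, n_bc = plane$n_tiles,
    n_pc = n_pc, n_dcn = n_pc, n_groups = n_groups,
    bc_group = attr(conn, "bc_group"),
    pc_group = attr(conn, "pc_group"),
    pc_dcn = cbind(pc = seq_len(n_pc), dcn = seq_len(n_pc)),
    params = list(SC = lif_params_from_config(config, "SC"),
                  BC = lif_params_from_config(config, "BC"),
                  PC = lif_params_from_config(config, "PC")),
    conn = conn,
    index = lapply(conn, function(g) csr_by_pre(g$pre, g$n_pre))
  ), class = "cerac_network")
  net$engine <- engine_pack(net)
  net
}

# flat, 0-based view of the network consumed by the compiled engine;
# built once per network so episodes only pass references
engine_pack <- function(net) {
  pl <- net$plane
  grp <- function(name) {
    g <- net$conn[[name]]
    ix <- net$index[[name]]
    out <- list(ptr = ix$ptr, sc = g$sc, tau_c = g$tau_c,
                plastic = g$plastic)
    if (g$plastic) {
      out$slot <- ix$ord - 1L          # CSR slot -> canonical synapse id
      out$post <- g$post - 1L          # canonical order
    } else {
      out$post_by_pre <- g$post[ix$ord] - 1L
      out$w <- g$w
    }
    out
  }
  list(
    plane = list(
      wx = pl$wx, wy = pl$wy, n_tiles = pl$n_tiles,
      npf_tile = pl$pfs_per_tile,
      cx = pl$centers[, 1], cy = pl$centers[, 2],
      sigma = pl$sigma, rho_pf = pl$rho_pf,
      nx = pl$nx, ny = pl$ny,
      xmin = pl$state_ranges$x[1], xmax = pl$state_ranges$x[2],
      ymin = pl$state_ranges$y[1], ymax = pl$state_ranges$y[2],
      dsx = unname(pl$delta_s["x"]), dsy = unname(pl$delta_s["y"])
    ),
    n_sc = net$n_sc, n_bc = net$n_bc, n_pc = net$n_pc,
    n_groups = net$n_groups,
    bc_group = net$bc_group - 1L, pc_group = net$pc_group - 1L,
    params = lapply(net$params, function(p) unlist(p[c(
      "Cm", "gL", "EL", "Uth", "Ureset", "Iext", "zeta", "tau_noise")])),
    groups = list(
      pf_sc = grp("pf_sc"), pf_bc = grp("pf_bc"), pf_pc = grp("pf_pc"),
      sc_pc = grp("sc_pc"), bc_bc = grp("bc_bc"), bc_pc = grp("bc_pc"),
      pc_bc = grp("pc_bc"), pc_pc = grp("pc_pc")
    )
  )
}

# presynaptic-major CSR: ptr has length n_pre + 1 (0-based offsets);
# ord maps CSR slots to the group's canonical edge positions (1-based).
csr_by_pre <- function(pre, n_pre) {
  ord <- order(pre, method = "radix")
  ptr <- c(0L, cumsum(tabulate(pre, n_pre)))
  list(ptr = as.integer(ptr), ord = as.integer(ord))
}

#' Initial plastic weight vectors for a network
#'
#' PF-SC starts at a scalar `w0`; PF-PC accepts either a scalar or one
#' value per action group (applied by the postsynaptic PC's group), which
#' the eyeblink task uses to bias the agent toward opening the eye.
#'
#' @param net a [build_network()] object.
#' @return list with numeric vectors `pf_sc` and `pf_pc` in the canonical
#'   (post, pre) edge order of the plastic groups.
#' @export
initial_weights <- function(net) {
  cfg <- net$config$plasticity
  w_sc <- rep(cfg$pf_sc$w0[1], length(net$conn$pf_sc$pre))
  w0pc <- cfg$pf_pc$w0
  if (length(w0pc) == 1L) {
    w_pc <- rep(w0pc, length(net$conn$pf_pc$pre))
  } else {
    stopifnot(length(w0pc) == net$n_groups)
    w_pc <- w0pc[net$pc_group[net$conn$pf_pc$post]]
  }
  list(pf_sc = w_sc, pf_pc = w_pc)
}

#' @export
print.cerac_network <- function(x, ...) {
  cat("<cerac_network> task:", x$config$task, "\n")
  cat("  populations: ", x$plane$n_pf, " PFs, ", x$n_sc, " SCs, ",
      x$n_bc, " BCs, ", x$n_pc, " PCs, ", x$n_dcn, " DCN (",
      x$n_groups, " action groups)\n", sep = "")
  for (g in x$conn)
    cat("  ", format(g$name, width = 6), length(g$pre), "edges\n")
  invisible(x)
}

#' Export / import adjacency as a plain-text edge list
#'
#' Writes one row per edge (`group`, `pre`, `post`) as gzip-compressed TSV
#' so a network realization can be archived with a run and re-checked.
#'
#' @param net a `cerac_network`.
#' @param file path (a `.tsv.gz` suffix is conventional).
#' @export
write_adjacency <- function(net, file) {
  df <- do.call(rbind, lapply(net$conn, function(g)
    data.frame(group = g$name, pre = g$pre, post = g$post)))
  con <- gzfile(file, "wt")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(file) {
  read.table(gzfile(file), header = TRUE, sep = "\t",
             stringsAsFactors = FALSE)
}
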