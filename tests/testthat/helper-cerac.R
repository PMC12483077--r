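# shared fixtures ------------------------------------------------------

# a small network configuration that keeps engine-level tests fast
tiny_config <- function(task = "mountain_car", ...) {
  cerac_config(task,
               plane = list(nx = 4L, ny = 4L, margin = 1L,
                            pfs_per_tile = 10L),
               populations = list(n_pc = 4L, n_groups = 2L),
               run = list(pre_ms = 50L, post_ms = 50L, t_max = 200L),
               ...)
}

# random spike-train fixture for the plasticity oracle comparisons:
# n_syn synapses onto n_post neurons, T steps, plus CF and value traces
random_plasticity_fixture <- function(T = 300L, n_post = 3L,
                                      syn_per_post = 2L,
                                      p_pre = 0.04, p_post = 0.06,
                                      p_cf = 0.01) {
  n_syn <- n_post * syn_per_post
  post_of <- rep(seq_len(n_post), each = syn_per_post)
  list(
    pre = matrix(runif(T * n_syn) < p_pre, T, n_syn),
    post_neuron = matrix(runif(T * n_post) < p_post, T, n_post),
    post_of = post_of,
    cf = ifelse(runif(T) < p_cf, 5, 0),
    V = as.numeric(stats::filter(rnorm(T, 0, 0.3), 0.9,
                                 method = "recursive"))
  )
}

expand_post <- function(fix) fix$post_neuron[, fix$post_of, drop = FALSE]
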