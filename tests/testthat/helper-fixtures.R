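# Hand-built minimal network states for exercising the plasticity rules
# without running the simulator.

# A network-like object with explicit positions, types, element counts and
# connectivity. K defaults to flat (autapse-free).
make_toy_net <- function(W, is_ex, A = NULL, D_ex = NULL, D_in = NULL,
                         K = NULL, pos = NULL, tau_vac = 10,
                         window_ms = 500) {
  n <- nrow(W)
  cfg <- msp_config("mini")
  cfg$growth$tau_vac <- tau_vac
  cfg$schedule$window_ms <- window_ms
  if (is.null(pos)) pos <- cbind(x = seq_len(n) * 150, y = rep(0, n))
  if (is.null(K)) { K <- matrix(1, n, n); diag(K) <- 0 }
  pop <- structure(list(
    n = n, n_ex = sum(is_ex), n_in = sum(!is_ex),
    pos = pos, nominal = pos,
    is_excitatory = is_ex,
    in_lpz = rep(FALSE, n)
  ), class = "msp_population")
  zero <- numeric(n)
  structure(list(
    config = cfg, pop = pop, K = K, W = W,
    A = if (is.null(A)) zero else A,
    D_ex = if (is.null(D_ex)) zero else D_ex,
    D_in = if (is.null(D_in)) zero else D_in,
    v = rep(cfg$neuron$v0, n), u = rep(cfg$neuron$u0, n),
    dr_ex = zero, dr_in = zero, ca = zero,
    last_spikes = integer(n), T = 0L, lesioned = FALSE
  ), class = "msp_network")
}

# A tiny configuration for fast end-to-end runs (not the study mini scale).
tiny_config <- function(...) {
  msp_config("mini",
             network.grid_nx = 4L, network.grid_ny = 4L, network.n_in = 4L,
             schedule.lpz_rect = c(150, 150, 300, 300),
             schedule.lesion_onset = 5L, schedule.total_updates = 10L,
             ...)
}
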