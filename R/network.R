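#' Create an empty network
#'
#' Initializes the full simulation state for a configuration: the neuron
#' population, the (fixed) distance-kernel matrix, zero connectivity, zero
#' synaptic elements, and resting electrical state. Networks are always
#' grown from scratch from this state.
#'
#' @param cfg an [msp_config()].
#' @return an object of class \code{msp_network}; a list holding the
#'   configuration, the population, the connectivity matrix \code{W}
#'   (\code{W[i, j]} = number of synapses from presynaptic \code{j} to
#'   postsynaptic \code{i}), continuous element counts \code{A},
#'   \code{D_ex}, \code{D_in}, the electrical state, the current update
#'   index \code{T} and the lesion flag.
#' @export
new_network <- function(cfg) {
  cfg <- validate_config(cfg)
  pop <- build_population(cfg)
  n <- pop$n
  net <- list(
    config = cfg,
    pop = pop,
    K = kernel_matrix(pop$pos, cfg$growth),
    W = matrix(0L, n, n),
    A = numeric(n), D_ex = numeric(n), D_in = numeric(n),
    v = rep(cfg$neuron$v0, n),
    u = rep(cfg$neuron$u0, n),
    dr_ex = numeric(n), dr_in = numeric(n),
    ca = numeric(n),
    last_spikes = integer(n),
    T = 0L,
    lesioned = FALSE
  )
  class(net) <- "msp_network"
  net
}

#' @export
print.msp_network <- function(x, ...) {
  cat(sprintf("<msp_network> %d neurons, T=%d, %d synapses%s\n",
              x$pop$n, x$T, sum(x$W),
              if (x$lesioned) " (lesioned)" else ""))
  cat(sprintf("  mean calcium %.3f (LPZ %.3f)\n",
              mean(x$ca), mean(x$ca[x$pop$in_lpz])))
  invisible(x)
}

# Bound synaptic elements implied by W, per neuron and class.
# Outgoing synapses of j occupy axonal elements of j; incoming excitatory
# (inhibitory) synapses of i occupy excitatory (inhibitory) dendritic
# elements of i.
bound_counts <- function(net) {
  ex <- net$pop$is_excitatory
  list(
    A    = colSums(net$W),
    D_ex = rowSums(net$W[, ex, drop = FALSE]),
    D_in = rowSums(net$W[, !ex, drop = FALSE])
  )
}

# Vacant (unbound) integer element counts: floor(capacity) - bound,
# never negative.
vacant_counts <- function(net) {
  b <- bound_counts(net)
  list(
    A    = pmax(0, floor(net$A)    - b$A),
    D_ex = pmax(0, floor(net$D_ex) - b$D_ex),
    D_in = pmax(0, floor(net$D_in) - b$D_in)
  )
}

#' Write a connectivity snapshot as an edge list
#'
#' Writes the directed multiplicity matrix as a plain-text edge list with
#' columns \code{src,dst,count} (0-based neuron ids, one row per connected
#' ordered pair).
#'
#' @param W integer connectivity matrix, \code{W[i, j]} = synapses j -> i.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(W, path) {
  idx <- which(W > 0, arr.ind = TRUE)
  df <- data.frame(src = idx[, 2] - 1L, dst = idx[, 1] - 1L,
                   count = W[idx])
  df <- df[order(df$src, df$dst), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a connectivity edge list
#'
#' Inverse of [write_edge_list()]; used to re-analyze stored snapshots with
#' the topology functions.
#'
#' @param path edge-list file with columns \code{src,dst,count}.
#' @param n number of neurons (matrix dimension).
#' @return integer connectivity matrix.
#' @export
read_edge_list <- function(path, n) {
  df <- utils::read.csv(path)
  W <- matrix(0L, n, n)
  W[cbind(df$dst + 1L, df$src + 1L)] <- as.integer(df$count)
  W
}
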