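#' Excitatory graph view of a network
#'
#' Topology is assessed on the excitatory-to-excitatory subgraph only:
#' nodes are the excitatory neurons, edges carry the synapse multiplicity
#' \code{W}, and the length of an edge is \code{1/W} (more synapses =
#' shorter). Carries the LPZ/intact partition of the excitatory nodes.
#'
#' @param x an \code{msp_network}, or an integer connectivity matrix
#'   already restricted to excitatory neurons.
#' @param lpz logical LPZ membership of the excitatory nodes (required
#'   when \code{x} is a matrix).
#' @return an object of class \code{msp_graph}: list with \code{W}
#'   (\code{W[i, j]} = synapses j -> i), \code{lpz}, \code{n}.
#' @export
graph_view <- function(x, lpz = NULL) {
  if (inherits(x, "msp_network")) {
    ex <- x$pop$is_excitatory
    W <- x$W[ex, ex, drop = FALSE]
    lpz <- x$pop$in_lpz[ex]
  } else {
    W <- x
    if (is.null(lpz)) lpz <- rep(FALSE, nrow(W))
  }
  structure(list(W = W, lpz = lpz, n = nrow(W)), class = "msp_graph")
}

# igraph representation: edge from presynaptic to postsynaptic neuron,
# edge attribute `weight` = multiplicity. Our W is column-presynaptic,
# so the adjacency passed to igraph is t(W).
as_igraph <- function(view) {
  igraph::graph_from_adjacency_matrix(t(view$W), mode = "directed",
                                      weighted = TRUE)
}

#' Weighted shortest-path distances
#'
#' All-pairs (or restricted) shortest-path distances over the directed
#' excitatory graph with edge lengths \code{1/W}; unreachable pairs are
#' \code{Inf} and the diagonal is 0.
#'
#' @param view an [graph_view()].
#' @param sources,targets node index vectors (default: all nodes).
#' @return distance matrix (sources x targets).
#' @export
sp_distances <- function(view, sources = NULL, targets = NULL) {
  n <- view$n
  if (is.null(sources)) sources <- seq_len(n)
  if (is.null(targets)) targets <- seq_len(n)
  g <- as_igraph(view)
  w <- igraph::E(g)$weight
  igraph::distances(g, v = sources, to = targets, mode = "out",
                    weights = if (length(w)) 1 / w else NULL)
}

#' Weighted characteristic path length
#'
#' Mean shortest-path distance over ordered pairs (i to j, i != j) with
#' edge lengths \code{1/W}. Unreachable pairs are excluded from the mean
#' and their fraction is reported alongside; when no pair is reachable the
#' value is undefined (\code{NA}) rather than an error. Restricting
#' \code{from}/\code{to} gives the between-region variants (e.g. average
#' path length from intact-zone neurons to LPZ neurons).
#'
#' @param view an [graph_view()].
#' @param from,to node index vectors (default: all nodes).
#' @return list with \code{L}, \code{unreachable} (fraction of ordered
#'   pairs with no path), and \code{defined}.
#' @export
characteristic_path_length <- function(view, from = NULL, to = NULL) {
  if (is.null(from)) from <- seq_len(view$n)
  if (is.null(to)) to <- seq_len(view$n)
  D <- sp_distances(view, from, to)
  same <- outer(from, to, "==")
  d <- D[!same]
  if (!length(d)) return(list(L = NA_real_, unreachable = NA_real_,
                              defined = FALSE))
  finite <- is.finite(d)
  list(L = if (any(finite)) mean(d[finite]) else NA_real_,
       unreachable = mean(!finite),
       defined = any(finite))
}

#' Weighted directed clustering coefficient (Fagiolo)
#'
#' Per-node clustering for weighted directed graphs: weights are
#' normalized by the maximum weight, the geometric-mean (cube-root)
#' triangle intensity is accumulated over all directed triangles through a
#' node, and normalized by the number of possible triangles,
#' \eqn{k^{tot}_i (k^{tot}_i - 1) - 2 k^{recip}_i}. Nodes with fewer than
#' two neighbors score 0.
#'
#' @param view an [graph_view()].
#' @param subset node indices to average over (default: all).
#' @return list with per-node \code{Ci} and subset mean \code{C}.
#' @export
clustering_coefficient <- function(view, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(view$n)
  Wd <- t(view$W)                      # Wd[i, j] = weight of edge i -> j
  mx <- max(Wd)
  Ci <- numeric(view$n)
  if (mx > 0) {
    Wn <- (Wd / mx)^(1 / 3)
    S <- Wn + t(Wn)
    cyc3 <- diag(S %*% S %*% S) / 2
    A <- (Wd > 0) + 0
    k_tot <- rowSums(A) + colSums(A)
    k_recip <- diag(A %*% A)
    denom <- k_tot * (k_tot - 1) - 2 * k_recip
    ok <- denom > 0
    Ci[ok] <- cyc3[ok] / denom[ok]
  }
  list(Ci = Ci, C = mean(Ci[subset]))
}

#' Erdos-Renyi null model
#'
#' Reference clustering and path length for the small-world normalization:
#' the same number of synapses is placed uniformly at random over ordered
#' non-self node pairs (multiplicities arise by collision, mirroring the
#' multiplicity matrix of the data), and \code{C} and \code{L} are
#' averaged over replicates.
#'
#' @param n_nodes number of nodes.
#' @param n_synapses total synapse count to place.
#' @param replicates number of random graphs (default 10).
#' @return list with \code{C_rand}, \code{L_rand}, their SDs over
#'   replicates, and \code{defined} (FALSE when \code{L} was undefined in
#'   every replicate, e.g. zero synapses).
#' @export
er_null <- function(n_nodes, n_synapses, replicates = 10L) {
  stopifnot(n_synapses >= 0)
  Cs <- Ls <- numeric(replicates)
  for (r in seq_len(replicates)) {
    W <- er_graph(n_nodes, n_synapses)
    v <- graph_view(W)
    Cs[r] <- clustering_coefficient(v)$C
    Ls[r] <- characteristic_path_length(v)$L
  }
  ok <- is.finite(Ls)
  list(C_rand = mean(Cs), C_sd = stats::sd(Cs),
       L_rand = if (any(ok)) mean(Ls[ok]) else NA_real_,
       L_sd = if (any(ok)) stats::sd(Ls[ok]) else NA_real_,
       defined = any(ok))
}

# One ER multigraph with exactly n_synapses synapses on ordered non-self
# pairs.
er_graph <- function(n_nodes, n_synapses) {
  W <- matrix(0L, n_nodes, n_nodes)
  if (n_synapses > 0 && n_nodes > 1) {
    slots <- which(diag(n_nodes) == 0)
    picks <- slots[sample.int(length(slots), n_synapses, replace = TRUE)]
    tab <- tabulate(picks, nbins = n_nodes * n_nodes)
    W <- matrix(as.integer(tab), n_nodes, n_nodes)
  }
  W
}

#' Small-world index
#'
#' \eqn{S = \gamma/\lambda} with \eqn{\gamma = C/C^{rand}} and
#' \eqn{\lambda = L/L^{rand}}; values above 1 indicate small-world
#' structure (more clustered than random at comparable path length).
#'
#' @param C,L observed clustering and path length.
#' @param C_rand,L_rand null-model values.
#' @return list with \code{gamma}, \code{lambda}, \code{S} (NA when a
#'   denominator is zero or undefined).
#' @export
small_world <- function(C, L, C_rand, L_rand) {
  gamma <- if (isTRUE(C_rand > 0)) C / C_rand else NA_real_
  lambda <- if (isTRUE(L_rand > 0)) L / L_rand else NA_real_
  list(gamma = gamma, lambda = lambda,
       S = if (is.finite(gamma) && is.finite(lambda) && lambda != 0)
         gamma / lambda else NA_real_)
}

#' Betweenness centrality (Brandes, weighted directed)
#'
#' Per-node betweenness over weighted directed shortest paths (lengths
#' \code{1/W}), counting the multiplicity of equal-length paths:
#' \eqn{BC(i) = \sum_{k \ne i \ne l} \sigma_{kl}(i)/\sigma_{kl}}. Also
#' returns the global sum and the means over the LPZ and intact node sets.
#'
#' @param view an [graph_view()].
#' @return list with \code{bc} (per node), \code{global} (sum),
#'   \code{lpz_mean}, \code{intact_mean}.
#' @export
betweenness_centrality <- function(view) {
  g <- as_igraph(view)
  w <- igraph::E(g)$weight
  bc <- igraph::betweenness(g, directed = TRUE,
                            weights = if (length(w)) 1 / w else NULL)
  bc <- as.numeric(bc)
  list(bc = bc, global = sum(bc),
       lpz_mean = if (any(view$lpz)) mean(bc[view$lpz]) else NA_real_,
       intact_mean = if (any(!view$lpz)) mean(bc[!view$lpz]) else NA_real_)
}

#' Local efficiency
#'
#' For each node, the neighbors (union of in- and out-neighbors) are taken
#' as an induced subgraph \emph{excluding the node itself}, and the mean
#' inverse shortest-path length over ordered neighbor pairs is computed
#' with the weighted edge lengths \code{1/W}. Nodes with fewer than two
#' neighbors score 0. High local efficiency means a node's neighborhood
#' stays well connected without the node.
#'
#' @param view an [graph_view()].
#' @param subset node indices to average over (default: all).
#' @return list with per-node \code{Ei} and subset mean \code{E_loc}.
#' @export
local_efficiency <- function(view, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(view$n)
  A <- view$W > 0
  Ei <- numeric(view$n)
  for (i in seq_len(view$n)) {
    nb <- which(A[, i] | A[i, ])       # out- or in-neighbor of i
    nb <- setdiff(nb, i)
    if (length(nb) < 2) next
    sub <- graph_view(view$W[nb, nb, drop = FALSE])
    D <- sp_distances(sub)
    inv <- 1 / D
    diag(inv) <- 0
    Ei[i] <- sum(inv) / (length(nb) * (length(nb) - 1))
  }
  list(Ei = Ei, E_loc = mean(Ei[subset]))
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over ordered pairs, with
#' \code{1/Inf = 0} so disconnected pairs contribute neutrally — the
#' reason this measure is preferred over path length for sparse or
#' fragmented graphs. \code{subset} restricts the source nodes (the
#' per-region variant); targets always range over the whole graph.
#'
#' @param view an [graph_view()].
#' @param subset source node indices (default: all).
#' @return mean efficiency (0 for a single node).
#' @export
global_efficiency <- function(view, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(view$n)
  if (view$n < 2) return(0)
  D <- sp_distances(view, subset, seq_len(view$n))
  inv <- 1 / D
  inv[outer(subset, seq_len(view$n), "==")] <- 0
  mean(rowSums(inv) / (view$n - 1))
}

#' Degree distributions by region
#'
#' Multiplicity-weighted in-degree (total incoming synapses) and
#' out-degree (total outgoing synapses) histograms for the LPZ and intact
#' node sets, with bin edges shared across regions so the distributions
#' are directly comparable.
#'
#' @param view an [graph_view()].
#' @param n_bins number of histogram bins.
#' @param breaks optional explicit bin edges (shared across regions and,
#'   if supplied consistently, across time points).
#' @return list with \code{in_degree}, \code{out_degree} (per node),
#'   \code{breaks}, and per-region count matrices \code{in_hist},
#'   \code{out_hist} (rows lpz/intact).
#' @export
degree_distributions <- function(view, n_bins = 20L, breaks = NULL) {
  in_deg <- rowSums(view$W)
  out_deg <- colSums(view$W)
  if (is.null(breaks)) {
    hi <- max(in_deg, out_deg, 1)
    breaks <- seq(0, hi, length.out = n_bins + 1L)
  }
  hist_counts <- function(x) {
    if (!length(x)) return(numeric(length(breaks) - 1L))
    x <- pmin(x, max(breaks))
    graphics::hist(x, breaks = breaks, plot = FALSE, right = TRUE,
                   include.lowest = TRUE)$counts
  }
  regions <- list(lpz = view$lpz, intact = !view$lpz)
  list(in_degree = in_deg, out_degree = out_deg, breaks = breaks,
       in_hist = t(vapply(regions, function(m) hist_counts(in_deg[m]),
                          numeric(length(breaks) - 1L))),
       out_hist = t(vapply(regions, function(m) hist_counts(out_deg[m]),
                           numeric(length(breaks) - 1L))))
}

#' Full topology record
#'
#' Evaluates the whole battery on one graph: characteristic path length
#' and Fagiolo clustering, their Erdos-Renyi normalizations gamma and
#' lambda and the small-world index S, global and per-region betweenness
#' centrality, local and global efficiency (global and per region), and
#' the between-region path lengths.
#'
#' @param view an [graph_view()].
#' @param replicates Erdos-Renyi replicates for the normalization.
#' @return named list of scalar metrics.
#' @export
topology_record <- function(view, replicates = 10L) {
  lpz <- which(view$lpz); intact <- which(!view$lpz)
  Lc <- characteristic_path_length(view)
  Cc <- clustering_coefficient(view)
  null <- er_null(view$n, sum(view$W), replicates)
  sw <- small_world(Cc$C, Lc$L, null$C_rand, null$L_rand)
  bc <- betweenness_centrality(view)
  el <- local_efficiency(view)
  list(
    L = Lc$L, L_unreachable = Lc$unreachable, C = Cc$C,
    C_rand = null$C_rand, L_rand = null$L_rand,
    gamma = sw$gamma, lambda = sw$lambda, S = sw$S,
    BC_global = bc$global, BC_lpz_mean = bc$lpz_mean,
    BC_intact_mean = bc$intact_mean,
    E_loc = el$E_loc,
    E_loc_lpz = if (length(lpz)) mean(el$Ei[lpz]) else NA_real_,
    E_loc_intact = if (length(intact)) mean(el$Ei[intact]) else NA_real_,
    E_glob = global_efficiency(view),
    E_glob_lpz = if (length(lpz)) global_efficiency(view, lpz) else NA_real_,
    E_glob_intact = if (length(intact))
      global_efficiency(view, intact) else NA_real_,
    L_intact_to_lpz = if (length(lpz) && length(intact))
      characteristic_path_length(view, intact, lpz)$L else NA_real_,
    L_lpz_to_intact = if (length(lpz) && length(intact))
      characteristic_path_length(view, lpz, intact)$L else NA_real_
  )
}
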