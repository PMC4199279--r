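#' Activity-dependent element growth rate
#'
#' Gaussian growth curve for the continuous number of synaptic elements as
#' a function of the calcium trace:
#' \deqn{dz/dt = \nu\,(2 e^{-((Ca - \xi)/\zeta)^2} - 1)}
#' with \eqn{\xi = (\eta + \epsilon)/2} and
#' \eqn{\zeta = (\eta - \epsilon)/(2\sqrt{\ln 2})}, so that the curve
#' crosses zero exactly at the minimum calcium \eqn{\eta} for element
#' formation and at the homeostatic set-point \eqn{\epsilon}: elements are
#' retracted below \eqn{\eta} and above \eqn{\epsilon}, grown in between
#' (fastest, at rate \eqn{+\nu}, at the midpoint), and the rate tends to
#' \eqn{-\nu} for very high activity. When the homeostatic-range variant is
#' active (\code{use_range}, the default), the rate is exactly 0 for
#' calcium inside \code{[eps_lo, eps_hi]}, which stops rewiring once
#' neurons are close to the set-point.
#'
#' @param ca calcium value(s), >= 0.
#' @param kind \code{"axonal"} (uses \code{eta_A}) or \code{"dendritic"}
#'   (uses \code{eta_D}).
#' @param g growth parameter list (see \code{msp_config()$growth}).
#' @return dz/dt in elements per ms, same length as \code{ca}.
#' @examples
#' g <- msp_config("full")$growth
#' growth_rate(0.55, "axonal", g)  # peak: +1e-4
#' growth_rate(0.70, "axonal", g)  # inside the homeostatic range: 0
#' @export
growth_rate <- function(ca, kind = c("axonal", "dendritic"), g) {
  kind <- match.arg(kind)
  eta <- if (kind == "axonal") g$eta_A else g$eta_D
  xi <- (eta + g$eps_center) / 2
  zeta <- (eta - g$eps_center) / (2 * sqrt(log(2)))
  rate <- g$nu * (2 * exp(-((ca - xi) / zeta)^2) - 1)
  if (isTRUE(g$use_range)) rate[ca >= g$eps_lo & ca <= g$eps_hi] <- 0
  rate
}

#' Advance the continuous element counts over one update
#'
#' One Euler step of the growth curve per connectivity update (rate times
#' the electrical window length), clamped at zero, followed by spontaneous
#' decay of the vacant elements: every whole vacant element a neuron holds
#' (integer part of the count in excess of the bound synapses) disappears
#' independently with probability \code{1 - exp(-1/tau_vac)} per update,
#' i.e. a vacant element that is not used for synapse formation lives
#' \code{tau_vac} connectivity updates on average. For large vacancy pools
#' this converges to the pool shrinking by the factor
#' \code{exp(-1/tau_vac)} per update; for a lone vacant element it gives
#' the element its proper finite lifetime instead of dissolving it before
#' the next formation step can see it. Fractional growth progress toward
#' the next element is never eroded, so elements can accumulate from zero
#' even though the per-update growth increment is far below one.
#'
#' @param net an \code{msp_network} whose calcium is current (i.e. after
#'   [simulate_window()]).
#' @return the network with updated \code{A}, \code{D_ex}, \code{D_in}.
#' @export
integrate_elements <- function(net) {
  g <- net$config$growth
  win <- net$config$schedule$window_ms
  b <- bound_counts(net)
  step <- function(z, kind, bound) {
    z <- pmax(0, z + growth_rate(net$ca, kind, g) * win)
    vac_int <- pmax(0, floor(z) - bound)
    lost <- stats::rbinom(length(z), vac_int, 1 - exp(-1 / g$tau_vac))
    z - lost
  }
  net$A    <- step(net$A,    "axonal",    b$A)
  net$D_ex <- step(net$D_ex, "dendritic", b$D_ex)
  net$D_in <- step(net$D_in, "dendritic", b$D_in)
  net
}

#' Distance kernel between two neurons
#'
#' Likelihood factor that a presynaptic neuron connects to a postsynaptic
#' neuron at all, as a function of their Euclidean distance. The Gaussian
#' flavor \eqn{K = e^{-d^2/\sigma^2}} favors local wiring and yields
#' small-world networks; the flat flavor (\eqn{K = 1}) yields random
#' networks. Autapses are excluded (\eqn{K = 0} for \eqn{i = j}) in both
#' flavors. The kernel depends on positions only and is fixed for the
#' whole simulation.
#'
#' @param pos_i,pos_j coordinate pairs (um) of post- and presynaptic neuron.
#' @param g growth parameter list (\code{kernel}, \code{sigma}).
#' @param same_neuron is this the diagonal pair i == j?
#' @return kernel value in [0, 1].
#' @export
distance_kernel <- function(pos_i, pos_j, g, same_neuron = FALSE) {
  if (same_neuron) return(0)
  if (g$kernel == "flat") return(1)
  exp(-sum((pos_i - pos_j)^2) / g$sigma^2)
}

# Full kernel matrix K[i, j] (postsynaptic i, presynaptic j), zero diagonal.
kernel_matrix <- function(pos, g) {
  n <- nrow(pos)
  if (g$kernel == "flat") {
    K <- matrix(1, n, n)
  } else {
    d2 <- outer(pos[, 1], pos[, 1], "-")^2 + outer(pos[, 2], pos[, 2], "-")^2
    K <- exp(-d2 / g$sigma^2)
  }
  diag(K) <- 0
  K
}

#' Deletion probabilities for one neuron's synapses
#'
#' Probability that a given connection loses the next synapse when a neuron
#' has to shed surplus synapses of one class: each synapse has an equal
#' chance, so a connection's probability is its multiplicity divided by the
#' neuron's total multiplicity in that class. Four classes exist per
#' neuron: outgoing synapses (normalized over all of the presynaptic
#' neuron's targets; the sign is the neuron's own type) and incoming
#' excitatory or inhibitory synapses (normalized over the postsynaptic
#' neuron's afferents of that sign).
#'
#' @param W connectivity matrix.
#' @param neuron neuron index.
#' @param direction \code{"incoming"} or \code{"outgoing"}.
#' @param sign for incoming synapses, \code{"excitatory"} or
#'   \code{"inhibitory"} (the presynaptic type); ignored for outgoing.
#' @param is_ex logical vector of neuron types.
#' @return named numeric vector of probabilities (names = partner indices),
#'   summing to 1.
#' @export
deletion_probabilities <- function(W, neuron, direction = c("incoming", "outgoing"),
                                   sign = c("excitatory", "inhibitory"),
                                   is_ex) {
  direction <- match.arg(direction)
  if (direction == "outgoing") {
    w <- W[, neuron]
  } else {
    sign <- match.arg(sign)
    mask <- if (sign == "excitatory") is_ex else !is_ex
    w <- ifelse(mask, W[neuron, ], 0)
  }
  keep <- which(w > 0)
  if (!length(keep))
    stop("neuron ", neuron, " has no ", direction, " synapses of that class",
         call. = FALSE)
  p <- w[keep] / sum(w[keep])
  names(p) <- keep
  p
}

#' Delete surplus synapses
#'
#' When a neuron holds fewer integer elements (floor of the continuous
#' count) than synapses bound to them, the surplus synapses are removed.
#' Within each class the synapses to drop are drawn uniformly without
#' replacement over the neuron's synapse units, i.e. each connection loses
#' synapses in proportion to its multiplicity and never more than it has.
#' The partner's complementary element survives and becomes vacant.
#' Classes are processed in order: outgoing excitatory, outgoing
#' inhibitory, incoming excitatory, incoming inhibitory (counts are
#' re-evaluated as deletions proceed).
#'
#' @param net an \code{msp_network} with current element counts.
#' @return the network with a pruned \code{W}.
#' @export
delete_surplus <- function(net) {
  ex <- net$pop$is_excitatory
  capA <- floor(net$A); capDex <- floor(net$D_ex); capDin <- floor(net$D_in)

  drop_units <- function(w, surplus) {
    # uniform without replacement over synapse units of one class
    units <- rep(seq_along(w), w)
    picked <- units[sample.int(length(units), surplus)]
    tabulate(picked, nbins = length(w))
  }

  for (j in which(ex)) {                       # outgoing excitatory
    surplus <- sum(net$W[, j]) - capA[j]
    if (surplus > 0) net$W[, j] <- net$W[, j] - drop_units(net$W[, j], surplus)
  }
  for (j in which(!ex)) {                      # outgoing inhibitory
    surplus <- sum(net$W[, j]) - capA[j]
    if (surplus > 0) net$W[, j] <- net$W[, j] - drop_units(net$W[, j], surplus)
  }
  for (i in seq_len(net$pop$n)) {              # incoming excitatory
    w <- ifelse(ex, net$W[i, ], 0L)
    surplus <- sum(w) - capDex[i]
    if (surplus > 0) net$W[i, ] <- net$W[i, ] - drop_units(w, surplus)
  }
  for (i in seq_len(net$pop$n)) {              # incoming inhibitory
    w <- ifelse(ex, 0L, net$W[i, ])
    surplus <- sum(w) - capDin[i]
    if (surplus > 0) net$W[i, ] <- net$W[i, ] - drop_units(w, surplus)
  }
  net
}

#' Synapse-formation probabilities for one sign class
#'
#' Probability that the next potential synapse forms from presynaptic
#' \code{j} to postsynaptic \code{i}: the product of the two neurons'
#' vacant-element fractions, weighted by the distance kernel,
#' \deqn{P_{i,j} = \frac{A^{vac}_j D^{vac}_i}{\sum A^{vac} \sum D^{vac}} K_{i,j}.}
#' Sources are restricted to one sign (excitatory axons pair with
#' excitatory dendritic elements, inhibitory with inhibitory); targets
#' range over all neurons. Probabilities sum to at most 1 (exactly 1 only
#' under a flat kernel); the deficit is the chance that a formation try
#' yields nothing.
#'
#' @param A_vac per-neuron vacant axonal elements (entries of the wrong
#'   sign are ignored).
#' @param D_vac per-neuron vacant dendritic elements of the matching sign.
#' @param src_mask logical, which neurons are eligible sources (the sign
#'   class).
#' @param K kernel matrix.
#' @return matrix \code{P[i, j]} of formation probabilities (zero for
#'   ineligible pairs); all zeros when either vacancy pool is empty.
#' @export
formation_probabilities <- function(A_vac, D_vac, src_mask, K) {
  A_vac <- ifelse(src_mask, A_vac, 0)
  sum_A <- sum(A_vac)
  sum_D <- sum(D_vac)
  if (sum_A <= 0 || sum_D <= 0) return(matrix(0, length(A_vac), length(A_vac)))
  outer(D_vac / sum_D, A_vac / sum_A) * K
}

#' Form new synapses from vacant elements
#'
#' For each sign class, at most \eqn{M^{pot} = \min(\sum A^{vac},
#' \sum D^{vac})} formation tries are made. Each try draws a uniform number
#' against the cumulative formation probabilities (frozen at the start of
#' the update; not recomputed between tries): the connection whose
#' accumulated probability the draw just does not exceed receives a
#' synapse, and a draw beyond the total mass forms nothing. Every accepted
#' synapse consumes one vacant axonal element of the source and one vacant
#' dendritic element of the target; a try whose source or target has no
#' vacancy left is rejected. This keeps bound synapses within the integer
#' element capacity of every neuron after every update (and implies the
#' per-pair bound: a connection never gains more synapses in one update
#' than the smaller of the two partners' starting vacancies).
#'
#' @param net an \code{msp_network} after [delete_surplus()].
#' @return the network with newly formed synapses added to \code{W}.
#' @export
form_synapses <- function(net) {
  ex <- net$pop$is_excitatory
  vac <- vacant_counts(net)
  for (sign in c("ex", "in")) {
    src_mask <- if (sign == "ex") ex else !ex
    D_vac <- if (sign == "ex") vac$D_ex else vac$D_in
    A_src <- ifelse(src_mask, vac$A, 0)
    m_pot <- min(sum(A_src), sum(D_vac))
    if (m_pot < 1) next
    P <- formation_probabilities(vac$A, D_vac, src_mask, net$K)
    pos <- which(P > 0)
    if (!length(pos)) next
    cum <- cumsum(P[pos])
    i_idx <- (pos - 1L) %% net$pop$n + 1L
    j_idx <- (pos - 1L) %/% net$pop$n + 1L
    remA <- A_src
    remD <- D_vac
    gained <- integer(length(pos))
    for (try in seq_len(m_pot)) {
      u <- stats::runif(1)
      k <- findInterval(u, cum) + 1L
      if (k > length(pos)) next          # beyond the total mass: no synapse
      if (remA[j_idx[k]] < 1 || remD[i_idx[k]] < 1) next  # no vacancy left
      gained[k] <- gained[k] + 1L
      remA[j_idx[k]] <- remA[j_idx[k]] - 1
      remD[i_idx[k]] <- remD[i_idx[k]] - 1
    }
    formed <- gained > 0
    if (any(formed)) {
      net$W[cbind(i_idx[formed], j_idx[formed])] <-
        net$W[cbind(i_idx[formed], j_idx[formed])] + gained[formed]
    }
  }
  net
}

#' One full connectivity update
#'
#' The three-step cycle of the model: (1) electrical activity is simulated
#' for one window; (2) element counts are advanced from the window-end
#' calcium, and neurons holding more synapses than integer elements shed
#' the surplus; (3) vacant elements recombine into new synapses. The
#' update counter advances by one.
#'
#' @param net an \code{msp_network}.
#' @return the updated network.
#' @export
connectivity_update <- function(net) {
  net <- simulate_window(net)
  net <- integrate_elements(net)
  net <- delete_surplus(net)
  net <- form_synapses(net)
  net$T <- net$T + 1L
  net
}
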