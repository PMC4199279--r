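#' Single Euler step of the Izhikevich membrane equations
#'
#' Advances membrane potential \code{v} and recovery variable \code{u} by
#' one forward-Euler step of
#' \deqn{dv/dt = k_1 v^2 + k_2 v + k_3 - u + I,\qquad du/dt = a(bv - u)}
#' and applies the after-spike reset: if \code{v >= v_spike} after the
#' update, \code{v <- c}, \code{u <- u + d} and a spike is flagged.
#' Vectorized over neurons. This is the reference single-step operation;
#' whole windows run through the compiled integrator in
#' [simulate_window()].
#'
#' @param v,u membrane potential (mV) and recovery variable.
#' @param I_total total drive per neuron (mV/ms): synaptic plus external.
#' @param dt integration step (ms), > 0.
#' @param prm neuron parameter list (see \code{msp_config()$neuron}).
#' @return list with \code{v}, \code{u}, and logical \code{spiked}.
#' @export
membrane_step <- function(v, u, I_total, dt, prm) {
  stopifnot(dt > 0)
  vn <- v + dt * (prm$k1 * v^2 + prm$k2 * v + prm$k3 - u + I_total)
  un <- u + dt * prm$a * (prm$b * v - u)
  if (any(!is.finite(vn)) || any(!is.finite(un)))
    stop("non-finite membrane state at neuron index ",
         which(!is.finite(vn) | !is.finite(un))[1], call. = FALSE)
  spiked <- vn >= prm$v_spike
  vn[spiked] <- prm$c
  un[spiked] <- un[spiked] + prm$d
  list(v = vn, u = un, spiked = spiked)
}

#' Single step of the exponential synaptic filter
#'
#' Each postsynaptic drive decays by \code{exp(-dt/mu)} and is incremented
#' by \code{syn_strength} per synapse for every presynaptic spike
#' (excitatory drives and inhibitory drives tracked separately; the total
#' synaptic input is their difference). The spikes passed in are those of
#' the previous integration step (one-step transmission delay).
#'
#' @param spikes logical/0-1 vector of presynaptic spikes.
#' @param W connectivity matrix, \code{W[i, j]} = synapses j -> i.
#' @param dr_ex,dr_in current filtered drives (mV/ms).
#' @param is_ex logical, which presynaptic neurons are excitatory.
#' @param dt step (ms).
#' @param prm neuron parameter list (\code{mu}, \code{syn_strength}).
#' @return list with updated \code{dr_ex}, \code{dr_in}.
#' @export
synaptic_drive <- function(spikes, W, dr_ex, dr_in, is_ex, dt, prm) {
  dec <- exp(-dt / prm$mu)
  dr_ex <- dr_ex * dec
  dr_in <- dr_in * dec
  sp <- as.numeric(spikes)
  if (any(sp > 0)) {
    dr_ex <- dr_ex + prm$syn_strength *
      drop(W[, is_ex, drop = FALSE] %*% sp[is_ex])
    dr_in <- dr_in + prm$syn_strength *
      drop(W[, !is_ex, drop = FALSE] %*% sp[!is_ex])
  }
  list(dr_ex = dr_ex, dr_in = dr_in)
}

#' External input schedule
#'
#' Mean external drive as a function of the connectivity-update index
#' \code{T}: a plateau of \code{ext_high} (8 mV/ms) for the first
#' \code{ramp_mid} (500) updates while the network grows, then the logistic
#' ramp \eqn{(8-5)/(1+\exp((T-500)/200)) + 5} down to the baseline of
#' 5 mV/ms. From lesion onset onward, neurons in the LPZ receive exactly 0,
#' noise included. The plateau and the ramp disagree at the switch point
#' (the ramp starts at 6.5); the printed schedule is implemented as is.
#'
#' @param T connectivity-update index (>= 0).
#' @param cfg an [msp_config()].
#' @param in_lpz logical vector (or scalar) of LPZ membership.
#' @param lesioned has the lesion been applied?
#' @return list with per-neuron \code{mean} and \code{sd} of the external
#'   input at update \code{T}.
#' @export
external_input <- function(T, cfg, in_lpz, lesioned = FALSE) {
  s <- cfg$schedule
  m <- if (T < s$ramp_mid) s$ext_high else
    (s$ext_high - s$ext_low) / (1 + exp((T - s$ramp_mid) / s$ramp_tau)) +
      s$ext_low
  mean <- rep(m, length(in_lpz))
  sd <- rep(s$ext_sd, length(in_lpz))
  if (lesioned) {
    mean[in_lpz] <- 0
    sd[in_lpz] <- 0
  }
  list(mean = mean, sd = sd)
}

#' Single step of the calcium trace
#'
#' Calcium decays exponentially with time constant \code{tau_ca} and jumps
#' by \code{beta} at each spike; it is the low-pass-filtered firing rate
#' used as the activity measure by the growth rules (steady state
#' \code{rate * beta * tau_ca} for a constant rate per ms).
#'
#' @param ca per-neuron calcium (>= 0).
#' @param spikes logical/0-1 spike indicator for this step.
#' @param dt step (ms).
#' @param prm neuron parameter list (\code{beta}, \code{tau_ca}).
#' @return updated calcium vector.
#' @export
calcium_update <- function(ca, spikes, dt, prm) {
  ca * exp(-dt / prm$tau_ca) + prm$beta * as.numeric(spikes)
}

#' Simulate one electrical window
#'
#' Integrates membrane dynamics, synaptic filtering and the calcium trace
#' for \code{window_ms} at resolution \code{dt_ms}, carrying all state
#' across windows. The external-input schedule is evaluated at the current
#' update index; LPZ neurons are silenced after the lesion. Runs compiled.
#'
#' @param net an \code{msp_network}.
#' @return the network with advanced electrical state and an added field
#'   \code{spike_counts} (per-neuron spikes in this window).
#' @export
simulate_window <- function(net) {
  s <- net$config$schedule
  ext <- external_input(net$T, net$config, net$pop$in_lpz, net$lesioned)
  n_steps <- as.integer(round(s$window_ms / s$dt_ms))
  out <- simulate_window_cpp(net$v, net$u, net$dr_ex, net$dr_in, net$ca,
                             net$last_spikes, net$W + 0.0,
                             net$pop$is_excitatory,
                             ext$mean, ext$sd, n_steps, s$dt_ms,
                             net$config$neuron)
  net[c("v", "u", "dr_ex", "dr_in", "ca", "last_spikes")] <-
    out[c("v", "u", "dr_ex", "dr_in", "ca", "last_spikes")]
  net$spike_counts <- out$spike_counts
  net
}
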