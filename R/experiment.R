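#' Growth-rule presets
#'
#' The three growth-parameter regimes: in the \emph{physiological} case
#' axonal elements need more activity to form than dendritic ones
#' (\code{eta_A} = 0.4, \code{eta_D} = 0.1), which makes repair proceed by
#' ingrowth from the intact zone; in the \emph{recurrent} case both grow at
#' low activity (\code{eta_A} = \code{eta_D} = 0.1) and the deafferented
#' zone repairs itself with massive recurrent synapses; in the
#' \emph{no_repair} case dendritic elements need high activity
#' (\code{eta_A} = 0.1, \code{eta_D} = 0.4) and activity is never restored.
#'
#' @param name one of \code{"physiological"}, \code{"recurrent"},
#'   \code{"no_repair"}.
#' @param kernel \code{"gaussian"} (small-world initial topology) or
#'   \code{"flat"} (random initial topology; kept for the whole run).
#' @param control if \code{TRUE}, no lesion is applied (the LPZ flag is
#'   still tracked, as the control region).
#' @return a list with class \code{msp_preset}.
#' @export
experiment_preset <- function(name = c("physiological", "recurrent", "no_repair"),
                              kernel = c("gaussian", "flat"),
                              control = FALSE) {
  name <- match.arg(name)
  etas <- switch(name,
    physiological = c(eta_A = 0.4, eta_D = 0.1),
    recurrent     = c(eta_A = 0.1, eta_D = 0.1),
    no_repair     = c(eta_A = 0.1, eta_D = 0.4)
  )
  structure(list(name = name, eta_A = unname(etas["eta_A"]),
                 eta_D = unname(etas["eta_D"]),
                 kernel = match.arg(kernel), control = control),
            class = "msp_preset")
}

#' Grow a network from scratch
#'
#' Runs connectivity updates from zero connectivity and zero synaptic
#' elements up to (but not including) the lesion onset, under the elevated
#' early external input that bootstraps growth. This is how every
#' experiment network is obtained; there is no other initialization.
#'
#' @param cfg an [msp_config()].
#' @param record callback \code{function(net)} invoked after every update
#'   (used internally to collect the time series); \code{NULL} to skip.
#' @return the network at lesion onset.
#' @export
grow_network <- function(cfg, record = NULL) {
  net <- new_network(cfg)
  for (T in seq_len(cfg$schedule$lesion_onset)) {
    net <- connectivity_update(net)
    if (!is.null(record)) record(net)
  }
  net
}

#' Apply the deafferentation
#'
#' Permanently removes the external input (mean and noise) of every neuron
#' in the lesion projection zone. Connectivity and element counts are not
#' touched: all subsequent changes are the network's own response.
#'
#' @param net an \code{msp_network} at lesion onset.
#' @return the lesioned network.
#' @export
apply_lesion <- function(net) {
  net$lesioned <- TRUE
  net
}

# Per-update diagnostics: mean calcium by region and excitatory-to-
# excitatory synapse counts by region pair (pre -> post).
update_diagnostics <- function(net) {
  ex <- net$pop$is_excitatory
  lpz <- net$pop$in_lpz
  exW <- net$W[ex & lpz, ex, drop = FALSE]
  lpz_ex <- lpz[ex]
  Wee <- net$W[ex, ex, drop = FALSE]
  c(T = net$T,
    ca_lpz = mean(net$ca[lpz]),
    ca_intact = mean(net$ca[!lpz]),
    syn_lpz_lpz = sum(Wee[lpz_ex, lpz_ex]),
    syn_intact_lpz = sum(Wee[lpz_ex, !lpz_ex]),    # pre intact -> post LPZ
    syn_lpz_intact = sum(Wee[!lpz_ex, lpz_ex]),    # pre LPZ -> post intact
    syn_intact_intact = sum(Wee[!lpz_ex, !lpz_ex]),
    syn_total = sum(net$W))
}

#' Run a full deafferentation experiment
#'
#' Grows a network from scratch, applies the lesion at onset (unless the
#' preset is a control), and continues to the end of the schedule. Records
#' per update the mean calcium of the LPZ and the intact zone and the
#' excitatory-to-excitatory synapse counts by region pair, takes
#' connectivity snapshots shortly before the lesion (50 updates before
#' onset) and at the end, and optionally evaluates the full topology
#' battery on a stride.
#'
#' @param preset an [experiment_preset()].
#' @param cfg an [msp_config()]; its \code{eta_A}, \code{eta_D} and kernel
#'   are overridden by the preset.
#' @param seed integer seed; the whole run is deterministic given it.
#' @param topology_every stride (in updates) for topology evaluation; 0
#'   disables it (snapshots are always taken).
#' @param null_replicates Erdos-Renyi replicates per topology evaluation.
#' @return an object of class \code{msp_result}: list with \code{series}
#'   (data frame, one row per update), \code{snapshots} (named list of W
#'   matrices at \code{T0} and \code{T1}), \code{topology} (data frame or
#'   NULL), \code{net} (final network), \code{preset}, \code{config},
#'   \code{seed}.
#' @examples
#' \donttest{
#' cfg <- msp_config("mini")
#' res <- run_experiment(experiment_preset("physiological"), cfg, seed = 1)
#' tail(res$series$ca_lpz, 1)
#' }
#' @export
run_experiment <- function(preset, cfg, seed = 1L, topology_every = 0L,
                           null_replicates = 10L) {
  stopifnot(inherits(preset, "msp_preset"))
  cfg$growth$eta_A <- preset$eta_A
  cfg$growth$eta_D <- preset$eta_D
  cfg$growth$kernel <- preset$kernel
  cfg <- validate_config(cfg)

  set.seed(as.integer(seed))
  s <- cfg$schedule
  total <- s$total_updates
  t0 <- max(1L, s$lesion_onset - 50L)

  series <- matrix(NA_real_, nrow = total, ncol = 8,
                   dimnames = list(NULL, c("T", "ca_lpz", "ca_intact",
                                           "syn_lpz_lpz", "syn_intact_lpz",
                                           "syn_lpz_intact",
                                           "syn_intact_intact", "syn_total")))
  topo_rows <- list()
  snapshots <- list()

  net <- new_network(cfg)
  for (T in seq_len(total)) {
    if (T == s$lesion_onset + 1L && !preset$control) net <- apply_lesion(net)
    net <- connectivity_update(net)
    series[T, ] <- update_diagnostics(net)
    if (net$T == t0) snapshots$T0 <- net$W
    if (topology_every > 0 && net$T %% topology_every == 0) {
      topo_rows[[length(topo_rows) + 1L]] <-
        c(T = net$T, unlist(topology_record(
          graph_view(net), replicates = null_replicates)))
    }
  }
  snapshots$T1 <- net$W

  structure(list(
    series = as.data.frame(series),
    snapshots = snapshots,
    topology = if (length(topo_rows))
      as.data.frame(do.call(rbind, topo_rows)) else NULL,
    net = net, preset = preset, config = cfg, seed = seed
  ), class = "msp_result")
}

#' @export
print.msp_result <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("<msp_result> preset '%s'%s, %d updates, seed %s\n",
              x$preset$name, if (x$preset$control) " (control)" else "",
              n, format(x$seed)))
  cat(sprintf("  final mean calcium: LPZ %.3f, intact %.3f; %d synapses\n",
              x$series$ca_lpz[n], x$series$ca_intact[n],
              as.integer(x$series$syn_total[n])))
  invisible(x)
}

#' Updates-to-days calibration
#'
#' Converts a number of connectivity updates into post-lesion days using
#' the calibration constant of the schedule (1000 updates = 14 days by
#' default, so the standard 12000 post-lesion updates span 24 weeks).
#'
#' @param updates number of connectivity updates.
#' @param cfg an [msp_config()].
#' @return days (numeric).
#' @export
updates_to_days <- function(updates, cfg) {
  updates / cfg$schedule$updates_per_day
}

#' Write an experiment result to disk
#'
#' Emits \code{series.csv}, one edge list per snapshot under
#' \code{snapshots/}, \code{topology.csv} (when computed) and the fully
#' resolved configuration as \code{config.resolved} — the layout the
#' command-line driver produces.
#'
#' @param res an \code{msp_result}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_result <- function(res, dir) {
  dir.create(file.path(dir, "snapshots"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.csv(res$series, file.path(dir, "series.csv"),
                   row.names = FALSE)
  for (nm in names(res$snapshots)) {
    Tlab <- if (nm == "T0") max(1L, res$config$schedule$lesion_onset - 50L)
            else res$config$schedule$total_updates
    write_edge_list(res$snapshots[[nm]],
                    file.path(dir, "snapshots", sprintf("T%d.edges", Tlab)))
  }
  if (!is.null(res$topology))
    utils::write.csv(res$topology, file.path(dir, "topology.csv"),
                     row.names = FALSE)
  write_config(res$config, file.path(dir, "config.resolved"))
  invisible(dir)
}
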