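# Lazily computed, cached study runs at the mini scale. Only the
# acceptance tests touch these; each run takes well under a minute.
.run_cache <- new.env(parent = emptyenv())

get_mini_run <- function(preset_name, seed) {
  key <- paste0(preset_name, "_", seed)
  if (!exists(key, envir = .run_cache)) {
    res <- run_experiment(experiment_preset(preset_name), msp_config("mini"),
                          seed = seed)
    assign(key, res, envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# Topology of a stored snapshot of a run (full W restricted to the
# excitatory subgraph, with the run's LPZ partition).
snapshot_view <- function(res, which = c("T0", "T1")) {
  which <- match.arg(which)
  ex <- res$net$pop$is_excitatory
  graph_view(res$snapshots[[which]][ex, ex, drop = FALSE],
             lpz = res$net$pop$in_lpz[ex])
}
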