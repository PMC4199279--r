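# mspnet

Homeostatic structural plasticity in spiking networks: growth, focal
deafferentation, and graph-topology analysis.

## What this package is for

After a focal loss of input — a retinal lesion projecting to visual
cortex, a subcortical stroke deafferenting a motor area — cortical
networks rewire for months. `mspnet` implements a model of structural
plasticity in which that rewiring emerges from a single local rule:
every neuron maintains a homeostatic level of its own activity by
growing synaptic elements (axonal boutons, dendritic spines) when its
calcium-tracked firing rate is too low and removing them when it is too
high. Vacant boutons and spines of different neurons recombine into
synapses, preferentially over short distances. The package is aimed at
computational neuroscientists studying lesion-induced reorganization,
diaschisis, and topological biomarkers of repair such as betweenness
centrality.

The core pieces:

* **Activity**: Izhikevich neurons (`dv/dt = 0.04 v² + 5 v + 140 − u +
  I`, reset at 30 mV) with exponentially filtered synaptic input
  (unit kick per spike, μ = 5 ms) and a calcium trace
  `ca ← ca·e^(−dt/τ) + β` per spike (β = 0.001, τ = 10 s) — the
  activity measure of the growth rules. The per-window integration runs
  compiled (Rcpp).
* **Growth**: Gaussian growth curves `dz/dt = ν(2 e^(−((ca−ξ)/ζ)²) − 1)`
  with zero crossings pinned at the minimum calcium η for element
  formation and the homeostatic set-point ε = 0.7, replaced in
  simulations by a hard-zero homeostatic range [0.65, 0.75]. Three
  (η_A, η_D) presets: `physiological` (0.4, 0.1), `recurrent`
  (0.1, 0.1), `no_repair` (0.1, 0.4).
* **Rewiring**: multiplicity-proportional synapse deletion when bound
  synapses exceed integer element capacity; probabilistic formation of
  vacant element pairs weighted by a Gaussian (or flat) distance kernel;
  whole vacant elements decay with a mean lifetime of 10 updates.
* **Experiment**: networks grown from scratch under a decaying input
  ramp (8 → 5 mV/ms), then a rectangular lesion projection zone (LPZ)
  loses all external input; 1000 connectivity updates map to 14 days.
* **Topology**: on the excitatory→excitatory multiplicity graph with
  edge lengths 1/W — characteristic path length, Fagiolo weighted
  directed clustering, small-worldness S = γ/λ against an Erdős–Rényi
  null, Brandes betweenness centrality, local and global efficiency,
  degree distributions, and between-region variants.

## A worked example

```r
library(mspnet)

g <- msp_config("full")$growth
growth_rate(0.55, "axonal", g)   # 1e-04   : peak growth at the midpoint
growth_rate(0.70, "axonal", g)   # 0       : homeostatic range, no change
growth_rate(0.90, "axonal", g)   # -9.5e-05: retraction above the range

cfg <- msp_config("mini")        # 10 x 8 grid + 20 inhibitory, 4 x 4 LPZ
res <- run_experiment(experiment_preset("physiological"), cfg, seed = 1)
res
#> <msp_result> preset 'physiological', 5000 updates, seed 1
#>   final mean calcium: LPZ 0.000, intact 0.653; 757 synapses
```

At lesion onset (update 2000) this run has grown 833 synapses and the
LPZ sits at mean calcium 0.657, inside the homeostatic range. The
pre-lesion excitatory graph is clearly small-world:

```r
ex <- res$net$pop$is_excitatory
v0 <- graph_view(res$snapshots$T0[ex, ex], lpz = res$net$pop$in_lpz[ex])
set.seed(1)
topology_record(v0, replicates = 10)[c("C", "gamma", "lambda", "S")]
#> $C      0.0855
#> $gamma  2.52
#> $lambda 1.30
#> $S      1.93
```

After deafferentation the LPZ of this implementation falls silent and
disconnects (final LPZ calcium ~0) in all three growth regimes: with the
default electrical parameters the residual afferent drive of a
deafferented neuron (~1–2 mV/ms) is far below the 4 mV/ms rheobase, and
once calcium drops under η_D the growth rules forbid re-innervation. The
methods vignette (`vignettes/homeostatic-rewiring.Rmd`) derives this
quantitatively and spells out what the model does and does not
reproduce; the acceptance checks encoding successful repair are left
failing rather than re-tuned.

A thin command-line driver is installed as `exec/msp`:

```sh
msp run --preset physiological --scale mini --seed 1 --out out_dir
```

writing `series.csv`, `snapshots/T*.edges`, and the resolved
configuration (`config.resolved`) for re-analysis with the topology
functions (`read_edge_list()`, `graph_view()`, `topology_record()`).

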