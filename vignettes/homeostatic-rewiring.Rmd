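---
title: "Homeostatic structural rewiring after focal deafferentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeostatic structural rewiring after focal deafferentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mspnet` simulates cortical-sheet networks of spiking neurons whose
connectivity is not fixed but grows out of a single local rule: every
neuron tries to keep its own time-averaged electrical activity inside a
homeostatic range by building synaptic elements when it is too quiet and
removing them when it is too active. Synapses arise when a vacant axonal
element (bouton) of one neuron is matched with a vacant dendritic element
(spine) of another. The package grows networks from scratch, deprives a
circumscribed region of its external input (a lesion projection zone,
LPZ, the situation after a focal retinal lesion or a subcortical stroke),
and quantifies the ensuing rewiring with weighted directed graph
topology: characteristic path length, Fagiolo clustering, small-worldness
against an Erdős–Rényi null, Brandes betweenness centrality, and local
and global efficiency.

# The model

## Electrical activity

Each of the $n^{ex} + n^{in}$ neurons follows the two-variable quadratic
(Izhikevich) dynamics

$$\frac{dv}{dt} = k_1 v^2 + k_2 v + k_3 - u + I_{syn} + I_{ext}, \qquad
  \frac{du}{dt} = a(bv - u),$$

with a reset $v \leftarrow c$, $u \leftarrow u + d$ whenever $v$ reaches
30 mV. Defaults are $k_1 = 0.04\,\mathrm{mV^{-1}ms^{-1}}$, $k_2 =
5\,\mathrm{ms^{-1}}$, $k_3 = 140\,\mathrm{mV\,ms^{-1}}$, $a =
0.1\,\mathrm{ms^{-1}}$, $b = 0.2\,\mathrm{ms^{-1}}$, $c = -65$ mV, $d =
2\,\mathrm{mV\,ms^{-1}}$. Integration is forward Euler at `dt_ms` = 0.5
ms, the standard choice for this neuron model; halving `dt` changes
noise-free subthreshold trajectories by well under 0.1 mV over a window
(tested). Inhibitory neurons differ only in the sign of their
transmission.

Every synapse contributes a fixed kick of 1 mV ms$^{-1}$ per presynaptic
spike to an exponentially filtered drive with decay $\mu = 5$ ms;
excitatory and inhibitory drives are tracked separately and enter the
membrane equation as their difference. Transmission has a one-step
delay. External input is Gaussian white noise, one independent draw per
neuron per integration step (the discretization is the package's choice;
only mean and SD are model constants).

A calcium-like trace integrates spiking as the activity measure of the
growth rules: it jumps by $\beta = 10^{-3}$ per spike and decays with
$\tau_{Ca} = 10^4$ ms, so a steady rate $r$ (per ms) gives
$[Ca^{2+}] \approx r\,\beta\,\tau_{Ca}$ — 70 Hz corresponds to 0.7.

## Growth curves

Continuous per-neuron counts of axonal elements $A$, excitatory dendritic
elements $D^{ex}$ and inhibitory dendritic elements $D^{in}$ evolve as

$$\frac{dz}{dt} = \nu\left(2\,e^{-\left(\frac{[Ca^{2+}]-\xi}{\zeta}\right)^2} - 1\right),
 \qquad \xi = \frac{\eta + \epsilon}{2},\quad
 \zeta = \frac{\eta - \epsilon}{2\sqrt{\ln 2}},$$

a Gaussian whose two zero crossings are pinned at the minimum calcium
$\eta$ required to form that element type and at the homeostatic
set-point $\epsilon = 0.7$: elements are removed below $\eta$ and above
$\epsilon$, grown in between (at most $+\nu = 10^{-4}\,\mathrm{ms^{-1}}$
at the midpoint), and removed at rate approaching $\nu$ far above the
set-point. Because discrete synapses can never satisfy the set-point
exactly, the set-point is replaced in all simulations by a hard zero
plateau on the homeostatic *range* $0.65 \le [Ca^{2+}] \le 0.75$.

Three $(\eta_A, \eta_D)$ regimes are shipped as presets:

| preset | $\eta_A$ | $\eta_D$ | expected phenotype |
|---|---|---|---|
| `physiological` | 0.4 | 0.1 | repair by ingrowth from the intact zone |
| `recurrent` | 0.1 | 0.1 | repair by massive recurrent LPZ synapses |
| `no_repair` | 0.1 | 0.4 | no restoration of activity |

## Synapse deletion and formation

Connectivity updates happen at discrete steps. After each electrical
window the element counts advance by one Euler step of the growth curve
(window-end calcium), and then:

1. **Deletion.** A neuron holding more outgoing synapses than
   $\lfloor A \rfloor$, or more incoming synapses of a sign than the
   floor of the matching dendritic count, sheds the surplus. Victims are
   drawn uniformly over the synapse units of the class, i.e. a
   connection loses synapses in proportion to its multiplicity
   $W_{i,j}$ and never more than it has. The partner element of a broken
   synapse survives and becomes vacant. Classes are processed in the
   order outgoing excitatory, outgoing inhibitory, incoming excitatory,
   incoming inhibitory, and the normalization of the deletion
   probabilities is per neuron and class (for incoming deletion, over
   that neuron's afferents of the sign — the per-neuron reading of an
   ambiguous normalization; the alternative, network-wide normalization,
   would make a neuron's deletion depend on everyone else's synapses).
2. **Formation.** Vacant elements recombine. The probability that a try
   forms a synapse $j \to i$ is the product of the two neurons' shares
   of the sign-class vacancy pools, weighted by a distance kernel
   $K_{i,j}$ — Gaussian $e^{-d^2/\sigma^2}$ with $\sigma = 150\,\mu m$
   (one grid spacing; yields small-world networks) or flat (yields
   random networks). At most $\min(\sum A^{vac}, \sum D^{vac})$ tries
   are made per update against the cumulative probability vector, which
   is frozen within the update; a uniform draw beyond the total mass
   forms nothing. Every accepted synapse consumes one vacant element on
   each side, so no neuron can be driven past its integer capacity
   within an update.

Vacant elements that stay unused decay: each whole vacant element
disappears independently with probability $1 - e^{-1/\tau_{vac}}$ per
update ($\tau_{vac} = 10$ updates). Two numerical readings of this decay
were considered. Shrinking the *continuous* vacant portion by
$e^{-1/\tau_{vac}}$ per update looks equivalent but is not: the
continuous count then has the fixed point
$\nu \cdot \mathrm{window} / (1 - e^{-1/\tau_{vac}})$, which is below
one element for any electrical window shorter than several seconds, so a
network could never grow its first synapse. Treating completed vacant
elements as discrete entities with a geometric lifetime of
$\tau_{vac}$ updates preserves the intended pool-level decay (the
deterministic factor is recovered in expectation, which the tests
verify) while letting sub-unity growth progress accumulate. The
fractional progress toward the next element is never eroded.

## The experiment protocol

Networks are always grown from scratch: zero connectivity, zero
elements. Because an empty network cannot sustain the target rate on the
baseline input, the external drive starts at 8 mV ms$^{-1}$ for the
first 500 updates and then relaxes to 5 mV ms$^{-1}$ along the logistic
$I_{ext}(T) = 3/(1+e^{(T-500)/200}) + 5$ (the plateau and the ramp
disagree by 1.5 at the switch point; the printed schedule is implemented
as is). At lesion onset the external input of every neuron inside the
LPZ rectangle — mean and noise — is set to zero permanently; nothing
else is touched. One thousand connectivity updates correspond to 14
days, so the standard 12 000 post-lesion updates span 24 weeks.

Excitatory neurons sit on a jittered grid (uniform jitter of $\pm 0.1$
grid spacings per coordinate, the package's choice: small enough that
the grid topology stays unambiguous); inhibitory neurons sit on an even
interstitial sub-lattice. LPZ membership is decided from the unjittered
lattice position, because the published rectangle runs exactly through
grid points and deciding membership on jittered positions would make the
LPZ composition a coin flip for the boundary rows. The kernel, in
contrast, sees the jittered positions.

Two scales ship as first-class configurations. `full` is the published
geometry (20 × 16 excitatory grid, 80 inhibitory, lesion at $T = 8000$
of 20 000). `mini` (10 × 8 excitatory, 20 inhibitory, central 4 × 4 LPZ,
lesion at 2000 of 5000) preserves the LPZ-to-network ratio and is what
the tests and the acceptance script run; a mini run takes well under a
minute, so the three-seed study design stays cheap.

## Topology measures

All topology is computed on the excitatory-to-excitatory multiplicity
matrix $W^{ex,ex}$, as a directed graph with edge lengths $1/W$.
Shortest paths and betweenness run through igraph (Dijkstra and Brandes
with multiplicity-aware path counting); the Fagiolo weighted directed
clustering (weights normalized by the maximum, cube-root triangle
intensities) and the efficiency measures are implemented in the package.
Unreachable pairs are excluded from the characteristic path length and
their fraction is reported alongside, while the efficiencies count them
as zero contribution — the reason efficiency remains meaningful for
fragmented graphs. The Erdős–Rényi null places the same number of
synapses uniformly over ordered non-self pairs (multiplicities by
collision) and is averaged over 10 replicates by default; every measure
is cross-checked in the test suite against brute-force oracles
(Floyd–Warshall, exhaustive path enumeration, literal triple-loop
clustering) on exhaustive 3-node and sampled 4-, 5- and 8-node digraphs.

# A worked run

```{r}
library(mspnet)
cfg <- msp_config("mini")
res <- run_experiment(experiment_preset("physiological"), cfg, seed = 1)
res
tail(res$series[, c("T", "ca_lpz", "ca_intact", "syn_intact_lpz")], 3)
topology_record(graph_view(res$net), replicates = 10)
```

# What the simulations do and do not show

The synthetic networks reproduce the *constructive* side of the model
faithfully, and the tests pin it quantitatively: networks grow from
nothing to a stable state with mean calcium inside the homeostatic range
(seed 1 mini run: mean LPZ calcium 0.657 and 833 synapses at lesion
onset, with a clearly small-world excitatory graph, $S \approx 1.9$,
$\gamma \approx 2.5$ against its ER null); deletion frequencies match the
multiplicity-proportional rule and formation frequencies match the
vacancy-product-times-kernel rule (chi-squared, $p > 0.01$ at $10^4$
trials); every graph measure agrees with its brute-force oracle.

The *repair* side deserves honesty. Under the default electrical
parameters this implementation does not reproduce post-lesion recovery:
in all three growth regimes the LPZ falls silent and disconnects. The
chain is short. (i) At the homeostatic equilibrium a neuron holds about
8 synapses, because the gap between the isolated firing rate on baseline
input (~42 Hz) and the 70 Hz set-point corresponds to only ~2 mV
ms$^{-1}$ of net synaptic drive at 0.335 mV ms$^{-1}$ per synapse.
(ii) The deterministic rheobase of the quadratic neuron at these
parameters is 4 mV ms$^{-1}$; once the external input of the LPZ is
gone, the remaining 1–2 mV ms$^{-1}$ of afferent drive leaves LPZ
neurons at < 0.1 Hz (measured with frozen connectivity), and the network
is too sparse and asynchronous for coincident volleys to bridge the gap.
(iii) Calcium then falls below $\eta_D$ within ~37 updates, dendritic
elements are removed, and a neuron without dendritic vacancies can never
be re-innervated under the formation rule — deafferentation becomes
irreversible regardless of the growth preset and of the kernel. The race
is also scale- and window-invariant: during the ~1.9 calcium lifetimes
it takes the LPZ to cross $\eta_D$, a maximally hungry neuron can grow
about $\nu\,\tau_{Ca} \cdot 1.9 \approx 2$ elements, an order of
magnitude short of the ~12 active afferents needed to keep firing.
The same phenotype appears at the full published scale (20 × 16 grid,
8000 growth updates: mean calcium 0.679 and 3789 synapses at lesion
onset, LPZ silent and disconnected by 500 updates post-lesion).
Successful repair in this model class therefore requires an activity
regime — strong synchrony, or a rate-model transfer function without a
hard threshold — that the printed spiking parameters do not produce
here. The acceptance checks that encode successful repair are left
failing rather than re-tuned; the no-repair phenotype, the growth
dynamics, the stochastic-rule calibrations and the topology battery are
the validated surface.

Real cortex differs from these synthetic preparations in many further
ways (conductance synapses, dendritic geometry, neuromodulation,
distance-dependent delays), so green tests here validate the
implementation of the growth bookkeeping and graph analysis, not
biological prediction.

# Numerical choices

* One global R RNG stream drives everything (jitter, noise, decay,
  deletion, formation), threaded through the compiled window integrator;
  a run is bit-reproducible from `seed` alone. Sub-stream isolation was
  considered and rejected: it buys nothing for reproducibility here and
  would require hand-rolled RNG plumbing.
* Equal shortest-path lengths are genuine ties of small-integer ratios;
  betweenness relies on igraph's Brandes implementation, which counts
  them with multiplicity.
* The vacant-element decay is binomial per neuron and class, not
  per-element bookkeeping; the two are distributionally identical.
* Degenerate graphs (edgeless, single node, empty regions) return
  defined zeros or flagged `NA`s, never errors, so time series of
  topology records survive a disconnecting network.
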