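---
title: "Exchange of mtDNA products on mitochondrial encounter networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exchange of mtDNA products on mitochondrial encounter networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mitobingo)
```

## The biological problem

Plant mitochondria usually do not carry a complete copy of the mitochondrial
genome. Many carry a *subgenomic* mtDNA molecule encoding only a subset of
genes; some carry none. Yet each organelle needs the full complement of
mtDNA-encoded gene products to build its bioenergetic machinery. One proposed
resolution is social: mitochondria are highly mobile, they transiently
colocalise ("kiss-and-run"), and colocalisation can lead to fusion and
exchange of DNA, transcripts and proteins. Over time, an individual can then
be exposed to — and collect — the full product set, even though its own
genome stays incomplete.

This package models that process in three coupled layers:

1. **Encounter networks** — organelles are nodes; an edge (with a
   first-contact timestamp) records that two organelles came within a
   threshold distance at some frame of a tracking video
   (`build_encounter_network()`), or of a physical simulation.
2. **The bingo game** — a gossip-style exchange/decay process played on the
   temporal edge ordering of any such network (`play_game()`).
3. **Coupon-collector analytics** — closed-form predictions of game outcomes
   from node degrees alone (`predict_bingo_nodewise()`,
   `predict_bingo_threshold()`).

Synthetic null-model networks (`generate_network()`) and an agent-based
motility simulator (`run_until_edges()`) provide the comparison ensembles.

## The bingo game

Let `L` be the number of distinct genetic elements that together constitute
the full product set. Each node holds a DNA complement (initially one
element, drawn uniformly — or round-robin when a deterministic population is
wanted) and a level in `[0, 1]` for each of the `L` products.

* **Expression** is fast relative to decay, so a product whose gene is
  locally present sits pinned at level 1. This is the limit of a
  birth–death expression model in which the production rate greatly exceeds
  the decay rate; we never resolve expression kinetics below that limit.
* **Decay**: a product without a local gene decays as
  `level * exp(-nu * dt)`.
* **Exchange** at an encounter: DNA complements are either **traded**
  (`exchange_mode = "swap"`, the default interpretation for experiments
  here) or **merged** (`"union"`). In both modes, products backed by a gene
  in a partner's new complement jump to 1, and the remaining product levels
  are averaged between the partners (content mixing on fusion).
* **Scoring**: a node's *bingo score* is the fraction of the `L` products
  above the threshold `tau`; a *bingo* is a score of 1. The population
  summary `p` is the fraction of nodes that have ever scored a bingo
  (`scoring = "ever"`) or that hold one at the end of the window
  (`"final"`).

The game enables exchange at a proportion `q` of encounters, taken as a
prefix of the network's temporal edge order; decay acts continuously in time
regardless of which edges are enabled. Two initial conditions bracket
reality: `"empty"` (only your own product — how fast does a full set
*emerge*?) and `"full"` (everything at level 1 — how well is a full set
*retained* against decay?).

### Why `swap` is the default for experiments

The text description of an exchange ("DNA sets are exchanged") is ambiguous
between trading and merging. We implement both, but the experiment drivers
default to `swap` for three reasons grounded in the biology the model
excludes and in the model's own analytics:

* the model deliberately contains no mtDNA replication; `union` duplicates
  molecules at every encounter, which is replication by another name;
* cliquey networks are interesting precisely because their members can
  assimilate genes *without risk of losing them* to outside partners — genes
  can only be lost if exchange is a trade;
* the coupon-collector mapping treats each encounter as the draw of one
  partner element. That is literally true under `swap` (each node always
  carries exactly one element) and we measure Spearman rank correlations of
  ~0.93–0.95 between prediction and observation in that mode, versus ~0.56
  under `union`, where a single encounter can deliver an arbitrarily large
  accumulated set and the game saturates.

The hand-derived worked examples (two nodes sharing complements; a three-node
chain where the order of exchanges leaves the first node one product short,
`p = 2/3`) use `union`, and `union` remains the `bingo_config()` default so
those derivations hold verbatim.

### Clocks and the decay rate

Biological and simulated networks carry real first-contact times in seconds;
synthetic generator networks carry none. `play_game(clock = "rank")` places
every network on a common unit clock — one time unit per network-wide
encounter, ties in first-contact time broken by a seeded shuffle so the
order is always total — which makes games on differently sourced networks
commensurable. `nu` is then a rate per encounter step.

The package default `nu = log(2)/3600` per second is a one-hour product
half-life, at the fast end of measured mitochondrial RNA decay and matching
the timescale on which whole-population content mixing has been observed;
over a four-minute tracking window such decay is negligible, which is the
regime in which emergence questions are asked. The comparison experiments
(`run_comparison()`) instead probe the *retention* regime and default to a
half-life of **half the reference game length** (`log(2)/(e_ref/2)` per
step). This mirrors the hour-scale worked scenario — products with a 1-h
half-life, roughly one encounter per organelle per hour, observed over
2 h — in which decay and encounter dynamics compete. With that common clock,
a network family that needs more encounters in total (e.g. unpadded large
cliques, whose games are several times longer than an edge-matched network's)
pays for its slower assimilation in decayed product, which is exactly the
clique-size tension the model is meant to expose.

## Null-model network families

All generators produce simple graphs with exactly `n` nodes, and exactly `e`
edges where the construction permits; a shared padding routine adds uniform
random missing edges where needed. Conventions worth noting:

* **ER** — a uniform random `e`-subset of pairs (equivalent to rejection
  sampling of uniformly chosen pairs).
* **SF** — endpoint sampling with weight `degree + 1`. Pure
  degree-proportional sampling from an empty graph deadlocks (after the
  first edge, only its two endpoints ever have positive weight and their
  pair already exists), so the standard smoothed weight is used. Variant ii
  seeds a path to enforce connectivity; variant iii grows the network by
  sequential preferential attachment, then pads.
* **WS** — each node owns `floor(e/n)` or `floor(e/n) + 1` forward ring
  edges, with exactly `e - n*floor(e/n)` nodes (uniformly chosen) rounded
  up: mean-preserving and summing exactly to `e`. Forward edges are rewired
  with probability `rewire_prob` (default 0.1; the canonical small-world
  regime) to uniform non-duplicate targets.
* **cliquey** — `floor(n/c)` cliques of size `c`, remainder nodes forming
  one smaller clique rather than being stranded; variants: (a) disconnected,
  (b) consecutive cliques bridged by single edges, (c)/(d) the same padded
  to `e` (an error, reported and skipped by the ensemble builder, when the
  clique edges alone exceed `e`).
* **GRG** — `n` uniform points in the unit square, the `e` closest
  currently-unlinked pairs connected shortest-first.
* **star** — a hub wired to all others, padded to `e`.

## The physical simulator

`run_until_edges()` advances `n_agents` point agents in a 2D rectangular
domain with reflecting walls until the encounter network (pairs of
simultaneously active agents within `r_enc`, first contact timestamped)
holds `target_edges` edges. Per timestep, in a fixed order (move, reflect,
attach/detach, activity switch):

* detached active agents take independent per-axis
  `Normal(0, sqrt(2 D dt))` steps — the standard discretisation of 2D
  diffusion with constant `D`;
* attached active agents move ballistically at speed `v` along an
  axis-aligned direction drawn at attachment, modelling transport on
  cytoskeletal strands that cross the cell at constant x or constant y (the
  strands themselves are implicit: attachment is position-independent);
* attachment and detachment are resampled per step with `p_attach`,
  `p_detach`; activity switches with probabilities `1 - exp(-k dt)`.
  Inactive agents are frozen and invisible to encounters, modelling
  organelles that have left the region of observation; the stationary
  active fraction is `k_act/(k_act + k_inact)` (0.1 in the heterogeneous
  regime used here).

Exported trajectories use the same schema as the tracking reader, so a
simulation's own network is exactly recoverable by
`build_encounter_network()` at threshold `r_enc` — an internal consistency
oracle that the test suite exercises.

### Parameter choices

No public tracking dataset accompanies the model, and the characteristic
motility values are not recoverable from the available text, so the
simulator doubles as the package's synthetic-data generator with parameters
fixed once:

| parameter | default | rationale |
|---|---|---|
| frame interval | 1.94 s | tracking-video convention |
| pixel scale | 5.0 px/um | universal rescaling convention |
| encounter threshold / `r_enc` | 1.6 um | suggested colocalisation distance |
| `dt` | 0.1 s | resolves ballistic runs at `v` ~ 1 um/s |
| `D` | 0.1 um^2/s | sub-um^2/s organelle diffusion |
| `v` | 1 um/s | cytoskeletal transport speed scale |
| `p_attach`, `p_detach` | 0.05, 0.2 /step | ~20% attached, second-scale runs |
| `k_act`, `k_inact` | 0.01, 0.09 /s | 10% active entry/exit regime |
| domain | 40 x 10 um | elongated hypocotyl-cell geometry |

For the acceptance-scale experiments (100 agents, 150 edges) the domain is
enlarged to 100 x 25 um: in the default domain, ~99 of the 150 edges would
already be present at frame zero (`C(100,2) * pi * r_enc^2 / A`), leaving a
static geometric snapshot rather than a network built by motion. With the
larger domain the initial frame contributes only ~10% of the target.

### What the generator emulates — and what it does not

It emulates heterogeneous diffusive plus ballistic 2D motion, entry/exit
heterogeneity (which produces heavy-tailed degree distributions and
singletons, as in tracked data), reflecting confinement, and
threshold-distance encounters. It does **not** emulate: tracking noise and
identity switches (a real tracker can split one organelle into two nodes,
deflating degrees), spot-detection misses, 3D excursions, crowding or
hydrodynamic interactions, explicit filament geometry, or fusion
selectivity (every proximity event is a potential exchange; in reality
colocalisation is necessary but not sufficient). Tests passing on these
synthetic data therefore validate the machinery and its statistical
behaviour, not the fidelity of any particular biological parameter set.

## Coupon-collector predictions

With conserved molecules, a node of degree `m` makes `m` one-coupon draws,
each uniform on the `L` elements. The package provides the exact
inclusion–exclusion completion probability
`prob_complete(L, m, owned)` (= `sum_j (-1)^j C(L-owned, j) (1-j/L)^m`),
the expected distinct count `L(1 - (1-1/L)^m)`, and the waiting times
`L * H_L` / `L * H_{L-1}`. Two network-level predictors follow: the
node-wise sum of completion probabilities, and the count of nodes whose
degree reaches `T(L) = ceiling(L * H_{L-owned})` (a median-based threshold
is available via `rule = "median"`). Both condition by default on a node
owning its element (`owned = 1`); the alternative `owned = 0` is exposed
because the conditioning convention is not fixed by the problem statement.
The i.i.d.-uniform draw assumption ignores that partner elements are
correlated by the network (an element you passed on may return), so
predictions are compared to simulations by rank, not absolute equality.

## Study scales and numerical choices

The package's own experiments run at desk scale, chosen to finish in
minutes on one CPU while keeping every qualitative contrast testable:
ensembles of `n = 100`, `e = 150` networks with 10 repetitions per `L` in
`{2, 3, 5, 10, 15, 20}` for the matched-ensemble comparison, and a mixed
ensemble of `n = 60`, `e = 120` networks with 20 repetitions and `L` in
`{2, 3, 5}` for the prediction study. Other conventions: `ceiling(q * e)`
edges enabled at exchange proportion `q`; strict inequality (`level > tau`)
in the bingo score; `tau = 0.5`; per-rep element assignments and tie-break
orders drawn once and reused across the `q` grid so p(q) curves are
monotone under matched seeds; all stochastic entry points accept a seed and
derive child seeds deterministically.

At this scale one caveat matters: with mean degree `2e/n = 3`, retention
games at `L >= 5` score zero on every family — a node would need on the
order of `L` useful encounters within one decay half-life, and fewer than
two arrive. The high-`L` contrasts between families (large-versus-small
clique reversal, across-`L` robustness rankings) require the richer
networks of full-scale data and are not resolvable at `e/n = 1.5`; the
test suite states them anyway and documents the outcome rather than
weakening the conditions.

## Limitations

Beyond the simulator's scope above: the model tracks access to genetic
information and products only — no mtDNA replication, degradation,
recombination or copy-number dynamics; exchange is all-or-none rather than
partial; decay is a single global rate rather than per-product; and
encounter networks are analysed as given, with no attempt to infer missed
encounters. The normalised comparison scores are undefined wherever the
reference network's own score is zero, and are reported as `NA` rather than
imputed.
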