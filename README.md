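# mitobingo

Plant mitochondria usually carry *less than a full copy* of the
mitochondrial genome — many hold only a subgenomic mtDNA molecule, some none
at all. How, then, does every organelle obtain the complete set of
mtDNA-encoded gene products? One candidate answer is social: mitochondria
move rapidly through the cell, transiently colocalise, and on fusion can
exchange DNA, transcripts and proteins. `mitobingo` models this hypothesis
quantitatively, for researchers studying organelle dynamics and for network
scientists interested in gossip-style spreading on temporal graphs.

The package covers the full pipeline:

* **Encounter networks from tracking data** — parse TrackMate-dialect XML or
  plain trajectory tables (`read_trackmate_xml()`, `read_trajectory_table()`)
  and link any two organelles that come within a threshold distance in the
  same frame (`build_encounter_network()`), with first-contact timestamps,
  singleton pruning and trajectory truncation utilities.
* **The "bingo" exchange game** (`play_game()`) — each node holds one of the
  `L` genetic elements and a level in [0, 1] for each of the `L` products.
  Products with a local gene sit at level 1 (expression is fast); products
  without one decay as `exp(-nu * t)`. A proportion `q` of encounters, taken
  in temporal order, permits exchange: DNA complements are traded (`swap`)
  or merged (`union`), and orphan product levels are averaged. A node scores
  a **bingo** when all `L` products exceed the threshold `tau`; the summary
  `p(q)` is the proportion of nodes scoring bingo.
* **Null-model ensembles** (`generate_network()`, `matched_ensemble()`) —
  Erdős–Rényi, three scale-free variants, Watts–Strogatz, cliquey
  (disconnected / bridged / padded), geometric random graphs and stars, each
  matched to a reference network's `n` and `e`.
* **A physical simulator** (`run_until_edges()`) — agents diffuse (constant
  `D`), stochastically attach to an implicit cytoskeleton and run
  ballistically at speed `v`, and enter/exit the observation region; the
  simulation runs until the encounter network holds a target number of
  edges.
* **Coupon-collector analytics** (`prob_complete()`,
  `predict_bingo_nodewise()`, `predict_bingo_threshold()`) — a node of
  degree `m` is a collector making `m` uniform draws from `L` coupon types;
  inclusion–exclusion gives its completion probability
  `sum_j (-1)^j C(L-o, j) (1 - j/L)^m` and the waiting time `L * H_L`,
  turning degree sequences into predicted bingo counts without simulation.
* **Experiment drivers** (`run_comparison()`, `run_prediction_study()`,
  `run_robustness()`) — the matched-ensemble score comparison, the
  prediction-versus-observation study, and pruning/truncation robustness
  checks.

## Worked example

Simulate a small cell, summarise its encounter network, play the bingo game
on it, and compare with the analytic prediction:

```r
library(mitobingo)

cfg <- sim_config(n_agents = 60, target_edges = 90,
                  k_act = 0.01, k_inact = 0.09,      # ~10% active at a time
                  domain_width = 60, domain_height = 15, seed = 11)
run <- run_until_edges(cfg)
run$network
#> <encounter_network [simulated]: n = 60, e = 90>

summarize_network(run$network)
#> <stats_record: n 60, e 90, <k> 3, eff 0.256, Q 0.587, 4 comp, degree range 9>

res <- play_game(run$network,
                 bingo_config(L = 3, ic = "empty", scoring = "ever",
                              exchange_mode = "swap", nu = 0,
                              q_grid = c(0, 0.25, 0.5, 1), reps = 10,
                              seed = 2),
                 clock = "rank")
res$summary
#>      q     p_mean       p_sd
#> 1 0.00 0.00000000 0.00000000
#> 2 0.25 0.00000000 0.00000000
#> 3 0.50 0.01833333 0.01995365
#> 4 1.00 0.12500000 0.06443008

predict_bingo_nodewise(run$network, 3)
#> [1] 23.55726
res$final_score * network_n(run$network)   # observed mean bingo count
#> [1] 7.5
```

Reading the output: the simulated network has 60 organelles, 90 encounters,
mean degree 3 and a wide degree range (9 distinct degree values — the
signature of heterogeneous presence times). With `L = 3` genetic elements
and no exchange (`q = 0`) no organelle ever assembles a full product set;
when every encounter permits exchange (`q = 1`), 12.5% of organelles do.
The coupon-collector formula, which treats each partner as an independent
uniform draw, predicts 23.6 collectors — an over-estimate in absolute terms
(partner elements are correlated through the network), which is why the
package compares prediction and observation by *rank* across network
ensembles, where the agreement is strong (Spearman ρ ≈ 0.93).

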