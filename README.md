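# perturbnet

Perturbation spreading and silencing-time analysis on protein–protein
interaction networks.

## The problem

Knocking out or drugging a protein does not only affect that protein: the
perturbation propagates through the interactome. How efficiently it spreads
from a given node is a dynamical property of the node's network position,
and it separates biologically interesting node classes — drug targets
(especially targets of drugs with recorded side effects) and
disease-associated proteins tend to be markedly better spreaders than the
background proteome. `perturbnet` provides the simulation and the complete
statistical pipeline needed to measure and compare spreading efficiency
across node groups, for anyone studying network pharmacology, drug safety
signals, or disease-gene network position.

## The model

The dynamics are a discrete-time *communicating-vessels* diffusion with
dissipation. A starting energy *E* is split equally among the seed node(s).
Each step has two synchronous sub-phases:

1. **Flow.** Every edge {u, v} carries a flow *k*·(*E*ᵤ − *E*ᵥ) from the
   higher-energy endpoint to the lower, so node u updates as
   *E*ᵤ′ = *E*ᵤ + *k*·Σ_{v∈N(u)} (*E*ᵥ − *E*ᵤ) — one explicit-Euler step of
   the graph-Laplacian heat equation. Flow conserves total energy exactly.
2. **Dissipation.** Every node loses min(*E*ᵤ′, *D*) units, modelling decay
   of the perturbation.

Two metrics summarise a run seeded at a node (or at a drug's full target
set, with *E* split equally):

- **silencing time** — steps until every node's energy is below the
  threshold θ = 1 unit; *small* values mean *efficient* spreading;
- **perturbation reach** — the number of nodes whose energy ever met θ.

Defaults are *E* = 1000, *D* = 5, θ = 1, and *k* = 1/(deg_max + 1) (the
Laplacian stability bound). Around the simulator the package provides the
network-construction rules (TSV/SIF loading with loop/duplicate cleanup, ID
mapping, giant component, random node deletion), Mann–Whitney and Welch
group comparisons with cumulative distribution curves, degree/closeness/
betweenness centrality summaries, geodesic target-to-disease distances, and
a synthetic interactome generator with planted annotations that makes every
analysis testable end to end without external databases.

## Worked example

Generate a synthetic interactome with a planted effect — 40 drugs whose
side-effect-flagged half picks its targets with probability ∝ degree² —
and run the full analysis:

```r
library(perturbnet)

sc  <- synthetic_scenario(n_nodes = 2000, n_drugs = 40, degree_bias = 2, seed = 42)
net <- generate_network(sc$n_nodes, sc$m, rng_seed = 42)
ann <- plant_annotations(net, sc)
res <- run_full_analysis(net, ann, ed_grid = list(c(1000, 5)),
                         non_target_cap = 200, seed = 42)
print(res)
```

```
Perturbation-spreading analysis of a 2000-node, 3997-edge network
  groups: 37 with-SE / 50 without-SE / 1913 non-target
  grid point E1000_D5
    withSE_vs_withoutSE.silencing_time       p = 5.881e-09 (targets_with_SE < targets_without_SE)
    withoutSE_vs_nontargets.silencing_time   p = 0.102 (targets_without_SE < non_targets)
    withSE_vs_withoutSE.perturbation_reach   p = 4.453e-09 (targets_with_SE > targets_without_SE)
    withoutSE_vs_nontargets.perturbation_reach p = 0.05355 (targets_without_SE > non_targets)
  distance contrast: p = 2.103e-19 (central < peripheral)
```

The planted contrast is recovered: targets of side-effect drugs silence
significantly faster (smaller silencing times) and reach significantly more
nodes than targets of drugs without side effects, while the unbiased
without-SE group is statistically indistinguishable from background — the
generator plants a spreading advantage only for the side-effect group. The
distance line shows the hub-drawn ("central", cancer-like) disease set
sitting significantly closer to the drug targets than the low-degree
("peripheral", diabetes-like) set:

```r
print(res$distances$central)
```

```
Target-to-disease-set distances (87 targets, policy: exclude)
  mean of per-target means:   3.493 edges
  median of per-target means: 3.556 edges
```

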