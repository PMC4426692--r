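---
title: "Measuring perturbation spreading in interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring perturbation spreading in interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbnet)
```

## The model

`perturbnet` simulates how a localized perturbation — a drug binding its
target, a knockdown — spreads through an undirected protein interaction
network. The dynamics are a communicating-vessels model: a quantity we call
energy moves along edges in proportion to the difference between endpoint
values, and every node loses a fixed amount per step.

One step has two synchronous sub-phases:

1. **Flow.** For each edge $\{u, v\}$ a flow $k\,(E_u - E_v)$ passes from
   the higher-energy endpoint to the lower. Equivalently the energy vector
   is multiplied by $I - kL$ with $L$ the graph Laplacian — one explicit
   Euler step of the heat equation on the graph. This phase conserves total
   energy exactly.
2. **Dissipation.** Each node loses $\min(E_u, D)$ units. Flooring at zero
   keeps energies nonnegative.

A run starts by splitting the starting energy $E$ equally over the seed
set (a single probe protein, or all targets of a multi-target drug). Two
metrics summarise it:

- **Silencing time**: the number of completed steps until *every* node's
  energy is below the threshold $\theta$. Efficient spreaders distribute
  their energy over many nodes quickly; because each occupied node then
  dissipates $D$ in parallel, the perturbation drains *faster* — so small
  silencing times indicate good spreading.
- **Perturbation reach**: the number of nodes whose energy ever met
  $\theta$ (evaluated after each flow sub-phase, seeds included when their
  share is at least $\theta$). Good spreaders have large reach.

On an isolated node both definitions collapse to a closed form: with
$E = 1000$, $D = 5$, $\theta = 1$ the energy after $t$ steps is
$1000 - 5t$, first below 1 at $t = 200$:

```{r closed-form}
iso <- interaction_network(character(0), character(0), isolated = "A")
run_perturbation(iso, "A", perturbation_config(E = 1000, D = 5))
```

## Parameters and defaults

| parameter | meaning | default | rationale |
|---|---|---|---|
| $E$ | starting energy (units) | 1000 | traceable dynamics at desk scale; the robustness grid also uses 10000 |
| $D$ | dissipation (units/node/step) | 5 | drains a 1000-unit perturbation in at most 200 isolated-node steps; grid also uses 1 |
| $\theta$ | silencing/reach threshold (units) | 1 | one concept serves both metrics |
| $k$ | per-edge flow coefficient | $1/(\deg_{\max}+1)$ | the explicit-Euler stability bound of $I - kL$: eigenvalues of $L$ lie in $[0, 2\deg_{\max}]$, and $k \le 1/(\deg_{\max}+1)$ keeps the flow phase monotone with no overshoot or oscillation |
| `max_steps` | safety cap | $10\,E/\theta$ | unreachable in exact arithmetic (see below); hitting it is always reported |

Three ordering conventions had to be fixed because the model statement
leaves them open; they are config-visible choices, not derived facts:

- **Update order** is flow first, then dissipation; one (flow +
  dissipation) pair is one time step.
- **Silencing is evaluated after dissipation**; a network already below
  $\theta$ at $t = 0$ has silencing time 0. Evaluating before dissipation
  would differ by at most one step at the default parameters.
- **Reach uses the silencing threshold.** "Received the perturbation"
  means holding at least $\theta = 1$ unit at some point after a flow
  sub-phase.

Energies are real-valued throughout — the flow rule reads most naturally
as continuous — and the per-edge flow constant is exposed as `k` in
`perturbation_config()` so users can explore other conductances below the
stability bound.

Termination is guaranteed analytically: while any node holds $\geq \theta$
and $D \geq \theta$, dissipation removes at least $\theta$ in total per
step, so the silencing time is at most $E/\theta$ (1000 at defaults). With
$D < \theta$ the bound is $E/D$. The constructor therefore requires
`max_steps` $\geq E/\min(D, \theta)$, which makes the cap a pure guard
against numerical surprises.

## Implementation notes

All runs are independent, so `silencing_profile()` simulates many probes
as columns of one energy matrix against a shared sparse adjacency,
retiring columns as they silence; the unit tests verify the batched engine
is bit-identical to probe-by-probe `run_perturbation()` calls, and both
are checked elementwise against an independent dense $(I - kL)$ matrix
oracle on enumerated small graphs.

Centralities follow the conventions that make "fraction" statements true
on possibly disconnected graphs: closeness of a node in a component of
size $r$ is $\frac{r-1}{\sum d}\cdot\frac{r-1}{n-1}$ (within-component
inverse mean distance scaled by reachable fraction), and betweenness is
normalised by $(n-1)(n-2)/2$ with endpoints excluded. Geodesic distances
from drug targets to a disease set exclude unreachable disease members
from each target's mean by default and count them separately — averaging
over them is the only finite-valued reading when part of a disease set
falls outside the giant component; an alternative policy imputing the
network size as a penalty distance is selectable
(`unreachable_policy = "penalize"`), and `component_membership()` reports
how many members sit outside the giant component.

Group statistics mirror the conventions of base R, the de-facto standard
in this literature: `mann_whitney()` follows `wilcox.test` defaults (exact
for tie-free samples under 50, otherwise normal approximation with tie and
continuity correction), `welch_t()` uses Welch–Satterthwaite degrees of
freedom, and p-values are reported unadjusted. Deliberate tie-breaks keep
everything deterministic: equally large components break toward the
lexicographically smallest member ID, ambiguous ID mappings keep the
lexicographically smallest target (logged), and node deletion sorts IDs
before sampling so results depend only on the node set and seed.

## What the synthetic generator emulates

Real studies of this kind combine an interactome snapshot with drug-target,
side-effect and disease-gene annotations. Those databases cannot be bundled
or re-derived, so `synthetic_scenario()` plants the *structure* that drives
the analysis instead:

- a preferential-attachment network (complete seed graph on $m$ nodes,
  each new node attaching $m$ degree-weighted edges; exactly
  $m(n-m) + \binom{m}{2}$ edges, connected, heavy-tailed degrees) — the
  heavy tail is what makes spreading efficiency vary between nodes;
- drugs drawing 1–5 targets each, flagged as having side effects with
  probability 0.5 (balanced groups give the replicated tests reasonable
  power at 40 drugs);
- the planted ground truth: side-effect drugs pick targets with weight
  $\mathrm{degree}^\beta$ ($\beta = 2$ by default, $\beta = 0$ for null
  calibration). Degree is the right planting handle because seed degree
  anticorrelates strongly with silencing time under these dynamics
  (Spearman $\rho < -0.3$ is asserted in the tests; empirically
  $\rho \approx -0.93$ at $n = 1000$);
- two disease sets mirroring the central/peripheral contrast: a
  "cancer-like" set of 18 drawn from the top 5% of the degree
  distribution and a "diabetes-like" set of 14 drawn from the bottom 25%
  (the set sizes follow the colorectal-cancer and type-2-diabetes gene
  sets a full-scale interactome analysis would have).

All randomness flows from one scenario seed through deterministic
sub-stream seeds, so any component draw is independently reproducible and
`generate_scenario_bundle()` round-trips byte-identically through the TSV
loaders.

What passing the synthetic studies does *not* show: the generator produces
no degree correlations, clustering, or community structure beyond what
preferential attachment yields, its annotations are conditionally
independent given degree, and the "side-effect" flag carries none of the
reporting biases of real adverse-event data. Results on it validate the
*pipeline* — that the dynamics, statistics and bookkeeping recover a known
planted signal at the right error rates — not any biological claim about a
particular interactome.

## The replicated studies

The `*_study()` drivers and `scripts/acceptance.R` run the validation
experiments at fixed problem sizes, chosen as the smallest scales at which
the contrasts are stable across replicates: planted-effect recovery and
null calibration on $n = 2000$, 40-drug scenarios (50 biased and 200
unbiased replicates; Mann–Whitney on side-effect vs no-side-effect target
silencing times), the disease contrast on 50 replicates of the same size
with a 150-node background sample for the silencing-time tests, the
degree–silencing correlation on a single $n = 1000$ network, and
robustness as 10 replicates of 50% node deletion followed by giant
component extraction and group re-derivation. The expected outcomes are
asserted in `tests/testthat/test-acceptance.R`.

## Known limitations

- Flow is unweighted and undirected; confidence-weighted, directed or
  compartment-aware variants are out of scope.
- The per-drug side-effect flag is binary; side-effect frequency or
  severity weighting is not modelled.
- The exact flow constant, update order and reach threshold of other
  implementations of this model family are not recoverable; the choices
  here are documented above and exposed in the configuration rather than
  assumed to match any particular tool.
- `silencing_profile()` holds one dense column per probe in memory;
  for networks beyond ~10⁵ nodes probe batches should be chunked.
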