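---
title: "Fibration symmetries, input trees and building blocks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fibration symmetries, input trees and building blocks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibnet)
```

## The model

A directed multigraph `G = (V, E)` carries typed, integer-multiplicity edges;
in enzyme networks an edge `e1 → e2` typed by metabolite `m` means a reaction
catalyzed by `e1` produces `m`, which a reaction catalyzed by `e2` consumes.
The *input tree* `T_i` of node `i` is the layered tree of all directed paths
ending at `i`: layer 1 is the root, and layer `k+1` holds, for every node in
layer `k`, its in-neighbors, repeated according to edge multiplicity. Two
nodes with isomorphic input trees (an isomorphism must preserve edge types)
receive the same information history and, under admissible dynamics on the
network, synchronize. Maximal groups of such nodes are *fibers*; collapsing
each fiber to a single node yields the *base* `B` and a surjective graph
morphism `φ: G → B` with the lifting property: every edge into an image node
lifts uniquely to an edge into each preimage node. The dynamical equivalence
of `G` and `B` is represented in this package only by that structural check,
never by simulating dynamics.

## Minimal balanced coloring

`minimal_balanced_coloring()` computes the coarsest balanced coloring by
partition refinement: all nodes start with one color; each round, nodes are
re-keyed by (current color, in-profile), where the in-profile is the multiset
of (source color, edge type) pairs expanded by multiplicity; the loop stops
at the first round that creates no new class. Refinement only ever splits
classes, so a fixpoint is reached within `|V|` rounds (asserted). Design
choices:

* **In-edges only.** Input trees are built from incoming edges; out-degrees
  never influence colors.
* **Multiplicities count.** A node fed twice through one multiplicity-2 edge
  and a node fed once each by two same-color sources are equivalent; a node
  fed once is not. This is required for high-multiplicity blocks to get their
  elevated branching ratios.
* **Typed edges by default.** Distinct linking metabolites keep parallel
  edges distinct; `collapse_parallel = TRUE` merges them into one
  multiplicity when metabolite identity should be ignored. The default keeps
  types because the isomorphism definition respects link types.
* **Determinism.** Nodes are held in lexicographic order and color ids are
  assigned by first occurrence, so partitions, bases and all derived reports
  are byte-for-byte reproducible.

`is_balanced()` re-checks any partition directly against the definition and
returns the first violating pair; it serves as the independent oracle for the
refinement and as the precondition of `build_base()`, which maps each
fiber's lexicographically minimal member's in-edges through `φ` (balance
makes the member choice immaterial). Recoloring a base yields only
singletons — the base is minimal — and this is exercised in the tests.

## Layer sequences and the branching ratio

`layer_counts()` iterates the occurrence vector `occ_{i+1}(u) = Σ_v
mult(u→v) · occ_i(v)` from the root indicator; `a_i = Σ_u occ_i(u)` counts
paths of length `i−1` into the root. Counts are exact integers stored in
doubles, hence exact below 2^53; the property test that layer sequences of
generated blocks obey their recurrence exactly to depth 25 uses blocks whose
counts stay below that bound.

`branching_ratio()` tracks `r_i = a_{i+1}/a_i` while normalizing the
occurrence vector by its sup-norm each step to avoid overflow. Ratio
sequences oscillate around their limit (the high-multiplicity block with
self-loop ×6 and a ×4/×6 2-cycle oscillates around its fixed point
`3 + √33 ≈ 8.7446`, which is why a first-touch stopping rule can report
8.75), so convergence requires three consecutive steps with
`|r_i − r_{i−1}| < tol` (default `1e-9`). Empty layers mean a finite input
tree, reported as `r = 0` with status `finite_tree`; `r = 1` (within `1e-6`)
is a non-branching infinite chain. The limit equals the spectral radius of
the adjacency matrix restricted to the root's backward-reachable set whenever
that set's dominant class is aperiodic; a pure `d`-cycle with multiplicity
`n > 1` has no pointwise ratio limit (the ratio cycles through
`1, …, 1, n`), and the iteration then honestly reports `converged = FALSE`
at `max_iter` (default 10 000). The spectral-radius property tests therefore
generate blocks that always include a length-1 cycle, which guarantees
aperiodicity.

`recurrence_ratio()` iterates `a_i = Σ_d n_d a_{i−d}` directly (seeded
`a_1 = 1`, absent terms 0, window rescaled near overflow) and is
cross-checked in the tests against the dominant root of the characteristic
polynomial via `polyroot`.

## Building blocks and their taxonomy

`extract_block()` collects the fiber, its regulators (external
in-neighbors), and — when a fiber node reaches a regulator — every node on
every *shortest* such path (path length counts edges; multiplicity affects
`r`, not membership). One choice here was genuinely open: when a regulator
itself belongs to a nontrivial fiber, the block recursively absorbs that
whole fiber with its own regulators and feedback paths. The focal fiber's
input tree contains the regulating fiber's entire input tree, so without the
regulator fiber's circuitry the induced subgraph could not reproduce the
focal branching ratio — this is precisely what makes a feed-forward composite
inherit the regulating fiber's noninteger `r`.

`classify_block()` decides, in order:

1. a cycle crossing two or more nontrivial fibers (a strongly connected
   component of the block containing members of two fibers) makes a
   *Composite Feedback Fibonacci*. This test comes first because closing an
   inter-fiber loop can land on an integer ratio (the five-step ladder ends
   at exactly `r = 2`) which must not be mistaken for an `|n,l⟩` class;
2. otherwise a noninteger `r` (tolerance `integer_tol`, default `1e-6`,
   comfortably below the separation between desk-scale algebraic ratios and
   integers) is *Fibonacci*: simple with one nontrivial fiber, *Composite
   Feedforward* with several;
3. otherwise integer `r`: a single fiber is `|n,l⟩` with `n = round(r)`
   (0 for finite trees, 1 for chains) and `l` the number of regulator
   classes at base level (a regulator fiber counts once; trivial regulators
   individually); several fibers stacked acyclically form a *Multi-Layer*
   block whose label composes the per-fiber `|n,l⟩` labels in regulation
   order, e.g. `|0,2>+|0,0>`.

`fibonacci_conditions()` reports the two structural prerequisites of a
fractal tree — a fiber–regulator cycle, and a self-loop on the fiber or on
such a cycle — as independent flags, since a block can have a self-loop
without feedback (the `|1,1⟩` chain). `assign_defining_blocks()` maps every
fiber to its smallest containing block (shortest cycles dominate), ties
broken lexicographically.

## Synthetic data

The generators are first-class, tested code and define the study conditions:

* `make_fig_toy()` — the four-node illustration: two self-loop motifs
  distinguished by their linking metabolite. The published caption does not
  pin down the full wiring; this is the minimal wiring whose coloring
  reproduces the published two-fiber partition, and only that partition is
  asserted. With a single untyped metabolite all four nodes would
  legitimately merge, which is why the two halves use distinct edge types.
* `make_recurrence_block()` — realizes any cycle-term list `(d, n)` around a
  root, so layer sequences with prescribed recurrences can be produced and
  checked exactly.
* `make_ladder_steps()` — the five-step edge-addition progression from
  `|1,0⟩` to a two-fiber feedback composite. The downstream fiber is linked
  through a different metabolite than the fiber–regulator circuitry;
  otherwise the new fiber and the original regulator would (correctly) merge
  into one fiber, because both would receive exactly one edge from the same
  source fiber.
* `make_planted_fiber_network()` — plants groups with byte-identical
  in-neighborhoods fed by regulators with pairwise distinct self-loop
  multiplicities, using different edge types for regulator wiring and fiber
  feeds. The type separation is what makes recovery exact: with a single
  type, a member fed once by a regulator whose self-loop has multiplicity 1
  has an input tree genuinely isomorphic to the regulator's own chain, and
  the two would merge. Regulator subsets and multiplicities are drawn
  per-fiber but kept pairwise distinct, so the ground truth is recovered
  with ARI 1 by construction — which is what the recovery tests assert
  across 50 seeds.

What these fixtures emulate is the *combinatorial* structure of enzyme
networks (typed parallel edges, multiplicities, feedback); they do not
emulate organism-scale degree distributions, the density of real strongly
connected cores, or curation noise. Passing tests therefore demonstrate
algorithmic correctness on the defined conditions, not biological
completeness on deposited networks, whose fiber counts additionally depend
on the exact curation and currency-metabolite cuts used to build them.
Currency-metabolite removal is deliberately user-driven
(`rank_metabolites()` ranks, the caller excludes), mirroring a manual
discard step.

## Comparators

The adjusted Rand index follows the permutation-model contingency formula,
with an explicit `complete` flag that places nodes missing from one grouping
into singletons (for comparing partial covers such as motif membership
against full partitions); the tests cross-check it with independent
pair-counting. Directed modularity is evaluated exactly as the community sum
`Q = (1/m) Σ [A_uv − d_u^in d_v^out / m] δ(C_u, C_v)` with multiplicities in
`m`, `A` and the degrees; the greedy optimizer (local moves + aggregation)
is hand-written because no available routine optimizes the directed variant,
and it is validated against exhaustive partition enumeration on up to 8
nodes. The motif census counts node *subsets* whose induced connectivity
contains the pattern (mfinder-style; a `strict_induced` flag requires exact
matches), enumerating only weakly connected subsets (ESU) and verified
against exhaustive subset enumeration. The null model holds self-loops fixed
— they are structurally meaningful here — and attempts `10 × |E|`
double-edge swaps per draw; neither the swap count nor the default ensemble
size (1000; the orchestrating pipeline defaults to 100 to keep interactive
runs quick) is prescribed by the method's sources, so both are configurable.
A degenerate null (`σ = 0`) reports `Z = +∞` when the observed count exceeds
the null mean and 0 otherwise.

## Degenerate inputs and numerical conventions

Empty graphs color trivially; edgeless node sets form one fiber (all input
trees empty). Isolated and shell-fed nodes default to the `k_out` shell —
their role is not defined by the decomposition being mirrored, and the
choice is documented rather than claimed faithful. A singleton node with a
self-loop counts as an SCC member, consistent with treating self-loops as
cycles of length 1 in the Fibonacci conditions. Presentation rounds ratios
to two decimals; computation never rounds. Problem sizes in the test suite
(random graphs of up to 12 nodes for oracle equivalence, 200 instances;
blocks of up to ~10 nodes for spectral checks; 50 planted-recovery seeds)
were chosen so that brute-force oracles — recursive tree signatures,
transitive-closure SCCs, exhaustive subset motif counts, full partition
enumeration — remain exact references.

## Known limitations

No probabilistic or approximate symmetry detection (broken fibers are not
repaired); no SBML/BioPAX parsing; reversibility is handled only by the
`reversible` flag that mirrors every reaction; no dynamical simulation of
synchronization; organism-scale reproduction requires the externally
deposited networks, which the pipeline accepts as plain edge lists but does
not bundle.
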