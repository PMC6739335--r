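---
title: "Boundary-reaching control: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-reaching control: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brcnet)
```

## The model

brcnet works with synchronous Boolean networks: `n` named nodes, each
with a logical update rule over its inputs, all nodes updating
simultaneously. The state space has `2^n` states and the update map is a
*function* — every state has exactly one successor. Three consequences
shape the whole package:

- every trajectory ends in an attractor (a fixed point or a cycle);
- basins of distinct attractors partition the state space;
- preimages of disjoint state sets are disjoint, so backward exploration
  forms a forest of in-trees rooted at the attractor cycle.

Rules are stored as truth tables over their *essential* inputs: an input
the table does not actually depend on is pruned at construction. This is
not cosmetic — the structural classifications below are topological, and
a syntactic-but-inert edge would give a node a spurious positive
outdegree and block its peeling. A self-loop counts toward outdegree, so
a self-regulating node is never peeled.

Asynchronous and probabilistic update schemes are out of scope, as is
SBML-qual import; the text rule dialect (`target, expression` lines with
`&`, `|`, `!`, parentheses and the constants 0/1) is the interchange
format.

## Exact basin identification

Given a desired attractor `beta = [S1, ..., Sc]` (verified by stepping),
the basin is computed in five stages.

**Symmetric-node peeling.** A node with outdegree 0 influences no other
node, so whether a state converges to `beta` cannot depend on its value:
every basin is closed under flipping it, and its marginal mean over any
basin is exactly 0.5. Peeling such nodes (and repeating on the
subnetwork, since removal can expose new outdegree-0 nodes) splits the
network into `n_sym` symmetric nodes and a core with no outdegree-0
node. The basin factorises as
`{all 2^n_sym symmetric values} x {reduced basin of the projected
attractor}`, so all further work happens on the core and the final count
is `reduced count * 2^n_sym`. Peel rounds are recorded for reporting,
though the algebra needs only the set; peeling is order-independent (any
removal order of currently-outdegree-0 nodes reaches the same fixpoint),
which the test suite verifies by randomised orders.

**Deterministic inversion.** If node `y` has exactly one essential input
`x`, then `y`'s rule is a non-constant 1-input function — identity or
negation — hence invertible: observing `y(t+1)` forces `x(t)`. Such `x`
are *deterministic* nodes. A rule that is constant in its single input
cannot force anything, but that case cannot arise here: a constant rule
has no essential input and `y` would have indegree 0, not 1. (This is
the package's resolution of an otherwise ambiguous corner: inversion is
only ever applied to invertible rules, by construction.) When several
indegree-1 nodes share the same input, the first supplies the primary
inverse and the rest act as consistency checks.

**Terminal-state conditions.** A state with no predecessor ends a
backward branch. Two sufficient (not necessary) conditions are checked
cheaply before running the exact solver:

1. two indegree-1 targets of the same deterministic node force
   contradictory values on it;
2. for a nondeterministic node with at least one deterministic input,
   substituting the forced deterministic values and ranging every
   remaining input over {0, 1} cannot produce the node's observed value.

Because the conditions are merely sufficient, a `FALSE` means "unknown";
the exact predecessor computation below terminates such branches anyway
when the preimage is empty. The conditions are purely an accelerator —
disabling them changes nothing but runtime — and their soundness (no
flagged state has any predecessor) is property-tested against exhaustive
preimages.

**Exact preimages as wildcard cubes.** The predecessors of a target
state are the solutions of the Boolean system `f_v(prev) = target[v]`
for every node `v`, with deterministic coordinates pre-forced by
inversion. The package deliberately enforces *all* nodes' equations, not
only those of nondeterministic nodes: for indegree-1 targets the extra
equations coincide with the inversion and its consistency checks, and
enforcing the rest guarantees the result is the exact preimage whatever
the network's structure. The solver runs unit propagation to a fixpoint
(restricting each constraint's truth table by the partial assignment,
failing on an empty restriction, fixing variables that take one value in
all compatible rows), then branches on the unassigned variable occurring
in most active constraints. Variables left unconstrained become `*`
wildcards, so each emitted pattern over `{0, 1, *}` is a cube of
predecessor states. Branching on a variable's two values yields disjoint
cubes by construction, which keeps counting trivial and exact:
`sum(2^wildcards)` per cube, no inclusion–exclusion. Counts are doubles
(exact through `2^53`) and are exported as decimal strings.

**Layering and lifting.** The local basin of attractor state `S_q`
starts with layer 1 = `{S_q}`; each next layer is the exact preimage of
the current one, minus the attractor's own states. Removing the
attractor states is what keeps the local basins of distinct attractor
states disjoint (the cycle predecessor of `S_q` is `S_{q-1}`, which
roots its own local basin). No other deduplication is needed: since the
dynamics is a function, backward layers can never reconverge — a design
simplification this package relies on and asserts in tests, rather than
paying for a global visited set. Preimages are taken of whole cubes, not
of individual states (a cube's preimage simply constrains fewer
coordinates), so compression is preserved across layers. A configurable
cube-count guard (`max_cubes`, default 10^6) aborts exact mode with a
clear message when a basin is too large for desk-scale memory; runs at
that scale belong on a cluster.

## Control target identification

Basin nodes are decomposed by their values across the basin:

- *symmetric*: the structurally peeled nodes, plus any core node whose
  single flip maps the basin onto itself. The flip-closure reading is
  applied per node (the stronger interpretation) and verified directly
  on the cube set; a node failing verification is treated as unfixed,
  which is always safe.
- *fixed*: nodes taking one value in every basin member (read off the
  cube columns);
- *unfixed*: the rest.

For an undesired state `alpha`, the minimum Hamming distance to the
basin separates exactly: symmetric nodes cost nothing, every fixed-node
disagreement must be corrected (`rho_fixed`), and the unfixed
coordinates cost the minimum mismatch over basin members, computed per
cube on its non-wildcard unfixed positions (`rho_unfixed`); `mHD =
rho_fixed + rho_unfixed`. The per-cube minimum equals the true minimum
over members because within a cube every wildcard can match `alpha`.

The minimum control target sets are then the mandatory fixed corrections
plus one mismatch set from each cube attaining `rho_unfixed`
(deduplicated); applying any of them to `alpha` yields a basin member —
the corresponding boundary state — which the implementation re-verifies
at run time. The number of distinct sets can explode combinatorially, so
the reported list is capped (default 10^4) while the exact total is
always returned. On small networks the test suite checks both
minimality (no smaller flip set lands in the basin) and completeness
(every minimum flip set is emitted) against exhaustive search.

When the desired basin covers most of state space the exact basin is
unnecessary: `large_basin_control_search` enumerates flip sets
breadth-first by size over a caller-supplied candidate node list and
accepts a flip when forward simulation converges to a desired attractor.
The candidate list is a first-class parameter because practical case
studies exclude input nodes, output/phenotype nodes, conceptual nodes
and known persistent-intervention targets from perturbation.

## Temporary versus persistent interventions

A temporary perturbation overwrites the chosen node values once and lets
the network run; success means converging to the desired attractor with
no further contact with the system. Persistent clamping instead holds
the target values at every step, which spreads: stage 1 is the clamped
pattern, and stage `k+1` fixes every node whose rule is constant over
all completions of the stage-`k` pattern, decided by exact truth-table
restriction rather than heuristics. The fixed set grows monotonically
and closes within `n` stages; when it pins all nodes, the final state is
a fixed point of the clamped dynamics. Both the number of *states* in
the cascade and the number of *transitions* (states − 1) are reported,
because both counting conventions are in common use and they differ by
exactly one.

`interruption_success_rate` quantifies the practical weakness of
persistent control: clamps are imposed, held for `K` transitions,
then released, and the free dynamics is followed to its attractor. With
`K = 0` no clamping is applied at all, so the rate is the sample's
unperturbed desired-basin fraction; holding past cascade closure always
succeeds. Rates carry binomial standard errors `sqrt(p(1-p)/n)`.

## Monte-Carlo landscape estimation

For networks beyond exhaustive enumeration (the exact enumerator is
capped at 22 nodes by its `2^n` memory), the attractor landscape is
estimated from uniform random initial states — uniform over the free
nodes only, when clamps are in play — each followed to its attractor,
pooled by canonical form (cycles rotated to start at their minimal
integer encoding; no similarity merging). Basin ratios carry binomial
standard errors. The sampling distribution is a modelling choice: states
of a cell are not uniform, but uniformity is the standard neutral prior
for landscape estimation and is what the reported fractions mean.

Phenotype conditions (`node = value`, required constantly across an
attractor) label attractors desired or undesired; attractors whose
constrained nodes oscillate match neither label and are reported as
"other". Control-target probabilities pool all enumerated minimum
control sets over many sampled undesired states; the Pearson correlation
between a node's inclusion probability and the absolute difference of
its mean activity in undesired versus desired states is computed with
the usual t-transform p-value, with no multiple-testing correction since
a single pair is tested per network.

## The synthetic-data generator

`random_boolean_network` emulates the structural features the algorithms
exploit: a planted feed-forward chain of `n_peelable` nodes ending in an
outdegree-0 node (guaranteeing peelable structure), a tunable fraction
`p_deterministic` of indegree-1 copy/negation rules (seeding
deterministic equations), and random truth tables at indegrees up to
`k_max` elsewhere. Defaults (`k_max = 2`, `p_deterministic = 0.3`,
`n_peelable = 1`) reflect the sparse, canalising character of curated
regulatory logic, where mean indegree is small and single-input
activations/inhibitions are common. The generator does *not* emulate
scale-free degree distributions, the motif composition of real
signalling networks, or biologically meaningful phenotype nodes; passing
tests on generated fixtures therefore demonstrates algorithmic
correctness (basins, distances, control sets are exact), not biological
fidelity of any particular model. Published case-study rule sets can be
loaded through `load_model` once transcribed into the rule dialect; the
bundled `toy7` model is a synthetic reconstruction whose printed
behaviour (peel order, deterministic structure, fixed node, terminal
state, unique boundary flip) matches the worked example it illustrates,
found by randomised search under those constraints.

## Numerical and degenerate-input choices

- State encoding: node 1 is the least significant bit everywhere;
  attractor cycles are canonically rotated to their minimal encoding
  (ties impossible — cycle states are distinct). Wide networks
  (n > 53) compare encodings lexicographically on reversed bit strings
  instead of as numbers.
- Cycle detection uses an exact visited-state hash, not
  constant-memory cycle-finding: transients in regulatory models are
  short, and exactness of the transient length matters downstream.
- An empty core (everything peels — a feed-forward cascade) is legal:
  the reduced basin is the single empty pattern with count 1 and the
  full basin is the whole space, `2^n_sym` states.
- A cyclic attractor on an empty core is rejected as inconsistent (it
  cannot arise from a well-formed reduction).
- Empty preimages, basins at the memory guard, impossible phenotype
  sampling and contradictory clamps all fail with explicit messages
  rather than returning partial results.

## Problem sizes in the test suite

The suite validates exactness where exactness can be checked: backward
basins against forward brute force on a few hundred seeded random
networks of 5–14 nodes, control sets against exhaustive flip-set search
up to 12 nodes, terminal conditions against exhaustive preimages up to
8-node cores, and Monte-Carlo ratios against exhaustive fractions at
9–10 nodes. These sizes were chosen so the whole suite runs in well
under a minute while still covering every code path (cycles, empty
cores, all-symmetric networks, capped searches); the algorithms
themselves are size-independent and the cube representation is what
carries them beyond enumerable scales.

## Known limitations

- Exact basin identification is worst-case exponential; the structural
  reductions and cube compression defer, not remove, the blow-up. The
  `max_cubes` guard makes the failure mode explicit.
- Boundary states are chosen by Hamming distance alone; robustness of a
  boundary state to stochastic node fluctuation after the push is not
  assessed.
- Only synchronous deterministic dynamics is modelled; biological
  asynchrony can change both attractors and basins.
- Basin-level symmetric-node detection beyond structural peeling checks
  single-node flips only; closure under simultaneous multi-node flips
  that is not generated by single flips would be classified as unfixed
  (safe, but conservative).
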