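# brcnet — boundary-reaching control of synchronous Boolean networks

Boolean network models represent a molecular regulatory system as named
nodes with logical update rules under synchronous dynamics. Every cell
phenotype corresponds to an attractor (a fixed point or cycle of states),
and the set of states converging to an attractor is its basin of
attraction. A central question for network medicine is: given a network
sitting in an undesired state α (say, a proliferative cancer state), what
is the *smallest one-time* perturbation that moves the system into the
basin of a desired attractor, after which it converges on its own — no
sustained drug pressure, no persistent gene knockout?

brcnet implements this *boundary-reaching control* (BRC) workflow for
researchers working with logical models of signalling and regulatory
networks:

1. **Exact basin identification.** The basin of a desired attractor
   β = [S₁, …, S_c] is identified backward, layer by layer, starting from
   the attractor states. Structural reductions make this tractable:
   - *Symmetric nodes*: outdegree-0 nodes influence nothing, so every
     basin is closed under flipping them; they are peeled iteratively and
     reattached afterwards as a free 2^n_sym-fold lift.
   - *Deterministic equations*: if node y's only essential input is x,
     then y's rule is invertible and x(t) = f⁻¹(y(t+1)) — the past of x
     is forced by the present of y.
   - *Terminal-state conditions*: contradictory forced values, or an
     unreachable value of a node with deterministic inputs, prove a state
     has no predecessor, pruning the backward search.
   - Remaining coordinates are solved as Boolean constraint systems with
     unit propagation, emitting disjoint wildcard cubes (`0/1/*`
     patterns) so that huge basins are stored compactly with exact
     counts.
2. **Control target identification.** Basin nodes decompose into
   symmetric / fixed / unfixed. The minimum Hamming distance from α to
   the basin is mHD = ρ_fixed + ρ_unfixed, and all minimum control target
   sets (node → value assignments of size mHD) are enumerated together
   with the boundary states they reach. When the desired basin covers
   most of state space, a forward flip-set search
   (`large_basin_control_search`) finds the same targets without the
   exact basin.
3. **Intervention comparison and landscape estimation.** One-time
   temporary perturbations are simulated against persistent clamping
   (with its stage-wise indirect fixation cascade and
   interruption-success curves), and Monte-Carlo sampling estimates the
   attractor landscape of networks too large to enumerate.

## Worked example

The bundled `toy7` model (a synthetic 7-node reconstruction of the
published worked example, nodes A–G) has a desired fixed point
β = 1011110. Identify its exact basin, decompose it, and control the
undesired state α = 0000100:

```r
library(brcnet)
toy   <- load_model("toy7")$network
beta  <- find_attractor(toy, as_state("1011110", toy$nodes))$attractor
basin <- basin_of_attractor(toy, beta)
basin
#> Exact basin of attraction
#>   network: 7 nodes; 2 symmetric, 5 core
#>   attractor length: 1
#>   reduced basin: 6 states in 5 cubes
#>   full basin size: 24 (fraction 0.1875 of 2^7)

decompose_basin_nodes(basin)
#> Basin node decomposition
#>   symmetric: G, F
#>   fixed:     C=1
#>   unfixed:   A, B, D, E

alpha <- as_state("0000100", toy$nodes)
control_target_sets(alpha, basin)
#> Boundary-reaching control result
#>   alpha: 0000100
#>   mHD: 1 (fixed 1 + unfixed 0)
#>   control target sets: 1
#>    { C=1 }
```

Peeling removes G then F (2 symmetric nodes), the 5-node core's basin
holds 6 states in 5 wildcard cubes, and lifting over the symmetric nodes
gives the exact basin of 24 of the 128 states. Node C is fixed at 1
across the basin while A, B, D, E vary, so correcting C is mandatory and
sufficient: the unique minimum control target set is {C → 1}, reaching
the boundary state 0010100 at Hamming distance 1. Applying it once and
simulating freely,

```r
tp <- temporary_perturbation(toy, alpha, c(C = 1L))
apply(tp$trajectory, 1, state_string)
#> [1] "0010100" "1011111" "1011110"
```

the network walks from the boundary state into β without further
intervention.

A thin command-line front end wraps the same functions:

```sh
exec/brc control --network toy7_synthetic.bnet --state 1011110 --alpha 0000100
```

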