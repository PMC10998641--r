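---
title: "Bushiness, convergence and Z-parameters of Boolean network STGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bushiness, convergence and Z-parameters of Boolean network STGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolstg)
```

## The model

A Boolean network on N nodes assigns each node i a truth table f_i over an
ordered list of k_i regulators. Under synchronous update every node applies
its rule simultaneously, so each of the 2^N states has exactly one
successor and the whole dynamics is a functional graph — the state
transition graph (STG). Trajectories end in fixed points or cycles;
asynchronous update schemes are out of scope for this package.

Throughout, truth tables use one fixed convention: row r (0-based) holds
the output at the input vector whose binary expansion, with the *first*
input as the most significant bit, equals r. Network states are encoded
the same way (node 1 = most significant bit). This single convention makes
the 2^i-row blocks of a table correspond to hyperplanes of the input
hypercube and keeps the STG code index-only.

## Global measures

The dynamics contracts phase space: after one update only the states with
at least one predecessor remain. States with none are garden-of-Eden (GoE)
states, and

- **G-density** = |GoE| / 2^N is the one-step contraction factor,
- the mean in-degree of non-GoE states equals 1/(1 − G-density) — an exact
  identity (the 2^N outgoing edges land on the (1 − G-density)·2^N non-GoE
  states), which the test suite asserts to machine precision on every STG
  it builds.

Convergence is measured through transient lengths. The transient length of
a state is the number of synchronous steps to the *first* state of its
attractor, so it is 0 exactly on attractor states — including every state
of a cyclic attractor. This choice keeps λ well-defined for cycles and
matches the intuition "steps to reach the attractor". Then

- λ_GoE = 1/mean transient over GoE states (undefined for bijective
  dynamics, which have no GoE states; reported as `NA` with a flag),
- λ_all = 1/mean transient over all states,
- λ_random = the sampling estimator of λ_all: uniformly sampled start
  states walked forward until their trajectory revisits a state, with a
  bootstrap standard error (200 resamples, seeded). In exhaustive mode it
  reproduces λ_all exactly, which the tests use as an oracle.

`build_stg()` enumerates all states vectorially, finds attractor states by
iteratively peeling zero-in-degree states (what remains lies on cycles),
and assigns transient lengths by reverse breadth-first search from the
attractor states. The exhaustive bound is N ≤ 20 (about a million states)
by default — large enough for typical published gene regulatory network
models while keeping memory in the hundreds of megabytes; it is a plain
argument, not a hard limit.

## Rule-table descriptors

### The Z-parameter adapted to Boolean functions

For cellular automata, Wuensche's Z-parameter estimates the probability
that the next unknown cell of a partial pre-image is uniquely determined —
a rule-table quantity that correlates with the bushiness of the STG. Two
obstacles arise for Boolean networks: every node has its own rule, and a
node's inputs have no spatial order.

For one input ordering, `n_vector()` scans the truth table recursively
from the full block down. A 2^i-row block is *complement canalyzing* (CC)
when its top half (the sub-block where the splitting input is 0) is
constant at one output value and its bottom half constant at the
complement; such a block contributes its 2^i rows to n_(k−i+1) and is not
descended into (sub-blocks of a contributing block never contribute).
`z_left()` then aggregates

Z_left = 2^−k · Σ_j n_j · (1/2)^(k−j),

i.e. a CC-2^i-block contributes its rows with weight (1/2)^(i−1). This
weighting is the unique one consistent with the closed forms below: the
package's NCF oracle test recomputes Z_max, Z_min and Z_mid by brute force
over all k! orderings for *every* nested canalyzing function with k = 2–4
inputs and checks exact equality with the closed forms, which pins the
formula mechanically. It also gives the expected limits: constants → 0,
parity → 1 (fully pre-image-deterministic), single-input identity → 1.

Because inputs are unordered, `z_variants()` evaluates Z_left under all k!
orderings and reports Z_max, Z_min, Z_ave (mean) and
Z_mid = (Z_max + Z_min)/2. Useful exact properties, all asserted as tests:

- Z_left is invariant under negating any input and under complementing the
  output.
- Grouping the k! orderings by the permuted output column yields m
  distinct tables with *equal* multiplicities, and m divides k!; hence
  Z_ave can be computed over distinct permuted tables only
  (`distinct_permutations()`).
- For a k-input nested canalyzing function of bias P (P odd, ≠ 2^(k−1)):
  Z_max = P/2^(k−1) for P < 2^(k−1) and 2 − P/2^(k−1) above;
  Z_min = 1/2^(k−1); Z_mid = (1+P)/2^k below and 1 − (P−1)/2^k above
  (`ncf_closed_forms()`): Z_min depends on k only, and Z_max, Z_mid are
  linear in P — making these descriptors scalable for NCFs at any k.

The k! enumeration is bounded at k ≤ 8 (8!·256 table evaluations is
sub-second); above that `z_variants_sampled()` offers seeded
sampled-ordering estimates, clearly flagged as such. A median-of-Z_left
summary is available via `z_variants(median = TRUE)` but is not one of the
four variants.

At the network level `network_descriptors()` averages each variant over
nodes (Z̄_max, Z̄_min, Z̄_ave, Z̄_mid), along with the average sensitivity
s (mean number of output-changing single-input flips, in [0, k], not
normalized by k) whose node mean s̄ equals the one-step Derrida response δ
(`derrida_response()` can also sample the full Derrida curve).

### Function classes

Class tests are exhaustive over the table: `effectiveness()` (every input
matters somewhere), `input_signs()`/unateness (each input purely
activating or inhibiting), `is_ncf()` (recursive canalyzing-variable
peeling; at k = 1, identity and negation count as trivially nested
canalyzing, constants never do). `enumerate_class()` lists complete
classes for k ≤ 4: brute-force filtering for EF/EUF, constructive layer
structures for NCFs (deduplicated; brute-force filtering cross-checks at
k ≤ 3) and recursive AND/OR composition over signed literals with
memoization over variable subsets for read-once functions. Truth tables
serialize to one text line and to an integer encoding with row 0 as the
least-significant bit; the bit-order convention is isolated in the
`encode_integer()`/`decode_integer()` pair so it could be flipped in one
place if interoperability ever demanded it.

## Constrained ensembles

`generate_ensemble()` draws models that share one structure (nodes plus
ordered regulator lists) and keep a declared set of fixed points fixed,
while the node functions range over a class (EF, EUF, RoF, NCF). Each
fixed point X* pins, for node i, the truth-table row addressed by the
regulator values in X* to x_i* (`fixed_point_constraints()`; two fixed
points demanding different outputs on one row are reported as a structural
impossibility). Because the fixed-point property factorizes over nodes,
node functions are sampled independently given their row constraints; an
explicit `synchronous_step()` check of every declared fixed point of every
model backstops the sampler.

Sampling strategies per class: EF — uniform free rows with rejection until
effective; NCF and RoF at k ≤ 4 — uniform draw from the enumerated class
filtered by the constraints; NCF at k > 4 — random layer structure with
rejection; RoF at k > 4 — random read-once expression trees (random
binary splits, AND/OR labels, literal signs) with rejection; EUF at k ≤ 4
— uniform draw from the enumerated class; EUF at k > 4 — a
color-propagation sampler on the Boolean hypercube
(`sample_euf_colorprop()`): inhibiting inputs are mapped to activating
coordinates so the target is monotone, constrained vertices are
pre-colored and closed under monotonicity, then uncolored vertices are
picked uniformly, assigned a uniform output and closed (any vertex above a
1 becomes 1, below a 0 becomes 0), restarting on contradiction or
ineffectiveness. This sampler is *not* exactly uniform; the tests bound
its total-variation distance from uniform by 0.1 on the fully enumerable
cases (k ≤ 3, 10^4 draws), and the enumeration route keeps small-k
sampling exactly uniform. Input signs come from a user-supplied sign map
when regulation signs are known; otherwise a uniform random orientation is
drawn per attempt, which covers every effective unate function (each has a
unique sign signature). The per-node rejection budget defaults to 10^4
attempts before a constraint set is declared infeasible.

## Proxy analysis

`measure_ensemble()` surveys an ensemble into one row per model (global
measures plus descriptors; λ_random optional, seeded per model).
`spearman()` is rank correlation with average ranks on ties;
`proxy_evaluation()` treats the top-q fraction of a global measure as the
positive class (q = 0.05 by default, matching a "top 5% of models"
selection scenario; configurable), scores models by the *negated*
descriptor — lower Z̄_mid or s̄ predicts a bushier STG — and reports AUROC
(rank statistic), AUPRC (precision–recall step integration) and the mean
relative reference rank of the best-q descriptor stratum, where 0.5 means
no predictive power.

## What the generators emulate — and what they do not

The random-structure fixture draws each node's in-degree uniformly from
1..k_max (k_max = 3 by default, comparable to the mean in-degree of
curated gene regulatory network models such as the bundled 11-node myeloid
differentiation structure with its 30 edges) and its regulators uniformly
without replacement, self-loops allowed. That reproduces the scale and
connectivity of small published models, but not their degree
heterogeneity, motif structure or the co-occurrence of signs along
feedback loops; conclusions from passing tests therefore transfer to real
networks only at the level of trends, not effect sizes. The trend tests
themselves run scaled down by design — 8-node structures, one enforced
fixed point, 100 models per class ensemble — rather than at the scale of
exhaustive published-model surveys; the chain, identity and constant
fixtures are analytic edge cases (single-GoE chain with λ_GoE = 1/H,
requiring H = 2^m − 1 by its down-counter construction; bijective
dynamics; one-step total collapse) used as exact oracles.

## Numerical choices and degenerate inputs

- "Top half" of a block is where the splitting input is 0, fixed by the
  MSB-first row order; all Z quantities are dyadic rationals computed in
  doubles, so equality tests can be exact.
- k = 1 truth tables: identity and negation have Z_left = 1; constants 0.
  Constant nodes (k = 0) are legal in networks, parse with a warning, and
  contribute 0 to every network descriptor mean; the class samplers never
  produce them.
- λ_GoE is undefined (NA, flagged) exactly when dynamics are bijective;
  λ_random is undefined when every sampled transient is 0.
- Ties in `proxy_evaluation()` positives are broken by first occurrence at
  the q-quantile boundary; AUROC uses average ranks so tied scores count
  one half.
- All stochastic code takes explicit integer seeds; identical seeds give
  byte-identical survey tables.

## Known limitations

- Exhaustive STG construction stops at the memory wall around N ≈ 20; no
  symbolic/SAT pre-image counting is attempted.
- Z variants above k = 8 inputs are sampled estimates, not exact.
- The unate sampler's residual non-uniformity at large k is unquantified
  beyond the small-k total-variation bound.
- Ensembles are constrained by fixed points only; cyclic attractors are
  not supported as constraints.
- Read-once enumeration relies on output-column deduplication, which is
  exact but does not yield canonical expression syntax trees.
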