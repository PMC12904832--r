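---
title: "Fixed-order reduction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-order reduction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BitRepro)
```

## The problem

A distributed reduction combines `n` elements `e0 ... e(n-1)`, spread over
`p` processing elements (PEs), with an associative binary operator into one
result, `r = e0 ⊕ e1 ⊕ ... ⊕ e(n-1)`. For IEEE 754 floating-point addition
and multiplication, associativity holds only in exact arithmetic: every
machine operation rounds, so regrouping the same operands changes the result
in the last bits. Conventional parallel reductions group operands by data
distribution — each PE folds its local elements, then per-PE partials are
combined — so the realized grouping, and hence the result, depends on `p`.
In iterative optimization such as maximum-likelihood phylogenetic tree
search, where a branch-length or topology decision can hinge on a
comparison of two nearly equal scores, these last-bit deviations can
cascade into different final topologies.

BitRepro makes the reduction *bit-reproducible*: the result is a pure
function of the input array (and the operator), independent of `p`, of the
communication-tree degree, and of which PE owns which element.

## The algorithm

Three structures are separated deliberately:

1. **Reduction tree** (`buildReductionTree(n)`): a balanced binary tree
   over the `n` globally ordered elements. Its post-order traversal is the
   *definition* of the operation order. An interval `[a, b)` splits at
   `a + ceiling((b-a)/2)`; the tree depends only on `n`.
2. **Communication tree** (`buildCommTree(p, degree)`): a k-nomial tree
   over the PEs. The parent of rank `r > 0` is `r` with its lowest nonzero
   base-k digit cleared; for `k = 2` this is the classic binomial tree.
   It has exactly `p - 1` edges — the minimum number of messages for a
   reduction — and depends only on `(p, k)`.
3. **Schedule** (`compileSchedule`): the pre-processing step, run once per
   data distribution. Each leaf's push is assigned to its owner PE; each
   internal node's reduction is assigned to the lowest common ancestor (in
   the communication tree) of its children's PEs; the final result is
   routed to PE 0. Post-order traversal is realized as a stack machine with
   two operations, push-value and reduce-two-values: each PE executes its
   assigned ops sorted by global post-order position, and its residual
   stack, bottom to top, is exactly the one message it sends to its
   communication parent. A value consumed even higher is simply received
   and left on the stack — forwarding costs no extra messages.

At reduce time (`executeReduce`) the per-PE programs run against concrete
values. Because every PE's ops are sorted by the same global order, the
flattened sequence of reduce operations is precisely the post-order of the
reduction tree, for every `p`, degree and ownership map — hence bitwise
reproducibility for *arbitrary* associative operators, not only summation.
`executeAllReduce` appends a broadcast down the communication tree
(`2(p-1)` messages in total); broadcasting copies bits.

The operator is always applied as *(earlier post-order value) ⊕ (later
post-order value)* — the value popped second combines with the value popped
first. Commutativity is recorded but never exploited; consequently the
non-commutative concatenation monoid is a complete witness: if every
configuration returns the concatenation in global index order, the realized
operation order is the fixed tree order.

## The simulated engine

PEs are simulated deterministically in one process. The reference engine
interleaves PEs round-robin (forward or reverse) or runs them in
child-before-parent order, blocking a PE whose next op is a receive from an
unfinished sender; messages flow only from communication-tree children to
parents, so no interleaving can deadlock and — by contract, asserted in the
tests — none can change the result. Numeric operators additionally have a
compiled fast path (plain `double` arithmetic, no fused multiply-add, no
reassociation) that realizes the identical order; the tests assert bitwise
agreement between both engines. Any future optimized local kernel must
reproduce the same tree order bit-exactly — that contract, not a particular
vectorization, is what the package ships.

Two baselines frame the algorithm. `gatherBcastReduce` is the
reproducible-but-serial fallback: all elements funnel to the root
(`p - 1` messages, all `n` elements at one PE), which restores the global
order and folds left to right. `naiveReduce` is the conventional
non-reproducible scheme: per-PE left folds, then a fold over per-PE partials
in rank order — intentionally `p`-dependent for floats, and demonstrably so
on the cancellation inputs below.

## Accuracy

The balanced-tree order is not only reproducible; pairwise summation has a
smaller worst-case rounding error than a single left-to-right accumulator
(error growth O(log n) vs O(n) in the classic analyses). The package
quantifies this against `exactSum`, an error-free-transformation expansion:
every double is a rational number, and threading each addend through a
two-term transformation keeps a small set of non-overlapping components
whose exact sum *is* the exact real sum. Over 100 seeded cancellation
inputs of 1000 values, the median absolute error of the pairwise tree is at
most that of the left fold (the acceptance suite recomputes this).

## The phylogenetic demonstrator

The likelihood of a tree factorizes over alignment sites; production
inference tools compute per-site log-likelihoods in parallel and sum them.
Load balancers assign sites to PEs in a `p`-dependent way, so a per-PE
accumulator makes the total `p`-dependent. The demonstrator decouples the
two concerns: per-site values (Felsenstein pruning under JC69:
`P_same(t) = 1/4 + 3/4 e^(-4t/3)`, uniform base frequencies, gaps and N as
all-ones partials) are written at their global site index, and the total is
obtained with the fixed-order reduction — bitwise identical for every `p`,
including configurations where some PEs own no sites. The model is fixed to
JC69 on purpose: the demonstrated principle is accumulation-order
decoupling, not model sophistication; rate heterogeneity, GTR, derivative
kernels and branch-length optimization are out of scope. Sites are never
deduplicated (pattern compression would change the accumulation geometry).

`partitionSites(n, p)` emulates the defining property of a load balancer —
contiguous blocks of size `ceiling(n/p)` or `floor(n/p)`, larger blocks
first — without reproducing any particular production balancer; only
`p`-dependence matters for the demonstration.

Numerical conventions: a site of likelihood 0 yields `-Inf`, which is
propagated (never clamped) and counted. Trees read from unrooted Newick are
evaluated at the stored root node with children folded in their stored
order; under a reversible model the likelihood is rooting-invariant up to
rounding, so one fixed rooting is used everywhere rather than re-rooting
the input. No per-site rescaling is applied — with at most dozens of taxa
the per-site likelihood stays far above the double-precision underflow
threshold; very large trees would need scaled partials.

## Divergence metrics

Repeated runs that differ only in parallelization are compared by the
relative Robinson–Foulds distance: the proportion of non-trivial
bipartitions (splits induced by inner edges) that differ,
`|B1 Δ B2| / (|B1| + |B2|)`, which equals the RF distance normalized by
`2(n-3)` for binary trees. The denominator uses the actual split counts so
multifurcating search outputs are handled, and `0/0` is defined as 0
(two stars are topologically identical). A set of runs is *diverging* if it
contains at least two distinct topologies; pairs of distinct topologies
whose log-likelihood gap is below `1e-3` log units are treated as not
significantly different, larger gaps are marked as requiring an external
AU test — the test itself is statistical software outside this package.

## Synthetic inputs

All test inputs are generated, none stored. One RNG is fixed package-wide
(Mersenne-Twister, inversion normals, rejection sampling) and recorded in
every metadata sidecar. The value regimes emulate, at desk scale, the data
conditions that matter for rounding-order sensitivity:

* `uniform01` — benign positive values. A practical observation worth
  recording: R's `runif` values carry 32 significant bits, so sums of up to
  ~1e5 of them are *exact* in double arithmetic — every summation order
  agrees bitwise, and the cross-algorithm agreement difference on this
  regime is exactly 0 (comfortably within the 1e-6 bound the acceptance
  script checks).
* `mixed_magnitude` — signs random, magnitudes spanning ±12 decades;
  absorption of small addends makes the result order-sensitive.
* `cancellation` — pairs `(x + δ, -x)` with `δ ~ U(0, 1e-8)`, permuted: the
  exact sum is the tiny perturbation total, so relative rounding error is
  enormous and order sensitivity maximal. This regime provides the pinned
  non-reproducibility witness (n = 1000, seed 1: four distinct bit patterns
  of the per-PE baseline across p ∈ {1, 2, 4, 8}).

The alignment generator draws a random topology (`ape::rtree`), branch
lengths from an exponential with mean 0.1 substitutions/site, and evolves
iid sites under JC69 from stationary root states. What it deliberately does
*not* emulate: rate heterogeneity, indel processes, selection, alignment
error. Passing tests therefore show correctness of the order-decoupling
machinery on model-conform data, not robustness of likelihood inference on
real alignments.

## Problem sizes and test scale

The property suite runs 210 seeded inputs (3 regimes × sizes
n ∈ {1, 2, 17, 1000, 10000} × 14 seeds) against the full configuration grid
p ∈ {1, 2, 3, 4, 7, 8, 16}, degree ∈ {2, 4}, schemes
{contiguous, round_robin, random}; the cross-algorithm agreement check uses
n = 100 000; the likelihood demonstration uses ten fixtures of 4–16 taxa
and 100–2000 sites. Schedules are value-independent, so each configuration
is compiled once and reused across inputs of the same size.

## Known limitations

* The engine simulates message passing in one process; a real
  message-passing backend would be an adapter realizing the same schedule
  contract, and wall-clock behaviour (overlap of communication with
  computation is visible in the schedule structure) is not measured here.
* `int-add` operates on doubles and is exact only below 2^53.
* Reproducibility is guaranteed across PE counts and distributions for a
  fixed binary; it does not, by itself, span different floating-point
  hardware semantics (e.g. extended-precision or FMA-contracted builds).
* The likelihood demonstrator omits per-site rescaling and is not intended
  for trees beyond the tested sizes.
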