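---
title: "Testing connectedness and quantifying indirectness of evidence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing connectedness and quantifying indirectness of evidence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmaconnect)
```

## The problem

Network meta-analysis synthesizes evidence on many treatments from a set of
randomized trials, but an estimate comparing two treatments is only
meaningful if a chain of trials links them. For complex evidence bases —
many outcomes, time points and subgroup analyses, each with its own
network — eyeballing a network plot is slow and error-prone, and comparing
treatments across disconnected components produces numerically unstable,
scientifically invalid results. This package automates two questions:

1. **Connectedness** — which treatment pairs can be compared at all,
   directly or indirectly?
2. **Indirectness** — how many trial-to-trial steps does each comparison
   rely on? Each extra step stacks further homogeneity assumptions about
   trial designs and populations, so a distance of 7 deserves much more
   skepticism than a head-to-head trial at distance 1.

## The matrix method

Let the network have $n$ treatments. The *adjacency matrix* $A$ is the
$n \times n$ symmetric 0/1 matrix with $a_{ij} = 1$ exactly when treatments
$i$ and $j$ were compared in at least one trial, with a zero diagonal. A
trial with $k$ arms contributes a complete subgraph — all $k(k-1)/2$
pairs — and repeated comparisons of the same pair still yield a single 1.

Everything else is matrix algebra on $A$:

* $A^k$ counts **$k$-step walks**: entry $(i, j)$ is the number of chains
  of $k$ comparisons leading from $i$ to $j$ (walks may revisit
  treatments).
* $C_l = \sum_{k=1}^{l} A^k$ counts walks of length $l$ *or less*.
* The indicator operator $I(\cdot)$ maps nonzero entries to 1. Since no
  shortest path needs more than $n - 1$ steps, $I(C_{n-1})$ — the
  **indirect connection matrix** — has a 1 exactly where two treatments are
  connected by *some* walk: it is the transitive closure of the adjacency
  relation. The network is connected iff all its off-diagonal entries
  are 1.
* The **distance matrix** follows from the incremental identity
  $$D = A + \sum_{i=2}^{n-1} i \left( I(C_i) - I(C_{i-1}) \right):$$
  a pair first reachable at walk length $i$ has shortest-path distance
  $i$. For $n = 2$ the sum is empty and $D = A$.

When the network is disconnected, a permutation of rows and columns
collects $I(C_{n-1})$ and $D$ into block-diagonal form, one block per
connected component — the number of blocks is the number of components and
every off-block cell is an impossible comparison.

```{r example}
net <- example_network("figure2")   # 8 treatments, 6 pairwise trials
walk_counts(adjacency_matrix(net), 2)["2", "2"]  # three 2-walks loop at 2
distance_matrix(adjacency_matrix(net))
connectivity_summary(example_network("network3"))
```

## Numerical choices

**Boolean recurrence instead of literal power sums.** Entries of $A^k$ grow
exponentially (a dense 23-treatment network exceeds $10^{15}$ within a
couple of dozen powers), so the reachability path — `indirect_connection()`
and `distance_matrix()` — never forms the power sum. It iterates the
boolean recurrence $R_1 = I(A)$, $R_i = I(R_{i-1} + R_{i-1}A)$, which
equals $I(C_i)$ but stays in 0/1 arithmetic, and stops at the first $i$
with $R_i = R_{i-1}$: all later increments of the distance formula are
zero, so the result is identical and sparse networks finish in a handful of
multiplications. The test suite verifies the two routes agree on hundreds
of random graphs.

**Exact walk counts at any size.** `walk_counts()` and
`cumulative_walks()` are kept for walk-level inspection and must be exact
integers. They run in double precision while a conservative bound
($n \cdot \max(A^k) < 2^{53}$) guarantees exactness, then switch to a
small built-in base-$10^6$ limb big-integer multiply, returning decimal
strings once values no longer fit a double. No silent overflow or rounding
is possible on either path.

**Diagonal conventions.** The indirect connection matrix carries ones on
its diagonal for every treatment, including isolated ones (a treatment is
trivially "connected to itself" even with no trials); the literal
$I(C_{n-1})$ would give an isolated vertex a zero there, so the diagonal is
forced after the recurrence. Conversely, the distance formula above would
place a 2 on the diagonal of every non-isolated vertex (the loop walk
$i \to j \to i$ appears in $I(C_2)$), while a distance matrix must have
zero self-distance; the implementation therefore applies the formula
off-diagonal and fixes the diagonal at zero. Related: cumulative
reachability $I(C_l)$ stabilizes for $l \ge n-1$ *off* the diagonal;
diagonal entries only fill from $l = 2$, which matters for $n = 2$ and is
why the stabilization tests compare off-diagonal verdicts.

**Unconnected pairs.** Published distance tables leave unconnected cells
blank and define them as zero, which conflates "self" with "no possible
comparison". The zero coding is the default so published matrices
reproduce bit-exactly; `distance_matrix(..., unconnected = "missing")`
returns `NA` instead, and the writer can render unconnected cells as `0`,
blank, or `Inf`.

**Component ordering.** Components are ordered by the smallest original
vertex index they contain, and labels inside a component keep their
original relative order. This makes block-collected output deterministic
and matches the header ordering of the published block-diagonal tables
(`1 3 6 7 | 2 4 5` for the 7-treatment example).

**Labels.** Treatment codes are strings, never numbers: `"01"` and `"1"`
are different treatments, and numeric coercion would silently reorder
matrices. Vertex order is first-appearance order unless an explicit
`labels` vector is given; all orderings represent the same network.

**Degenerate inputs.** An empty network is vacuously connected (with a
warning); a single treatment is connected; a single-arm study contributes
a vertex but no edges; self-comparisons are rejected as errors.

## Input formats

Three dialects cover how trial structure is typically stored: a long
arm-level table (`study`, `treatment`; one row per arm), the wide
one-row-per-study treatment matrix used in technical support documents for
evidence synthesis (columns `t1...tK`, missing markers `NA`, empty or `.`
— the exact column naming varies between sources, so any `t<number>`
column is accepted), and a plain edge list (`t_from`, `t_to`). All three
produce identical networks for the same evidence; readers collapse
duplicates with a warning and refuse self-comparisons. Only treatment
structure is read — outcome data never matters for connectivity.

## The random-network generator

`random_network()` exists to make structural claims testable: it plants an
exact component structure by laying down a uniform random spanning tree
(random Prüfer sequence) inside each component and adding each remaining
within-component pair independently with probability `edge_density`.
Because no between-component edge is ever added and each tree is connected
by construction, the realized component count always equals the requested
one — which is precisely what the recovery tests assert.

What it emulates is the *graph structure* of evidence networks, not their
clinical texture: real networks have hub treatments (placebo, standard of
care), degree distributions far from a uniform tree's, and multi-arm
trials that create correlated cliques. Passing tests therefore demonstrate
the graph algorithms are correct on arbitrary structures, not that any
clinical conclusion transfers.

## Problem sizes and determinism

The package's own test suite reproduces every published example matrix
cell-for-cell (8, 7, 23 and 25 treatments) and checks oracle equivalence —
breadth-first-search distances, union-find components, exhaustive walk
enumeration — on a few hundred seeded random graphs of up to 12 vertices,
sizes at which exhaustive oracles are still trivially fast and every
density from empty to complete gets covered. All randomness flows through
explicit seeds; the command-line tool is fully deterministic, writing
byte-identical output on repeated runs.

## Limitations

The package stops where estimation begins: it performs no effect-size
synthesis, no inconsistency or node-splitting assessment, and no weighting
of comparisons by precision or risk of bias. Distance counts steps, not
evidence strength — a distance-2 comparison through one enormous trial may
be far more trustworthy than a distance-1 comparison from a tiny one, and
with loops in the network the distance is only approximately the number of
assumption-stacking steps. It also draws no network plots; its output is
matrices, summaries and exit codes.
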