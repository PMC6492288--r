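# nmaconnect

Connectedness testing and indirectness quantification for network
meta-analysis evidence networks.

Network meta-analysis compares many treatments through a network of
randomized trials, but only treatments joined by a chain of trials can be
compared at all — and for complex evidence bases (many outcomes, time
points, subgroups, each with its own network) it is genuinely hard to see
whether a network is connected. Comparing across disconnected components
yields invalid, numerically unstable estimates. `nmaconnect` automates the
check with elementary matrix graph theory, and quantifies *how indirect*
each feasible comparison is, since every extra step in a chain of trials
stacks further homogeneity assumptions.

## The method

For `n` treatments, the **adjacency matrix** `A` is the symmetric 0/1
matrix with `a_ij = 1` when treatments i and j have been compared in at
least one trial (multi-arm trials contribute all their pairs; the diagonal
is zero). Then:

- `A^k` counts the k-step walks between each pair of treatments;
- `C_l = A + A² + … + A^l` counts walks of length ≤ l;
- the **indirect connection matrix** `I(C_{n-1})` (the indicator `I(·)`
  maps nonzero entries to 1) has a 1 exactly where two treatments are
  connected by some walk — the network is connected iff all off-diagonal
  entries are 1;
- the **distance matrix** `D = A + Σ_{i=2..n-1} i·(I(C_i) − I(C_{i-1}))`
  holds shortest-path lengths: the number of trial comparisons the most
  direct chain of evidence needs.

Internally the closure and distances are computed with an equivalent
boolean recurrence (`R_1 = I(A)`, `R_i = I(R_{i-1} + R_{i-1}A)`) that
stays in 0/1 arithmetic and stops at its fixed point, so nothing can
overflow and sparse networks finish early; explicit walk counts switch to
built-in big-integer arithmetic when they outgrow double precision.
Disconnected networks are collected into block-diagonal form, one block
per connected component.

## Worked example

Six pairwise trials on eight treatments, as an edge list:

```r
library(nmaconnect)
writeLines(c("t_from,t_to", "1,2", "2,3", "2,5", "4,5", "6,7", "7,8"),
           "trials.csv")
net <- read_edge_list("trials.csv")   # or read_long_arm_table / read_dsu_wide
connectivity_summary(net)
```

```
8 treatments, 6 direct comparisons, 2 connected components
Network is DISCONNECTED
  component 1: 1, 2, 3, 5, 4
  component 2: 6, 7, 8
Maximum finite distance: 3 (1-4, 3-4)
```

Treatments 1–5 can be compared with each other, but never with 6, 7 or 8:
any meta-analysis must treat the two components separately. Within the
first component the farthest comparison (1 vs 4) needs a three-step chain
of trials, so it leans on assumptions of homogeneity across three trial
populations. The matrices themselves:

```r
distance_matrix(adjacency_matrix(net))
```

```
  1 2 3 5 4 6 7 8
1 0 1 2 2 3 0 0 0
2 1 0 1 1 2 0 0 0
3 2 1 0 2 3 0 0 0
5 2 1 2 0 1 0 0 0
4 3 2 3 1 0 0 0 0
6 0 0 0 0 0 0 1 2
7 0 0 0 0 0 1 0 1
8 0 0 0 0 0 2 1 0
```

A 1 marks a direct (head-to-head) comparison; larger entries mark
increasingly indirect ones; 0 off the diagonal means no comparison is
possible (`unconnected = "missing"` returns `NA` instead). Larger
demonstration networks with 7, 23 and 25 treatments are built in — e.g.
`connectivity_summary(example_network("network3"))` — and
`random_network()` generates seeded networks with a planted component
structure.

## Command line

A thin wrapper exposes the same checks to shell pipelines:

```sh
Rscript inst/cli/nma-connect.R check trials.csv            # exit 0/2/1
Rscript inst/cli/nma-connect.R distance trials.csv --blocked \
    --unconnected blank --out D.csv
Rscript inst/cli/nma-connect.R components trials.csv
```

Exit status 0 means connected, 2 disconnected (a machine-checkable
warning; `--strict` turns it into a failure), 1 an input error. Reports go
to stdout, log messages to stderr, matrices to `--out` or stdout.

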