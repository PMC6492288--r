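test_that("indicator maps nonzero to one and rejects negatives", {
  z <- matrix(0, 3, 3)
  expect_equal(indicator(z), z)
  m <- matrix(c(0, 4020, 2, 0), 2, 2)
  expect_equal(unname(indicator(m)), matrix(c(0, 1, 1, 0), 2, 2))
  expect_error(indicator(matrix(-1, 1, 1)), class = "nmaconnect_domain_error")
})

test_that("boolean-recurrence reachability equals the power-sum route", {
  set.seed(202)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    A <- rand_adjacency(n, stats::runif(1, 0, 1))
    via_powers <- indicator(cumulative_walks(A, n - 1))
    diag(via_powers) <- 1
    expect_equal(indirect_connection(A), via_powers)
  }
})

test_that("indirect connection handles cliques and isolated vertices", {
  K4 <- adjacency_matrix(network_from_studies(
    list(list(study_id = "s", arms = c("a", "b", "c", "d")))))
  expect_equal(unname(indirect_connection(K4)), matrix(1, 4, 4))
  iso <- evidence_network(rbind(c("A", "B")), labels = c("A", "B", "C"))
  R <- indirect_connection(adjacency_matrix(iso))
  expect_equal(diag(R), c(A = 1, B = 1, C = 1))  # ones even when isolated
  expect_equal(unname(R["C", c("A", "B")]), c(0, 0))
})

test_that("cumulative reachability stabilizes at walk length n-1", {
  # off-diagonal verdicts: no pair becomes reachable after n-1 steps (the
  # diagonal is excluded because loop walks only exist from length 2)
  set.seed(303)
  for (rep in 1:12) {
    n <- sample(2:8, 1)
    A <- rand_adjacency(n, stats::runif(1))
    ref <- indicator(cumulative_walks(A, max(n - 1, 1)))
    diag(ref) <- 1
    for (l in (n - 1):(n + 2)) {
      if (l < 1) next
      got <- indicator(cumulative_walks(A, l))
      diag(got) <- 1
      expect_equal(got, ref)
    }
  }
})

test_that("connectedness verdicts match the component count", {
  expect_true(is_connected(adjacency_matrix(
    evidence_network(labels = "only"))))
  expect_warning(v <- is_connected(adjacency_matrix(evidence_network())),
                 "vacuously")
  expect_true(v)
  expect_false(is_connected(example_network("figure2")))
  tri <- network_from_studies(list(list(study_id = "s", arms = c("a", "b", "c"))))
  expect_true(is_connected(tri))
})

test_that("components are ordered by smallest original index", {
  none <- evidence_network(labels = c("x", "y", "z"))
  p <- connected_components(adjacency_matrix(none))
  expect_identical(p$groups, list("x", "y", "z"))
  p2 <- connected_components(example_network("figure2"))
  expect_identical(p2$groups, list(as.character(1:5), as.character(6:8)))
  expect_identical(p2$permutation, 1:8)
})

test_that("components agree with a union-find oracle on random graphs", {
  set.seed(404)
  for (rep in 1:20) {
    n <- sample(1:12, 1)
    A <- rand_adjacency(n, stats::runif(1, 0, 0.5))
    expect_identical(connected_components(A)$groups, uf_components(A))
  }
})

test_that("distances match breadth-first search on random graphs", {
  set.seed(505)
  for (rep in 1:25) {
    n <- sample(1:12, 1)
    A <- rand_adjacency(n, stats::runif(1))
    expect_equal(distance_matrix(A), bfs_distances(A))
    Dm <- distance_matrix(A, unconnected = "missing")
    expect_equal(Dm, bfs_distances(A, unconnected = NA_real_))
  }
})

test_that("distance matrix satisfies its structural invariants", {
  set.seed(606)
  for (rep in 1:10) {
    n <- sample(2:12, 1)
    A <- rand_adjacency(n, stats::runif(1, 0.1, 0.9))
    D <- distance_matrix(A)
    expect_equal(D, t(D))
    expect_equal(diag(D), setNames(rep(0, n), rownames(A)))
    expect_true(all(D <= n - 1))
    expect_equal(unname(D == 1), unname(A == 1))  # d = 1 iff direct edge
    # triangle inequality within components
    R <- indirect_connection(A)
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      if (R[i, j] == 1 && R[j, k] == 1 && i != j && j != k && i != k) {
        expect_lte(D[i, k], D[i, j] + D[j, k])
      }
    }
  }
})

test_that("degenerate distance cases follow the formula", {
  pairD <- distance_matrix(adjacency_matrix(evidence_network(rbind(c("1", "2")))))
  expect_equal(unname(pairD), rbind(c(0, 1), c(1, 0)))
  # n = 2, no edge: the incremental sum is empty so D = A = 0
  two <- adjacency_matrix(evidence_network(labels = c("a", "b")))
  expect_equal(unname(distance_matrix(two)), matrix(0, 2, 2))
  expect_equal(dim(distance_matrix(adjacency_matrix(evidence_network()))),
               c(0L, 0L))
})

test_that("relabelling vertices permutes all derived matrices alike", {
  set.seed(707)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    A <- rand_adjacency(n, stats::runif(1))
    perm <- sample(n)
    Ap <- A[perm, perm]
    expect_equal(indirect_connection(A)[perm, perm], indirect_connection(Ap))
    expect_equal(distance_matrix(A)[perm, perm], distance_matrix(Ap))
  }
})

test_that("block sorting produces clean, idempotent block-diagonal form", {
  net <- example_network("network3")
  A <- adjacency_matrix(net)
  p <- connected_components(A)
  D <- distance_matrix(A)
  sorted <- block_sort(D, p)
  # multiset of entries preserved
  expect_equal(sort(as.vector(sorted$matrix)), sort(as.vector(D)))
  # off-block entries are the unconnected code (zero)
  sizes <- lengths(p$groups)
  stops <- cumsum(sizes)
  starts <- stops - sizes + 1
  for (bi in seq_along(sizes)) for (bj in seq_along(sizes)) {
    cells <- sorted$matrix[starts[bi]:stops[bi], starts[bj]:stops[bj]]
    if (bi != bj) expect_true(all(cells == 0))
  }
  # idempotent: re-sorting the sorted matrix changes nothing
  p2 <- connected_components(A[p$permutation, p$permutation])
  again <- block_sort(sorted$matrix, p2)
  expect_identical(again$matrix, sorted$matrix)
  expect_identical(again$labels, sorted$labels)
})

test_that("block sorting a connected network is the identity", {
  net <- example_network("network2")
  D <- distance_matrix(adjacency_matrix(net))
  p <- connected_components(adjacency_matrix(net))
  expect_identical(p$permutation, 1:23)
  expect_identical(block_sort(D, p)$matrix, D)
})

test_that("block_sort validates its label contract", {
  D <- distance_matrix(adjacency_matrix(example_network("network1")))
  p <- connected_components(example_network("figure2"))
  expect_error(block_sort(D, p), class = "nmaconnect_invalid_input")
})

test_that("adjacency validation catches malformed matrices", {
  expect_error(validate_input <- distance_matrix(matrix(c(0, 1, 0, 0), 2, 2)),
               class = "nmaconnect_invalid_input")  # asymmetric
  expect_error(distance_matrix(matrix(c(1, 1, 1, 1), 2, 2)),
               class = "nmaconnect_invalid_input")  # nonzero diagonal
  expect_error(distance_matrix(matrix(c(0, 2, 2, 0), 2, 2)),
               class = "nmaconnect_invalid_input")  # entries not 0/1
})
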