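#' Adjacency matrix of an evidence network
#'
#' The adjacency matrix A is the n x n symmetric 0/1 matrix with
#' `A[i, j] = 1` exactly when treatments i and j have been compared directly
#' in at least one trial, and a zero diagonal. Every connectivity quantity
#' in this package derives from A: its k-th power counts k-step walks, the
#' indicator of the cumulative power sum is the indirect connection matrix,
#' and the first power at which a pair becomes reachable is its distance.
#'
#' Multiple studies comparing the same pair still yield a single 1: the
#' matrix records whether direct evidence exists, not how much.
#'
#' @param network an [evidence_network()].
#' @return n x n numeric 0/1 matrix with treatment labels as dimnames.
#' @examples
#' adjacency_matrix(example_network("figure2"))
#' @export
adjacency_matrix <- function(network) {
  stopifnot(inherits(network, "evidence_network"))
  n <- length(network$labels)
  A <- matrix(0, n, n, dimnames = list(network$labels, network$labels))
  if (nrow(network$edges)) {
    i <- match(network$edges[, 1L], network$labels)
    j <- match(network$edges[, 2L], network$labels)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

# accept either a network or a bare matrix; always hand back a validated
# numeric adjacency with labels
as_adjacency <- function(x) {
  if (inherits(x, "evidence_network")) {
    return(adjacency_matrix(x))
  }
  validate_adjacency(x)
}

validate_adjacency <- function(A) {
  if (!is.matrix(A) || !is.numeric(A)) {
    stop_invalid_input("adjacency must be a numeric matrix")
  }
  if (nrow(A) != ncol(A)) {
    stop_invalid_input("adjacency must be square")
  }
  if (length(A) && !all(A %in% c(0, 1))) {
    stop_invalid_input("adjacency entries must be 0 or 1")
  }
  if (!isTRUE(all.equal(unname(A), unname(t(A))))) {
    stop_invalid_input("adjacency must be symmetric")
  }
  if (length(A) && any(diag(A) != 0)) {
    stop_invalid_input("adjacency must have a zero diagonal")
  }
  storage.mode(A) <- "double"
  if (is.null(dimnames(A))) {
    lab <- as.character(seq_len(nrow(A)))
    dimnames(A) <- list(lab, lab)
  }
  A
}

#' Walk counts between treatments
#'
#' Raising the adjacency matrix to the power k counts, for each pair of
#' treatments, the number of k-step walks between them (walks may revisit
#' vertices, so the diagonal of A^2 is the vertex degree). Arithmetic is
#' exact for any n and k: powers are computed in double precision while
#' every entry is provably below 2^53 and in big-integer arithmetic beyond,
#' in which case the entries are returned as decimal strings.
#'
#' @param adj adjacency matrix (or an `evidence_network`).
#' @param k walk length, a positive integer.
#' @return n x n matrix of exact walk counts: numeric when all entries fit
#'   in a double, otherwise character decimal strings.
#' @examples
#' A <- adjacency_matrix(example_network("figure2"))
#' walk_counts(A, 2)["2", "2"]  # three 2-walks loop from 2 back to itself
#' @export
walk_counts <- function(adj, k) {
  adj <- as_adjacency(adj)
  check_positive_int(k, "k")
  power_sequence(adj, k, cumulative = FALSE)
}

#' Cumulative walk counts
#'
#' The matrix \eqn{C_l = \sum_{k=1}^{l} A^k} counts, for each pair of
#' treatments, the walks of length l or less between them. Its indicator
#' at l = n-1 is the indirect connection matrix: a pair is connected
#' exactly when some walk of length at most n-1 (the longest possible
#' path) joins it. Arithmetic is exact as in [walk_counts()].
#'
#' @inheritParams walk_counts
#' @param l maximum walk length, a positive integer.
#' @return n x n matrix of exact cumulative walk counts (numeric, or
#'   character decimal strings when entries exceed 2^53).
#' @examples
#' A <- adjacency_matrix(example_network("figure2"))
#' indicator(cumulative_walks(A, 3))
#' @export
cumulative_walks <- function(adj, l) {
  adj <- as_adjacency(adj)
  check_positive_int(l, "l")
  power_sequence(adj, l, cumulative = TRUE)
}

# shared engine: A^k, or sum of A^1..A^k, switching from exact doubles to
# big-integer limbs the step before an entry could reach 2^53
power_sequence <- function(adj, k, cumulative) {
  n <- nrow(adj)
  labels <- rownames(adj)
  if (n == 0L) {
    return(matrix(numeric(), 0L, 0L, dimnames = list(NULL, NULL)))
  }
  P <- adj
  C <- if (cumulative) adj else NULL
  big <- FALSE
  step <- 1L
  while (step < k) {
    if (!big && n * max(P) >= 2^53) {
      P <- bigmat_from_matrix(P)
      if (cumulative) C <- bigmat_from_matrix(C)
      big <- TRUE
    }
    if (big) {
      P <- bigmat_mult_adj(P, adj)
      if (cumulative) C <- bigmat_add(C, P)
    } else {
      P <- P %*% adj
      if (cumulative) C <- C + P
    }
    step <- step + 1L
  }
  out <- if (cumulative) C else P
  if (big) {
    bigmat_to_matrix(out, labels)
  } else {
    dimnames(out) <- list(labels, labels)
    out
  }
}

check_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop_domain(sprintf("`%s` must be a positive integer", name))
  }
}

#' Indicator operator
#'
#' Elementwise map sending nonzero entries to 1 and zeros to 0. Applied to
#' a cumulative walk-count matrix it answers "is there any walk of this
#' length or less?", which is all connectedness needs.
#'
#' @param m numeric matrix with non-negative entries, or a character matrix
#'   of decimal strings as returned by [walk_counts()] for very large
#'   counts.
#' @return 0/1 numeric matrix of the same shape, dimnames preserved.
#' @export
indicator <- function(m) {
  if (is.character(m)) {
    out <- (m != "0") * 1
  } else {
    if (length(m) && any(m < 0)) {
      stop_domain("indicator() expects non-negative entries")
    }
    out <- (m != 0) * 1
  }
  dim(out) <- dim(m)
  dimnames(out) <- dimnames(m)
  out
}

#' Indirect connection matrix
#'
#' The transitive closure of the adjacency relation: entry (i, j) is 1
#' exactly when treatments i and j are joined by some walk, i.e. when they
#' can be compared directly or indirectly. The diagonal is 1 by convention.
#' Only treatment pairs with a 1 here can meaningfully enter the same
#' network meta-analysis.
#'
#' Mathematically this is the indicator of the cumulative walk-count matrix
#' \eqn{C_{n-1}} (no shortest path is longer than n-1 steps). It is
#' computed by the equivalent boolean reachability recurrence
#' \eqn{R_1 = I(A)}, \eqn{R_i = I(R_{i-1} + R_{i-1} A)}, which stays in
#' 0/1 arithmetic at every step (walk counts themselves grow exponentially)
#' and stops early at the first fixed point.
#'
#' @inheritParams walk_counts
#' @return n x n symmetric 0/1 matrix with ones on the diagonal.
#' @examples
#' indirect_connection(example_network("network1"))
#' @export
indirect_connection <- function(adj) {
  adj <- as_adjacency(adj)
  R <- reach_fixed_point(adj)$R
  diag(R) <- 1
  R
}

# iterate the boolean recurrence to its fixed point; also return, for each
# pair, the first step i at which it became reachable (0 = never), which is
# exactly the shortest-path distance
reach_fixed_point <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) {
    return(list(R = adj, first = adj))
  }
  R <- indicator(adj)
  first <- R  # step 1: direct comparisons
  i <- 1L
  while (i < n - 1L) {
    R_next <- indicator(R + R %*% adj)
    new_pairs <- R_next - R
    if (!any(new_pairs > 0)) break
    i <- i + 1L
    first <- first + i * new_pairs
    R <- R_next
  }
  list(R = R, first = first)
}

#' Test whether an evidence network is connected
#'
#' A network is connected when every off-diagonal entry of the indirect
#' connection matrix is 1, i.e. every pair of treatments can be compared
#' through some chain of trials. Single-vertex networks are connected; the
#' empty network is vacuously connected, with a warning.
#'
#' @inheritParams walk_counts
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_connected(example_network("network2"))  # TRUE
#' is_connected(example_network("network3"))  # FALSE, four components
#' @export
is_connected <- function(adj) {
  adj <- as_adjacency(adj)
  n <- nrow(adj)
  if (n == 0L) {
    warning("empty network: connectedness is vacuously TRUE")
    return(TRUE)
  }
  if (n == 1L) return(TRUE)
  R <- indirect_connection(adj)
  all(R[upper.tri(R)] == 1)
}

#' Connected components of an evidence network
#'
#' Partitions the treatments into maximal groups of mutually reachable
#' vertices, together with the row/column permutation that collects the
#' indirect connection or distance matrix into block-diagonal form (one
#' block per component). Components are ordered by the smallest original
#' vertex index they contain, and labels within a component keep their
#' original relative order, so reordered matrix headers are stable.
#'
#' @inheritParams walk_counts
#' @return An object of class `component_partition`: a list with `groups`
#'   (list of character label vectors), `permutation` (integer vector: the
#'   block order of the original indices) and `labels` (original order).
#' @examples
#' connected_components(example_network("network1"))
#' @export
connected_components <- function(adj) {
  adj <- as_adjacency(adj)
  n <- nrow(adj)
  labels <- rownames(adj)
  if (n == 0L) {
    return(new_partition(list(), integer(), character()))
  }
  R <- indirect_connection(adj)
  comp_first <- apply(R == 1, 1L, which.max)  # smallest index reachable
  perm <- order(comp_first, seq_len(n))
  groups <- lapply(unique(comp_first[perm]),
                   function(f) labels[comp_first == f])
  new_partition(groups, perm, labels)
}

new_partition <- function(groups, perm, labels) {
  structure(list(groups = groups, permutation = perm, labels = labels),
            class = "component_partition")
}

#' @export
print.component_partition <- function(x, ...) {
  k <- length(x$groups)
  cat(sprintf("Component partition: %d component%s\n", k,
              if (k == 1L) "" else "s"))
  for (i in seq_len(k)) {
    cat(sprintf("  [%d] %s\n", i, paste(x$groups[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Distance matrix of an evidence network
#'
#' Entry (i, j) is the length of the shortest path between treatments i
#' and j: the minimum number of trial comparisons a chain of evidence must
#' traverse. A 1 is a direct comparison; larger values flag increasingly
#' indirect comparisons, each extra step stacking further homogeneity
#' assumptions across trial designs and populations. The diagonal is zero.
#'
#' The matrix is evaluated through the incremental identity
#' \eqn{D = A + \sum_{i=2}^{n-1} i\,(I(C_i) - I(C_{i-1}))}: a pair first
#' reachable at step i has distance i. The increments are computed with the
#' boolean reachability recurrence (see [indirect_connection()]) and the
#' iteration stops as soon as reachability stabilizes. The diagonal is held
#' at zero throughout.
#'
#' @inheritParams walk_counts
#' @param unconnected how to encode pairs in different components:
#'   `"zero"` (default; mirrors published presentation but conflates
#'   "self" with "unreachable") or `"missing"` for `NA`.
#' @return n x n symmetric matrix of integer distances; entries are at
#'   most n-1.
#' @examples
#' distance_matrix(example_network("figure2"))
#' @export
distance_matrix <- function(adj, unconnected = c("zero", "missing")) {
  adj <- as_adjacency(adj)
  unconnected <- match.arg(unconnected)
  res <- reach_fixed_point(adj)
  D <- res$first
  if (nrow(D)) diag(D) <- 0
  if (unconnected == "missing" && nrow(D)) {
    off <- res$R == 0
    diag(off) <- FALSE
    D[off] <- NA_real_
  }
  D
}

#' Collect a matrix into block-diagonal component order
#'
#' Permutes the rows and columns of an indirect connection or distance
#' matrix so that each connected component occupies one diagonal block.
#' Off-block entries are the unconnected code (0, or `NA` for a distance
#' matrix built with `unconnected = "missing"`), so component structure is
#' visible at a glance; the permuted label order is returned alongside,
#' since row/column names are essential once the original order is lost.
#'
#' @param m square labelled matrix (indirect connection or distance) whose
#'   dimnames match `partition$labels`.
#' @param partition a [connected_components()] partition for the same
#'   network.
#' @return list with `matrix` (the permuted matrix), `labels` (permuted
#'   label order) and `partition`.
#' @examples
#' net <- example_network("network1")
#' block_sort(distance_matrix(net), connected_components(net))
#' @export
block_sort <- function(m, partition) {
  stopifnot(inherits(partition, "component_partition"))
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_invalid_input("`m` must be a square matrix")
  }
  labs <- rownames(m)
  if (is.null(labs) || !identical(labs, partition$labels)) {
    stop_invalid_input("matrix labels do not match the partition's labels")
  }
  perm <- partition$permutation
  out <- m[perm, perm, drop = FALSE]
  list(matrix = out, labels = labs[perm], partition = partition)
}

#' Connectivity summary of an evidence network
#'
#' One-stop report: treatment and direct-comparison counts, the connected
#' components, and how indirect the farthest comparisons are.
#'
#' @param network an [evidence_network()].
#' @return An object of class `connectivity_summary`: a list with
#'   `n_treatments`, `n_edges`, `n_components`, `components` (list of label
#'   groups), `connected`, `max_finite_distance` (largest distance between
#'   connected pairs; `NA` when no pair is connected), `pairs_at_max`
#'   (two-column character matrix of the pairs attaining it) and
#'   `distances` (the full distance matrix, zero-coded).
#' @examples
#' connectivity_summary(example_network("network3"))
#' @export
connectivity_summary <- function(network) {
  stopifnot(inherits(network, "evidence_network"))
  A <- adjacency_matrix(network)
  n <- nrow(A)
  parts <- connected_components(A)
  D <- distance_matrix(A)
  if (n > 1L) {
    up <- upper.tri(D)
    finite <- D[up][D[up] > 0]
    maxd <- if (length(finite)) max(finite) else NA_real_
  } else {
    maxd <- NA_real_
  }
  if (!is.na(maxd)) {
    at <- which(D == maxd & upper.tri(D), arr.ind = TRUE)
    pairs <- cbind(rownames(D)[at[, 1L]], colnames(D)[at[, 2L]])
  } else {
    pairs <- matrix(character(), 0L, 2L)
  }
  dimnames(pairs) <- list(NULL, c("from", "to"))
  structure(
    list(n_treatments = n,
         n_edges = nrow(network$edges),
         n_components = length(parts$groups),
         components = parts$groups,
         connected = length(parts$groups) <= 1L,
         max_finite_distance = maxd,
         pairs_at_max = pairs,
         distances = D),
    class = "connectivity_summary")
}

#' @export
print.connectivity_summary <- function(x, ...) {
  cat(sprintf("%d treatments, %d direct comparisons, %d connected component%s\n",
              x$n_treatments, x$n_edges, x$n_components,
              if (x$n_components == 1L) "" else "s"))
  cat(if (x$connected) "Network is CONNECTED\n" else "Network is DISCONNECTED\n")
  for (i in seq_along(x$components)) {
    cat(sprintf("  component %d: %s\n", i,
                paste(x$components[[i]], collapse = ", ")))
  }
  if (!is.na(x$max_finite_distance)) {
    cat(sprintf("Maximum finite distance: %d (%s)\n",
                as.integer(x$max_finite_distance),
                paste(x$pairs_at_max[, 1L], x$pairs_at_max[, 2L],
                      sep = "-", collapse = ", ")))
  }
  invisible(x)
}
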