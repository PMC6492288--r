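# Worked-example networks and their published matrices, built in code so
# every test and demonstration runs without external data, plus a seeded
# random-network generator with planted components.

# 8-treatment illustration: six pairwise trials
FIG2_EDGES <- rbind(
  c("1", "2"), c("2", "3"), c("2", "5"),
  c("4", "5"), c("6", "7"), c("7", "8"))

# 7-treatment disconnected example (components {1,3,6,7} and {2,4,5});
# edges are the 1-entries of its published adjacency matrix
NET1_EDGES <- rbind(
  c("1", "3"), c("1", "6"), c("1", "7"),
  c("2", "4"), c("4", "5"), c("6", "7"))

# 23-treatment connected example. The publication prints only the distance
# matrix; since d_ij = 1 exactly when i and j are directly compared, the
# edge set is its distance-1 cells, listed here row by row of the upper
# triangle. (Its accompanying text says 25 direct comparisons, but the
# printed matrix contains 24 distance-1 pairs and is internally consistent
# with exactly these 24 edges.)
NET2_EDGES <- rbind(
  c("1", "9"), c("1", "15"), c("1", "17"), c("1", "22"),
  c("2", "7"), c("2", "18"),
  c("3", "14"), c("3", "21"),
  c("4", "21"),
  c("5", "15"),
  c("6", "8"), c("6", "10"), c("6", "11"),
  c("7", "13"),
  c("8", "12"), c("8", "20"),
  c("10", "14"), c("10", "23"),
  c("12", "21"),
  c("13", "16"), c("13", "23"),
  c("15", "18"),
  c("17", "23"),
  c("19", "22"))

# 25-treatment example with four components; edges are the distance-1
# cells of its published block-collected distance matrix, block by block
NET3_EDGES <- rbind(
  c("1", "4"), c("2", "8"), c("4", "8"),                    # block {1,2,4,8}
  c("3", "19"), c("5", "14"), c("5", "17"), c("5", "24"),   # 17-treatment block
  c("5", "25"), c("6", "12"), c("6", "25"), c("10", "22"),
  c("11", "23"), c("13", "24"), c("14", "19"), c("14", "25"),
  c("15", "25"), c("16", "25"), c("21", "22"), c("22", "23"),
  c("23", "24"),
  c("7", "20"),                                             # block {7,20}
  c("9", "18"))                                             # block {9,18}

#' Worked-example evidence networks
#'
#' Programmatic versions of four published demonstration networks:
#'
#' * `"figure2"` — 8 treatments, 6 pairwise trials, two components
#'   (\{1..5\} and \{6,7,8\}); the network used to illustrate walk counts.
#' * `"network1"` — 7 treatments, 6 comparisons, components \{1,3,6,7\}
#'   and \{2,4,5\}.
#' * `"network2"` — 23 treatments, 24 comparisons, connected but sparse
#'   (some comparisons are nine steps apart).
#' * `"network3"` — 25 treatments, 22 comparisons, four components.
#'
#' The edge sets of networks 2 and 3 are recovered from the distance-1
#' cells of their published distance matrices (a pair is at distance 1
#' exactly when directly compared); see [reference_matrix()] for the printed
#' matrices themselves.
#'
#' @param name one of `"figure2"`, `"network1"`, `"network2"`,
#'   `"network3"`.
#' @return An [evidence_network()].
#' @examples
#' connectivity_summary(example_network("network1"))
#' @export
example_network <- function(name = c("figure2", "network1", "network2",
                                   "network3")) {
  name <- match.arg(name)
  switch(name,
    figure2  = evidence_network(FIG2_EDGES, labels = as.character(1:8)),
    network1 = evidence_network(NET1_EDGES, labels = as.character(1:7)),
    network2 = evidence_network(NET2_EDGES, labels = as.character(1:23)),
    network3 = evidence_network(NET3_EDGES, labels = as.character(1:25)))
}

# published matrices, stored as compact digit strings / row text ----------

FIG2_A2 <- "1010100003010000101010000101000010102000000001010000002000000101"
FIG2_A3 <- "0301000030304000030100001010200004020000000000200000020200000020"
FIG2_IC <- "1111100011111000111110001111100011111000000001110000011100000111"
FIG2_D  <- "0123200010121000210320003230100021210000000000120000010100000210"

NET1_A_ROWS <- c(
  "0 0 1 0 0 1 1",
  "0 0 0 1 0 0 0",
  "1 0 0 0 0 0 0",
  "0 1 0 0 1 0 0",
  "0 0 0 1 0 0 0",
  "1 0 0 0 0 0 1",
  "1 0 0 0 0 1 0")
NET1_IC_ROWS <- c(
  "1 0 1 0 0 1 1",
  "0 1 0 1 1 0 0",
  "1 0 1 0 0 1 1",
  "0 1 0 1 1 0 0",
  "0 1 0 1 1 0 0",
  "1 0 1 0 0 1 1",
  "1 0 1 0 0 1 1")

# block-collected 7x7 distance matrix, labels 1,3,6,7 then 2,4,5
NET1_D_BLOCK_LABELS <- c("1", "3", "6", "7", "2", "4", "5")
NET1_D_BLOCK1 <- c(0, 1, 1, 1,
                   1, 0, 2, 2,
                   1, 2, 0, 1,
                   1, 2, 1, 0)
NET1_D_BLOCK2 <- c(0, 1, 2,
                   1, 0, 1,
                   2, 1, 0)

NET2_D_ROWS <- c(
  "0 3 5 7 2 4 4 5 1 3 5 6 3 4 1 4 1 2 2 6 6 1 2",
  "3 0 6 8 3 5 1 6 4 4 6 7 2 5 2 3 4 1 5 7 7 4 3",
  "5 6 0 2 7 3 5 3 6 2 4 2 4 1 6 5 4 7 7 4 1 6 3",
  "7 8 2 0 9 4 7 3 8 4 5 2 6 3 8 7 6 9 9 4 1 8 5",
  "2 3 7 9 0 6 4 7 3 5 7 8 5 6 1 6 3 2 4 8 8 3 4",
  "4 5 3 4 6 0 4 1 5 1 1 2 3 2 5 4 3 6 6 2 3 5 2",
  "4 1 5 7 4 4 0 5 5 3 5 6 1 4 3 2 3 2 6 6 6 5 2",
  "5 6 3 3 7 1 5 0 6 2 2 1 4 3 6 5 4 7 7 1 2 6 3",
  "1 4 6 8 3 5 5 6 0 4 6 7 4 5 2 5 2 3 3 7 7 2 3",
  "3 4 2 4 5 1 3 2 4 0 2 3 2 1 4 3 2 5 5 3 3 4 1",
  "5 6 4 5 7 1 5 2 6 2 0 3 4 3 6 5 4 7 7 3 4 6 3",
  "6 7 2 2 8 2 6 1 7 3 3 0 5 3 7 6 5 8 8 2 1 7 4",
  "3 2 4 6 5 3 1 4 4 2 4 5 0 3 4 1 2 3 5 5 5 4 1",
  "4 5 1 3 6 2 4 3 5 1 3 3 3 0 5 4 3 6 6 4 2 5 2",
  "1 2 6 8 1 5 3 6 2 4 6 7 4 5 0 5 2 1 3 7 7 2 3",
  "4 3 5 7 6 4 2 5 5 3 5 6 1 4 5 0 3 4 6 6 6 5 2",
  "1 4 4 6 3 3 3 4 2 2 4 5 2 3 2 3 0 3 3 5 5 2 1",
  "2 1 7 9 2 6 2 7 3 5 7 8 3 6 1 4 3 0 4 8 8 3 4",
  "2 5 7 9 4 6 6 7 3 5 7 8 5 6 3 6 3 4 0 8 8 1 4",
  "6 7 4 4 8 2 6 1 7 3 3 2 5 4 7 6 5 8 8 0 3 7 4",
  "6 7 1 1 8 3 6 2 7 3 4 1 5 2 7 6 5 8 8 3 0 7 4",
  "1 4 6 8 3 5 5 6 2 4 6 7 4 5 2 5 2 3 1 7 7 0 3",
  "2 3 3 5 4 2 2 3 3 1 3 4 1 2 3 2 1 4 4 4 4 3 0")

# 25-treatment blocked distance matrix: label order and the four diagonal
# blocks, row by row
NET3_D_BLOCK_LABELS <- c("1", "2", "4", "8",
                         "3", "5", "6", "10", "11", "12", "13", "14", "15",
                         "16", "17", "19", "21", "22", "23", "24", "25",
                         "7", "20", "9", "18")
NET3_D_B1_ROWS <- c("0 3 1 2", "3 0 2 1", "1 2 0 1", "2 1 1 0")
NET3_D_B2_ROWS <- c(
  "0 3 4 7 6 5 5 2 4 4 4 1 7 6 5 4 3",
  "3 0 2 4 3 3 2 1 2 2 1 2 4 3 2 1 1",
  "4 2 0 6 5 1 4 2 2 2 3 3 6 5 4 3 1",
  "7 4 6 0 3 7 4 5 6 6 5 6 2 1 2 3 5",
  "6 3 5 3 0 6 3 4 5 5 4 5 3 2 1 2 4",
  "5 3 1 7 6 0 5 3 3 3 4 4 7 6 5 4 2",
  "5 2 4 4 3 5 0 3 4 4 3 4 4 3 2 1 3",
  "2 1 2 5 4 3 3 0 2 2 2 1 5 4 3 2 1",
  "4 2 2 6 5 3 4 2 0 2 3 3 6 5 4 3 1",
  "4 2 2 6 5 3 4 2 2 0 3 3 6 5 4 3 1",
  "4 1 3 5 4 4 3 2 3 3 0 3 5 4 3 2 2",
  "1 2 3 6 5 4 4 1 3 3 3 0 6 5 4 3 2",
  "7 4 6 2 3 7 4 5 6 6 5 6 0 1 2 3 5",
  "6 3 5 1 2 6 3 4 5 5 4 5 1 0 1 2 4",
  "5 2 4 2 1 5 2 3 4 4 3 4 2 1 0 1 3",
  "4 1 3 3 2 4 1 2 3 3 2 3 3 2 1 0 2",
  "3 1 1 5 4 2 3 1 1 1 2 2 5 4 3 2 0")
NET3_D_B3_ROWS <- c("0 1", "1 0")
NET3_D_B4_ROWS <- c("0 1", "1 0")

digits_to_matrix <- function(s, n, labels) {
  vals <- as.numeric(strsplit(s, "")[[1L]])
  matrix(vals, n, n, byrow = TRUE, dimnames = list(labels, labels))
}

rows_to_matrix <- function(rows, labels) {
  vals <- lapply(strsplit(rows, " +"), as.numeric)
  m <- do.call(rbind, vals)
  dimnames(m) <- list(labels, labels)
  m
}

# assemble a block-diagonal matrix with NA off-block (published tables
# leave those cells blank)
blocks_to_matrix <- function(blocks, labels) {
  n <- length(labels)
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  at <- 0L
  for (b in blocks) {
    k <- nrow(b)
    idx <- at + seq_len(k)
    m[idx, idx] <- b
    at <- at + k
  }
  m
}

#' Published matrices of the worked-example networks
#'
#' The matrices printed for the example networks, for cell-for-cell
#' comparison against recomputed results:
#'
#' * `"figure2_A"`, `"figure2_A2"`, `"figure2_A3"` — adjacency of the
#'   8-treatment illustration and its 2- and 3-walk count matrices.
#' * `"figure2_IC3"`, `"figure2_IC7"` — indicator of the cumulative walk
#'   sums at length 3 and 7 (identical here; the blocks fill by length 3).
#' * `"figure2_D"` — its distance matrix.
#' * `"network1_A"`, `"network1_IC"` — adjacency and indirect connection
#'   matrix of the 7-treatment example.
#' * `"network1_D_blocked"`, `"network3_D_blocked"` — block-collected
#'   distance matrices (labels in block order; off-block cells `NA`,
#'   rendered blank in print).
#' * `"network2_D"` — the full 23 x 23 distance matrix.
#'
#' @param name one of the matrix names above.
#' @return Labelled numeric matrix.
#' @export
reference_matrix <- function(name = c("figure2_A", "figure2_A2", "figure2_A3",
                                  "figure2_IC3", "figure2_IC7", "figure2_D",
                                  "network1_A", "network1_IC",
                                  "network1_D_blocked", "network2_D",
                                  "network3_D_blocked")) {
  name <- match.arg(name)
  l8 <- as.character(1:8)
  l7 <- as.character(1:7)
  switch(name,
    figure2_A   = adjacency_matrix(example_network("figure2")),
    figure2_A2  = digits_to_matrix(FIG2_A2, 8L, l8),
    figure2_A3  = digits_to_matrix(FIG2_A3, 8L, l8),
    figure2_IC3 = digits_to_matrix(FIG2_IC, 8L, l8),
    figure2_IC7 = digits_to_matrix(FIG2_IC, 8L, l8),
    figure2_D   = digits_to_matrix(FIG2_D, 8L, l8),
    network1_A  = rows_to_matrix(NET1_A_ROWS, l7),
    network1_IC = rows_to_matrix(NET1_IC_ROWS, l7),
    network1_D_blocked = blocks_to_matrix(
      list(matrix(NET1_D_BLOCK1, 4L, 4L, byrow = TRUE),
           matrix(NET1_D_BLOCK2, 3L, 3L, byrow = TRUE)),
      NET1_D_BLOCK_LABELS),
    network2_D = rows_to_matrix(NET2_D_ROWS, as.character(1:23)),
    network3_D_blocked = blocks_to_matrix(
      lapply(list(NET3_D_B1_ROWS, NET3_D_B2_ROWS,
                  NET3_D_B3_ROWS, NET3_D_B4_ROWS),
             function(r) rows_to_matrix(r, as.character(seq_along(r)))),
      NET3_D_BLOCK_LABELS))
}

#' Seeded random evidence networks with planted components
#'
#' Generates a reproducible network with a prescribed component structure:
#' each component is laid down as a uniform random spanning tree (via a
#' random Pruefer sequence), guaranteeing it is connected, and every
#' remaining within-component pair is then added independently with
#' probability `edge_density`. No between-component edges are ever added,
#' so the realized number of connected components equals
#' `length(component_sizes)` by construction.
#'
#' @param n number of treatments; labels are `"1" ... "n"`.
#' @param component_sizes integer vector summing to `n`, one entry per
#'   planted component (default: one connected component).
#' @param edge_density probability in `[0, 1]` for each within-component
#'   non-tree pair (0 gives bare spanning trees, 1 complete components).
#' @param seed integer seed; the same seed always yields the same network.
#'   The caller's random number generator state is left untouched.
#' @return An [evidence_network()].
#' @examples
#' net <- random_network(6, component_sizes = c(3, 3), edge_density = 1,
#'                       seed = 42)
#' connected_components(net)
#' @export
random_network <- function(n, component_sizes = n, edge_density = 0, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    stop_invalid_input("`n` must be a positive integer")
  }
  component_sizes <- as.integer(component_sizes)
  if (any(component_sizes < 1L) || sum(component_sizes) != n) {
    stop_invalid_input("`component_sizes` must be positive and sum to `n`")
  }
  if (!is.numeric(edge_density) || edge_density < 0 || edge_density > 1) {
    stop_invalid_input("`edge_density` must be in [0, 1]")
  }
  if (missing(seed)) stop_invalid_input("`seed` is required")
  with_local_seed(seed, {
    labels <- as.character(seq_len(n))
    edges <- NULL
    at <- 0L
    for (size in component_sizes) {
      members <- labels[at + seq_len(size)]
      tree <- prufer_tree(size)
      comp_edges <- if (nrow(tree)) {
        cbind(members[tree[, 1L]], members[tree[, 2L]])
      } else {
        matrix(character(), 0L, 2L)
      }
      if (edge_density > 0 && size > 2L) {
        all_pairs <- t(utils::combn(size, 2L))
        in_tree <- paste(pmin(tree[, 1L], tree[, 2L]),
                         pmax(tree[, 1L], tree[, 2L]))
        key <- paste(all_pairs[, 1L], all_pairs[, 2L])
        extra <- all_pairs[!(key %in% in_tree), , drop = FALSE]
        take <- stats::runif(nrow(extra)) < edge_density
        if (any(take)) {
          comp_edges <- rbind(comp_edges,
                              cbind(members[extra[take, 1L]],
                                    members[extra[take, 2L]]))
        }
      }
      edges <- rbind(edges, comp_edges)
      at <- at + size
    }
    evidence_network(edges = edges, labels = labels)
  })
}

# uniform random labelled tree on m vertices, by decoding a random Pruefer
# sequence with the smallest-leaf rule
prufer_tree <- function(m) {
  if (m == 1L) return(matrix(integer(), 0L, 2L))
  if (m == 2L) return(matrix(c(1L, 2L), 1L, 2L))
  s <- sample.int(m, m - 2L, replace = TRUE)
  degree <- tabulate(s, m) + 1L
  edges <- matrix(0L, m - 1L, 2L)
  for (i in seq_along(s)) {
    leaf <- which(degree == 1L)[1L]
    edges[i, ] <- c(leaf, s[i])
    degree[leaf] <- 0L
    degree[s[i]] <- degree[s[i]] - 1L
  }
  edges[m - 1L, ] <- which(degree == 1L)
  edges
}

# run code under a fixed seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
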