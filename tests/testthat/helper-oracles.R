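# Independent oracles for property tests. Deliberately naive and written
# against different algorithmic ideas than the package (queue-based BFS,
# union-find, recursive walk enumeration) so agreement is meaningful.

# all-pairs shortest-path lengths by breadth-first search
bfs_distances <- function(adj, unconnected = 0) {
  n <- nrow(adj)
  D <- matrix(unconnected, n, n, dimnames = dimnames(adj))
  for (s in seq_len(n)) {
    dist <- rep(NA_real_, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(adj[v, ] == 1)
      fresh <- nb[is.na(dist[nb])]
      dist[fresh] <- dist[v] + 1
      queue <- c(queue, fresh)
    }
    dist[is.na(dist)] <- unconnected
    D[s, ] <- dist
  }
  diag(D) <- 0
  D
}

# connected components by union-find with path compression
uf_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(n)) {
    for (j in which(adj[i, ] == 1)) {
      ri <- find(i)
      rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  labels <- rownames(adj)
  lapply(unique(roots[order(roots)]), function(r) labels[roots == r])
}

# number of k-step walks from i to j by exhaustive recursion
count_walks_brute <- function(adj, k, i, j) {
  if (k == 0L) return(as.numeric(i == j))
  sum(vapply(which(adj[i, ] == 1), count_walks_brute,
             numeric(1L), adj = adj, k = k - 1L, j = j))
}

# raw random symmetric 0/1 adjacency, independent of the package generator
rand_adjacency <- function(n, p) {
  A <- matrix(0, n, n, dimnames = list(as.character(seq_len(n)),
                                       as.character(seq_len(n))))
  if (n > 1L) {
    up <- which(upper.tri(A))
    on <- up[stats::runif(length(up)) < p]
    A[on] <- 1
    A <- pmax(A, t(A))
  }
  A
}

# write an evidence network to a file in each input dialect
write_dialect <- function(net, format, path, sep = ",") {
  q <- function(x) x  # fixture labels never need quoting
  lines <- switch(format,
    edges = c(paste("t_from", "t_to", sep = sep),
              paste(net$edges[, 1L], net$edges[, 2L], sep = sep)),
    long = {
      pairs <- net$edges
      c(paste("study", "treatment", sep = sep),
        unlist(lapply(seq_len(nrow(pairs)), function(i) {
          paste(paste0("s", i), pairs[i, ], sep = sep)
        })))
    },
    wide = c(paste("t1", "t2", "t3", sep = sep),
             paste(net$edges[, 1L], net$edges[, 2L], "NA", sep = sep)))
  writeLines(lines, path)
  path
}
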