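# Minimal exact big-integer arithmetic for walk counts.
#
# Walk-count matrices grow like n^k, so double precision (exact only below
# 2^53) is not enough for the arbitrary-precision contract of walk_counts()
# and cumulative_walks(). Numbers are vectors of base-1e6 limbs, least
# significant first, stored as doubles; limb products stay below 1e12 and
# accumulated convolution sums stay far below 2^53 for any matrix size used
# here, so every operation is exact.

BIG_BASE <- 1e6

# carry-propagate and strip leading zero limbs
big_norm <- function(x) {
  i <- 1L
  while (i <= length(x)) {
    if (x[i] >= BIG_BASE) {
      carry <- x[i] %/% BIG_BASE
      x[i] <- x[i] - carry * BIG_BASE
      if (i == length(x)) x <- c(x, 0)
      x[i + 1L] <- x[i + 1L] + carry
    }
    i <- i + 1L
  }
  while (length(x) > 1L && x[length(x)] == 0) x <- x[-length(x)]
  x
}

big_from_num <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 2^53)
  if (x == 0) return(0)
  out <- numeric(0)
  while (x > 0) {
    out <- c(out, x %% BIG_BASE)
    x <- x %/% BIG_BASE
  }
  out
}

big_add <- function(a, b) {
  l <- max(length(a), length(b))
  big_norm(c(a, numeric(l - length(a))) + c(b, numeric(l - length(b))))
}

big_mul <- function(a, b) {
  if (big_is_zero(a) || big_is_zero(b)) return(0)
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1L)
    res[idx] <- res[idx] + a[i] * b
  }
  big_norm(res)
}

big_is_zero <- function(a) length(a) == 1L && a[1L] == 0

big_to_char <- function(a) {
  if (length(a) == 1L) return(formatC(a, format = "d"))
  head <- formatC(a[length(a)], format = "d")
  rest <- vapply(rev(a[-length(a)]), formatC,
                 character(1L), format = "d", width = 6, flag = "0")
  paste0(head, paste(rest, collapse = ""))
}

# exact numeric value, or NA if it does not fit below 2^53
big_to_num <- function(a) {
  v <- sum(a * BIG_BASE^(seq_along(a) - 1L))
  if (v < 2^53) v else NA_real_
}

# big matrices are plain lists in column-major order with an "n" attribute
bigmat_from_matrix <- function(m) {
  n <- nrow(m)
  structure(lapply(as.numeric(m), big_from_num), n = n)
}

# X %*% Y where Y is a small 0/1 numeric matrix (the adjacency)
bigmat_mult_adj <- function(X, adj) {
  n <- attr(X, "n")
  Z <- vector("list", n * n)
  for (j in seq_len(n)) {
    rows_k <- which(adj[, j] != 0)
    for (i in seq_len(n)) {
      acc <- 0
      for (k in rows_k) {
        acc <- big_add(acc, X[[i + (k - 1L) * n]])
      }
      Z[[i + (j - 1L) * n]] <- acc
    }
  }
  structure(Z, n = n)
}

bigmat_add <- function(X, Y) {
  structure(mapply(big_add, X, Y, SIMPLIFY = FALSE), n = attr(X, "n"))
}

# render as a numeric matrix when every entry fits below 2^53, otherwise as
# a character matrix of decimal strings
bigmat_to_matrix <- function(X, labels) {
  n <- attr(X, "n")
  num <- vapply(X, big_to_num, numeric(1L))
  if (!anyNA(num)) {
    out <- matrix(num, n, n)
  } else {
    out <- matrix(vapply(X, big_to_char, character(1L)), n, n)
  }
  dimnames(out) <- list(labels, labels)
  out
}
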