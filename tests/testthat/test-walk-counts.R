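test_that("walk counts agree with exhaustive enumeration on random graphs", {
  set.seed(101)
  for (rep in 1:15) {
    n <- sample(2:6, 1)
    A <- rand_adjacency(n, stats::runif(1))
    k <- sample(1:4, 1)
    W <- walk_counts(A, k)
    brute <- outer(seq_len(n), seq_len(n),
                   Vectorize(function(i, j) count_walks_brute(A, k, i, j)))
    expect_equal(unname(W), brute)
  }
})

test_that("small walk-count cases match hand enumeration", {
  path3 <- evidence_network(rbind(c("1", "2"), c("2", "3")))
  W2 <- walk_counts(adjacency_matrix(path3), 2)
  expect_equal(W2["1", "3"], 1)  # the single 2-walk 1-2-3
  expect_equal(W2["2", "2"], 2)  # 2-1-2 and 2-3-2
  A <- adjacency_matrix(example_network("figure2"))
  expect_identical(walk_counts(A, 1), A)
  edge <- adjacency_matrix(evidence_network(rbind(c("a", "b"))))
  C2 <- cumulative_walks(edge, 2)
  expect_equal(unname(C2), rbind(c(1, 1), c(1, 1)))  # one 2-walk back to self
  expect_identical(cumulative_walks(A, 1), A)
})

test_that("cumulative walks equal the explicit sum of powers", {
  set.seed(7)
  A <- rand_adjacency(7, 0.4)
  l <- 5
  expect_equal(cumulative_walks(A, l),
               Reduce(`+`, lapply(1:l, function(k) walk_counts(A, k))))
})

test_that("walk length must be a positive integer", {
  A <- adjacency_matrix(example_network("figure2"))
  expect_error(walk_counts(A, 0), class = "nmaconnect_domain_error")
  expect_error(walk_counts(A, 2.5), class = "nmaconnect_domain_error")
  expect_error(cumulative_walks(A, -1), class = "nmaconnect_domain_error")
})

test_that("big-integer limb arithmetic matches doubles in the exact range", {
  set.seed(11)
  for (rep in 1:50) {
    a <- as.numeric(sample.int(1e7, 1))
    b <- as.numeric(sample.int(1e7, 1))
    ba <- nmaconnect:::big_from_num(a)
    bb <- nmaconnect:::big_from_num(b)
    expect_equal(nmaconnect:::big_to_num(nmaconnect:::big_mul(ba, bb)), a * b)
    expect_equal(nmaconnect:::big_to_num(nmaconnect:::big_add(ba, bb)), a + b)
    expect_identical(nmaconnect:::big_to_char(ba), formatC(a, format = "d"))
  }
})

test_that("huge walk counts are exact (checked modulo independent primes)", {
  # complete graph on 8 vertices, 60-step walks: entries near 7^60 ~ 5e50,
  # far beyond double precision. Closed form for K_n: off-diagonal counts
  # are ((n-1)^k - (-1)^k) / n, diagonal ((n-1)^k + (n-1)(-1)^k) / n.
  # The decimal strings are verified modulo several primes against modular
  # exponentiation done entirely in doubles.
  n <- 8; k <- 60
  Kn <- matrix(1, n, n) - diag(n)
  dimnames(Kn) <- list(as.character(1:n), as.character(1:n))
  W <- walk_counts(Kn, k)
  expect_type(W, "character")
  str_mod <- function(s, p) {
    v <- 0
    for (d in as.integer(strsplit(s, "")[[1]])) v <- (v * 10 + d) %% p
    v
  }
  pow_mod <- function(base, exp, p) {
    r <- 1; base <- base %% p
    while (exp > 0) {
      if (exp %% 2 == 1) r <- (r * base) %% p
      base <- (base * base) %% p
      exp <- exp %/% 2
    }
    r
  }
  for (p in c(1009L, 7919L, 104729L)) {
    inv_n <- pow_mod(n, p - 2, p)  # Fermat inverse; p prime, p !| n
    off <- ((pow_mod(n - 1, k, p) - 1) %% p * inv_n) %% p
    dia <- ((pow_mod(n - 1, k, p) + (n - 1)) %% p * inv_n) %% p
    expect_equal(str_mod(W["1", "2"], p), off)
    expect_equal(str_mod(W["3", "3"], p), dia)
  }
  # all off-diagonal (and all diagonal) entries identical by symmetry
  expect_length(unique(W[upper.tri(W)]), 1)
  expect_length(unique(diag(W)), 1)
  # indicator handles the decimal-string representation
  expect_equal(unname(indicator(W)), matrix(1, n, n))
})
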