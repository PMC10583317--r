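# Brute-force oracles used by the equivalence tests. Everything here is the
# naive reference implementation, deliberately independent of the package's
# vectorized code paths.

# TOM by triple loop over nodes
brute_tom <- function(a) {
  a <- as.matrix(a)
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { tom[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# hypergeometric upper-tail P(X >= k) by direct summation of the pmf
enum_hypergeom <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# exact betweenness by DFS enumeration of all simple paths between every
# pair, keeping only shortest ones (feasible for small sparse graphs)
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  paths_between <- function(s, t) {
    found <- list()
    walk <- function(v, path) {
      if (v == t) { found[[length(found) + 1]] <<- path; return(invisible()) }
      for (w in which(adj[v, ] > 0)) {
        if (!(w %in% path)) walk(w, c(path, w))
      }
    }
    walk(s, s)
    if (length(found) == 0) return(list())
    len <- vapply(found, length, integer(1))
    found[len == min(len)]
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      ps <- paths_between(s, t)
      if (length(ps) == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(ps, function(p) v %in% p, logical(1)))
        btw[v] <- btw[v] + through / length(ps)
      }
    }
  }
  # undirected betweenness counts each unordered pair once
  btw
}

# Pearson correlation by explicit sums
brute_cor <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# a small deterministic abundance fixture: 6 features x 5 samples
fixture_table <- function() {
  m <- matrix(c(
    10, 12, 11,  9, 13,
     0,  0, 50,  0,  0,
     5,  0,  0,  6,  0,
    20, 18, 25, 22, 19,
     0, 40,  0,  0, 35,
     1,  2,  3,  4,  5), nrow = 6, byrow = TRUE,
    dimnames = list(paste0("f", 1:6), paste0("s", 1:5)))
  abundance_table(m)
}
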