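# Brute-force oracles, deliberately independent of the package internals.

# all-pairs shortest path lengths by Floyd-Warshall on an adjacency matrix
fw_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- D[i, k] + D[k, ]
      D[i, ] <- pmin(D[i, ], nd)
    }
  }
  D
}

brute_aspl <- function(A) {
  D <- fw_distances(A)
  mean(D[upper.tri(D)])
}

brute_diameter <- function(A) {
  D <- fw_distances(A)
  max(D[upper.tri(D)])
}

# mean local clustering by explicit neighbour-pair enumeration
brute_clustering <- function(A) {
  n <- nrow(A)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    pairs <- combn(nb, 2)
    tri <- sum(A[cbind(pairs[1, ], pairs[2, ])])
    tri / (k * (k - 1) / 2)
  }, numeric(1)))
}

igraph_to_adj <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

random_connected_graph <- function(n, p = 0.5) {
  repeat {
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < p)
    A <- A + t(A)
    if (n < 2) return(A)
    if (all(is.finite(fw_distances(A)))) return(A)
  }
}

adj_to_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# ---- brute-force planarity oracle (Euler bound + Kuratowski subdivisions) ----

# reduce: drop degree<=1 vertices, smooth degree-2 vertices, keep simple.
# These operations preserve planarity, and K5/K3,3 subdivisions survive them.
reduce_graph <- function(A) {
  repeat {
    n <- nrow(A)
    if (n == 0) return(A)
    deg <- rowSums(A)
    low <- which(deg <= 1)
    if (length(low) > 0) {
      A <- A[-low, -low, drop = FALSE]
      next
    }
    two <- which(deg == 2)
    if (length(two) == 0) return(A)
    v <- two[1]
    nb <- which(A[v, ] == 1)
    A[nb[1], nb[2]] <- 1L
    A[nb[2], nb[1]] <- 1L
    A <- A[-v, -v, drop = FALSE]
  }
}

# enumerate simple paths s -> t whose internal vertices come from `allowed`
paths_between <- function(A, s, t, allowed) {
  found <- list()
  walk <- function(v, path) {
    for (w in which(A[v, ] == 1)) {
      if (w == t) {
        found[[length(found) + 1]] <<- path
      } else if (w %in% allowed && !(w %in% path)) {
        walk(w, c(path, w))
      }
    }
  }
  walk(s, integer())
  found
}

# do internally-disjoint paths exist for all branch-vertex pairs?
disjoint_paths_exist <- function(A, pairs, branch) {
  n <- nrow(A)
  rec <- function(k, used) {
    if (k > ncol(pairs)) return(TRUE)
    s <- pairs[1, k]; t <- pairs[2, k]
    allowed <- setdiff(seq_len(n), c(branch, used))
    for (pth in paths_between(A, s, t, allowed)) {
      if (rec(k + 1, c(used, pth))) return(TRUE)
    }
    FALSE
  }
  rec(1, integer())
}

has_k5_subdivision <- function(A) {
  deg <- rowSums(A)
  cand <- which(deg >= 4)
  if (length(cand) < 5) return(FALSE)
  for (b in combn(cand, 5, simplify = FALSE)) {
    if (disjoint_paths_exist(A, combn(b, 2), b)) return(TRUE)
  }
  FALSE
}

has_k33_subdivision <- function(A) {
  deg <- rowSums(A)
  cand <- which(deg >= 3)
  if (length(cand) < 6) return(FALSE)
  for (six in combn(cand, 6, simplify = FALSE)) {
    # partitions of six vertices into two unordered triples
    for (two_more in combn(2:6, 2, simplify = FALSE)) {
      left <- six[c(1, two_more)]
      right <- setdiff(six, left)
      pairs <- rbind(rep(left, each = 3), rep(right, times = 3))
      if (disjoint_paths_exist(A, pairs, six)) return(TRUE)
    }
  }
  FALSE
}

brute_planar <- function(A) {
  A <- reduce_graph(A)
  n <- nrow(A)
  m <- sum(A) / 2
  if (n <= 4 || m <= 8) return(TRUE)
  if (m > 3 * n - 6) return(FALSE)
  !(has_k5_subdivision(A) || has_k33_subdivision(A))
}

# greedy PMFG with the brute-force planarity oracle at every step
brute_pmfg <- function(W) {
  n <- nrow(W)
  idx <- which(upper.tri(W), arr.ind = TRUE)
  ord <- order(-W[idx], idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  A <- matrix(0L, n, n)
  kept <- 0L
  for (r in seq_len(nrow(idx))) {
    if (kept == 3 * (n - 2)) break
    i <- idx[r, 1]; j <- idx[r, 2]
    A[i, j] <- A[j, i] <- 1L
    if (brute_planar(A)) kept <- kept + 1L
    else A[i, j] <- A[j, i] <- 0L
  }
  A
}

# random valid correlation matrix with word dimnames
random_corr_matrix <- function(n, vocab = sprintf("w%02d", seq_len(n))) {
  X <- matrix(rnorm((n + 5) * n), n + 5, n)
  C <- cor(X)
  dimnames(C) <- list(vocab, vocab)
  C
}

# small helper: random symmetric weight matrix with distinct entries
random_weight_matrix <- function(n, vocab = sprintf("w%02d", seq_len(n))) {
  W <- matrix(0, n, n, dimnames = list(vocab, vocab))
  W[upper.tri(W)] <- sample(seq_len(n * (n - 1) / 2)) / (n * n)
  W <- W + t(W)
  diag(W) <- 1
  W
}

# tiny two-group long-format fixture
toy_long_df <- function() {
  data.frame(
    group = rep(c("A", "B"), each = 6),
    subject = c("a1", "a1", "a1", "a2", "a2", "a2",
                "b1", "b1", "b1", "b2", "b2", "b2"),
    order = rep(1:3, 4),
    word = c("cat", "dog", "lion", "dog", "cat", "horse",
             "cat", "dog", "shark", "dog", "whale", "cat"),
    stringsAsFactors = FALSE
  )
}
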