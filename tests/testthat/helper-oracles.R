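# Independent oracles and small fixture builders shared across tests.

# Adjusted Rand index between two labelings (closed form on the
# contingency table; independent of any clustering code under test).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# Canonical undirected edge keys for edge-set comparison.
edge_key <- function(edges) {
  sort(paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to)))
}

# Exhaustive minimum spanning tree via Prufer-sequence enumeration of all
# n^(n-2) labeled trees; tractable for n <= 7 (7^5 = 16807 trees).
prufer_decode <- function(seq, nodes) {
  n <- length(nodes)
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, nrow = n - 1, ncol = 2)
  k <- 1L
  for (s in seq) {
    leaf <- which(degree == 1L)[1]
    edges[k, ] <- c(leaf, s)
    k <- k + 1L
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  last <- which(degree == 1L)
  edges[k, ] <- last
  edges
}

brute_force_mst_weight <- function(dm) {
  nodes <- rownames(dm)
  n <- length(nodes)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  best_edges <- NULL
  for (i in seq_len(nrow(seqs))) {
    e <- prufer_decode(seqs[i, ], nodes)
    w <- sum(dm[e])
    if (w < best) {
      best <- w
      best_edges <- e
    }
  }
  list(weight = best,
       edges = tibble::tibble(from = nodes[best_edges[, 1]],
                              to = nodes[best_edges[, 2]]))
}

# Brute-force pairwise Euclidean distance loop.
brute_force_distances <- function(profiles) {
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((profiles[i, ] - profiles[j, ])^2))
    }
  }
  d
}

# A noiseless 1-D curve through 6-D marker space, 100 cells per stage,
# used as planted pseudotime for the progression algorithms.
curve_events <- function(n_per = 100) {
  tt <- seq(0, 1, length.out = 7 * n_per)
  x <- tibble::tibble(CD24 = sin(3 * tt), CD25 = cos(3 * tt), CD73 = tt,
                      CD117 = tt^2, CD200 = sin(5 * tt), CD371 = cos(2 * tt))
  x$stage <- rep(gd_stages(), each = n_per)
  x$pseudotime <- tt
  attr(x, "transformed") <- TRUE
  x
}

# Small transformed synthetic event set shared by clustering tests.
small_events <- function(n = 2000, seed = 5, treatment = NULL) {
  arcsinh_transform(simulate_cytometry(cytometry_sim_config(
    n_events = n, treatment_effects = treatment, seed = seed)))
}
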