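#' Isomap progression of single cells
#'
#' Nonlinear progression analysis of marker space: each population is
#' down-sampled to `n_per_population` cells (seeded; smaller populations
#' keep all cells and are flagged), a symmetrised k-nearest-neighbour graph
#' is built on Euclidean marker distances, geodesic distances are taken as
#' shortest paths through the graph, and classical metric MDS of the
#' geodesics gives the low-dimensional coordinates.
#'
#' With `k_neighbors = n - 1` the graph is complete, geodesics equal the
#' raw Euclidean distances and the result reduces to classical MDS.
#'
#' @param events Transformed event tibble with a stage/population label.
#' @param label Name of the population label column.
#' @param n_per_population Cells retained per population (default 100).
#' @param k_neighbors Neighbours for the graph (default 10).
#' @param n_components Output dimensions (default 2).
#' @param seed Integer seed for the down-sampling.
#' @param markers Channels used.
#' @return Tibble with `iso1`, `iso2`, ... plus the retained events'
#'   annotation columns. Populations smaller than `n_per_population` are
#'   listed in the `short_groups` attribute.
#' @export
isomap_progression <- function(events, label = "stage",
                               n_per_population = 100, k_neighbors = 10,
                               n_components = 2, seed = 1,
                               markers = gd_markers()) {
  require_transformed(events, "isomap_progression")
  if (!label %in% names(events)) {
    abort(sprintf("no '%s' column in events", label))
  }
  sub <- downsample_by_group(events, label, n_per_population, seed)
  x <- marker_matrix(sub, markers)
  n <- nrow(x)
  if (k_neighbors >= n) k_neighbors <- n - 1
  d <- sqrt(cross_dist2(x, x))

  # symmetrised kNN adjacency
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nn <- order(d[i, -i])[seq_len(k_neighbors)]
    adj[i, seq_len(n)[-i][nn]] <- TRUE
  }
  adj <- adj | t(adj)
  w <- pmax(d, t(d)) * adj                 # exactly symmetric weights
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  if (igraph::components(g)$no > 1) {
    abort("k-NN graph is disconnected; increase k_neighbors")
  }
  geo <- igraph::distances(g, algorithm = "dijkstra")
  coords <- cmdscale(geo, k = n_components)
  colnames(coords) <- paste0("iso", seq_len(ncol(coords)))
  meta <- setdiff(names(sub), markers)
  out <- dplyr::bind_cols(tibble::as_tibble(coords),
                          sub[meta])
  attr(out, "short_groups") <- attr(sub, "short_groups")
  out
}

#' Diffusion-map progression of single cells
#'
#' Anisotropic diffusion map (alpha = 1) of marker space on a per-population
#' down-sampled set: Gaussian kernel `W_ij = exp(-d_ij^2 / (2 sigma^2))`
#' with `sigma` defaulting to the median pairwise distance, density
#' normalisation `W / (q q^T)`, row-normalisation to a Markov matrix, and
#' coordinates given by the leading non-trivial right eigenvectors scaled
#' by their eigenvalues.
#'
#' @inheritParams isomap_progression
#' @param sigma Kernel bandwidth; `NULL` uses the median heuristic.
#' @return Tibble with `dc1`, `dc2`, ... plus annotation columns; the
#'   eigenvalue spectrum (including the trivial unit eigenvalue) is in the
#'   `eigenvalues` attribute.
#' @export
diffusion_progression <- function(events, label = "stage",
                                  n_per_population = 100, sigma = NULL,
                                  n_components = 2, seed = 1,
                                  markers = gd_markers()) {
  require_transformed(events, "diffusion_progression")
  if (!label %in% names(events)) {
    abort(sprintf("no '%s' column in events", label))
  }
  sub <- downsample_by_group(events, label, n_per_population, seed)
  x <- marker_matrix(sub, markers)
  n <- nrow(x)
  d2 <- cross_dist2(x, x)
  if (is.null(sigma)) {
    sigma <- median(sqrt(d2[upper.tri(d2)]))
  }
  if (sigma <= 0) abort("sigma must be positive")

  w <- exp(-d2 / (2 * sigma^2))
  q <- rowSums(w)
  w1 <- w / outer(q, q)                     # alpha = 1 density normalisation
  deg <- rowSums(w1)
  s <- w1 / sqrt(outer(deg, deg))           # symmetric conjugate of the Markov matrix
  es <- eigen(s, symmetric = TRUE)
  lambda <- es$values
  psi <- es$vectors / sqrt(deg)             # right eigenvectors of P
  # fix signs deterministically
  for (j in seq_len(ncol(psi))) {
    i <- which.max(abs(psi[, j]))
    if (psi[i, j] < 0) psi[, j] <- -psi[, j]
  }
  k <- n_components
  coords <- psi[, 2:(k + 1), drop = FALSE] *
    rep(lambda[2:(k + 1)], each = n)
  colnames(coords) <- paste0("dc", seq_len(k))
  meta <- setdiff(names(sub), markers)
  out <- dplyr::bind_cols(tibble::as_tibble(coords), sub[meta])
  attr(out, "eigenvalues") <- lambda
  attr(out, "sigma") <- sigma
  attr(out, "short_groups") <- attr(sub, "short_groups")
  out
}
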