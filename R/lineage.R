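#' Pairwise transcriptional distance matrix between populations
#'
#' Euclidean distance between population expression profiles, computed on
#' log2 expression over all retained genes after averaging biological
#' replicates (populations are subset x stage combinations, or stages when
#' `subset` restricts to one subset). An exclusion list (e.g. erythrocyte-
#' associated transcripts) can be removed first.
#'
#' @param expr Wide expression tibble (`gene` column plus sample columns).
#' @param samples Sample metadata tibble with columns `sample`, `subset`,
#'   `stage`, `replicate`.
#' @param subset Optional subset label to restrict to.
#' @param exclude_genes Genes removed before computing distances.
#' @return Symmetric labelled matrix of class `gd_dist` (zero diagonal,
#'   `metric` attribute `"euclidean"`).
#' @examples
#' sim <- simulate_expression(expression_sim_config(n_genes = 200, seed = 1))
#' distance_matrix(sim$log2, sim$samples, subset = "Vg1.1")
#' @export
distance_matrix <- function(expr, samples, subset = NULL,
                            exclude_genes = NULL) {
  prof <- population_profiles(expr, samples, subset, exclude_genes)
  if (nrow(prof) < 2) {
    abort("at least 2 populations are required")
  }
  d <- as.matrix(dist(prof, method = "euclidean"))
  structure(d, metric = "euclidean", class = c("gd_dist", class(d)))
}

# Population (subset x stage) mean profiles: populations x genes matrix.
population_profiles <- function(expr, samples, subset = NULL,
                                exclude_genes = NULL) {
  stopifnot("gene" %in% names(expr))
  if (!is.null(subset)) {
    samples <- samples[samples$subset %in% subset, ]
  }
  if (nrow(samples) == 0) {
    abort("no samples left after subset filtering")
  }
  keep <- !(expr$gene %in% (exclude_genes %||% character(0)))
  x <- as.matrix(expr[keep, samples$sample, drop = FALSE])
  rownames(x) <- expr$gene[keep]
  pop <- if (length(unique(samples$subset)) > 1) {
    paste0("V", match(samples$subset, sort(unique(samples$subset))),
           samples$stage)
  } else {
    samples$stage
  }
  sizes <- table(pop)
  if (any(sizes == 0)) abort("population with zero samples")
  prof <- t(rowsum(t(x), pop) / as.vector(sizes[sort(unique(pop))]))
  t(prof)
}

#' Build a lineage graph from a distance matrix
#'
#' Connects populations by transcriptional similarity. `method = "mst"`
#' (default) gives the minimum spanning tree -- the minimal connected
#' realisation of "link the least different populations" -- via Kruskal's
#' algorithm with deterministic lexicographic tie-breaking. `method =
#' "knn"` links each population to its `k` nearest neighbours
#' (symmetrised).
#'
#' @param dm A `gd_dist` matrix (or any labelled symmetric matrix).
#' @param method `"mst"` or `"knn"`.
#' @param k Neighbours for the knn method.
#' @return Object of class `lineage_graph`: edge tibble (`from`, `to`,
#'   `weight`), node degrees, leaf set and branch points (degree >= 3).
#' @export
build_lineage_graph <- function(dm, method = c("mst", "knn"), k = 2) {
  method <- match.arg(method)
  dm <- as.matrix(dm)
  if (any(!is.finite(dm))) abort("distance matrix contains non-finite values")
  nodes <- rownames(dm)
  n <- length(nodes)
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  edges <- tibble::tibble(from = nodes[pairs[, 1]], to = nodes[pairs[, 2]],
                          weight = dm[pairs])
  edges <- dplyr::arrange(edges, .data$weight, .data$from, .data$to)

  if (method == "mst") {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    keep <- logical(nrow(edges))
    for (e in seq_len(nrow(edges))) {
      a <- find(match(edges$from[e], nodes))
      b <- find(match(edges$to[e], nodes))
      if (a != b) {
        parent[a] <- b
        keep[e] <- TRUE
      }
    }
    edges <- edges[keep, ]
  } else {
    picked <- lapply(seq_len(n), function(i) {
      ord <- order(dm[i, -i])[seq_len(min(k, n - 1))]
      others <- nodes[-i][ord]
      tibble::tibble(from = pmin(nodes[i], others),
                     to = pmax(nodes[i], others))
    })
    edges <- dplyr::bind_rows(picked) |>
      dplyr::distinct() |>
      dplyr::mutate(weight = dm[cbind(.data$from, .data$to)]) |>
      dplyr::arrange(.data$weight, .data$from, .data$to)
  }

  degree <- table(factor(c(edges$from, edges$to), levels = nodes))
  structure(
    list(edges = edges, nodes = nodes, method = method,
         degrees = setNames(as.integer(degree), nodes),
         leaves = nodes[degree == 1],
         branch_points = nodes[degree >= 3]),
    class = "lineage_graph")
}

#' @export
print.lineage_graph <- function(x, ...) {
  cat(sprintf("<lineage_graph> %s over %d nodes; leaves: %s; branch points: %s\n",
              x$method, length(x$nodes),
              paste(x$leaves, collapse = ", "),
              paste(x$branch_points, collapse = ", ")))
  print(x$edges)
  invisible(x)
}

#' Principal component analysis of population transcriptomes
#'
#' Column-centred PCA (via singular value decomposition) of samples in gene
#' space, as used to corroborate the branching structure of the population
#' graph.
#'
#' @param expr Wide expression tibble (`gene` column plus samples).
#' @param samples Sample metadata tibble.
#' @param n_components Components to return.
#' @param exclude_genes Optional genes to drop first.
#' @return Object of class `gd_pca`: `scores` tibble (sample metadata plus
#'   `PC1`, `PC2`, ...) and `explained_variance` fractions.
#' @export
pca_populations <- function(expr, samples, n_components = 2,
                            exclude_genes = NULL) {
  keep <- !(expr$gene %in% (exclude_genes %||% character(0)))
  x <- t(as.matrix(expr[keep, samples$sample, drop = FALSE]))
  if (nrow(x) < n_components) {
    abort("more components requested than samples")
  }
  if (all(abs(sweep(x, 2, colMeans(x))) < 1e-12)) {
    abort("expression matrix is constant; no variance to decompose")
  }
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  scores <- dplyr::bind_cols(samples,
                             tibble::as_tibble(fit$x[, seq_len(k), drop = FALSE]))
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = scores, explained_variance = ev[seq_len(k)],
                 rotation = fit$rotation[, seq_len(k), drop = FALSE],
                 center = fit$center, full_sdev = fit$sdev),
            class = "gd_pca")
}
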