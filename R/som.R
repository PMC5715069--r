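#' Train a self-organizing map on event intensities
#'
#' Batch-mode SOM on a rectangular grid: every epoch each event is assigned
#' to its best-matching unit (BMU; ties broken by lowest node index) and
#' codebook vectors are replaced by the neighbourhood-weighted mean of the
#' data, with a Gaussian neighbourhood whose radius shrinks linearly from
#' half the grid diagonal to 0.5 over the epochs. Deterministic given the
#' seed (codebook initialised from a seeded sample of events).
#'
#' @param events Transformed event tibble.
#' @param grid_rows,grid_cols Grid dimensions.
#' @param epochs Training epochs (default 20).
#' @param seed Integer seed.
#' @param markers Channels to train on (default the six staging markers).
#' @return Object of class `gd_som`: codebook matrix (nodes x markers),
#'   grid coordinates, quantisation-error trace and training parameters.
#' @examples
#' ev <- simulate_cytometry(cytometry_sim_config(n_events = 500, seed = 1))
#' som <- som_fit(arcsinh_transform(ev), grid_rows = 4, grid_cols = 4,
#'                epochs = 5, seed = 1)
#' glance(som)
#' @export
som_fit <- function(events, grid_rows = 10, grid_cols = 10, epochs = 20,
                    seed = 1, markers = gd_markers()) {
  require_transformed(events, "som_fit")
  stopifnot(grid_rows >= 1, grid_cols >= 1, epochs >= 1)
  x <- marker_matrix(events, markers)
  n_nodes <- grid_rows * grid_cols
  grid <- tidyr::expand_grid(row = seq_len(grid_rows), col = seq_len(grid_cols))
  grid <- dplyr::mutate(grid, node = dplyr::row_number(),
                        .before = "row")
  gd2 <- cross_dist2(as.matrix(grid[c("row", "col")]),
                     as.matrix(grid[c("row", "col")]))

  codebook <- local_seed(seed, {
    if (nrow(x) >= n_nodes) {
      x[sample.int(nrow(x), n_nodes), , drop = FALSE]
    } else {
      x[sample.int(nrow(x), n_nodes, replace = TRUE), , drop = FALSE] +
        matrix(rnorm(n_nodes * ncol(x), sd = 1e-3), n_nodes)
    }
  })
  rownames(codebook) <- NULL

  radius <- seq(max(grid_rows, grid_cols) / 2, 0.5, length.out = epochs)
  qe <- numeric(epochs + 1)
  for (t in seq_len(epochs)) {
    d2 <- cross_dist2(x, codebook)
    bmu <- max.col(-d2, ties.method = "first")
    qe[t] <- mean(sqrt(d2[cbind(seq_len(nrow(x)), bmu)]))
    h <- exp(-gd2 / (2 * radius[t]^2))
    cnt <- tabulate(bmu, n_nodes)
    xsum <- matrix(0, n_nodes, ncol(x), dimnames = list(NULL, colnames(x)))
    present <- rowsum(x, bmu)
    xsum[as.integer(rownames(present)), ] <- present
    codebook <- (h %*% xsum) / as.vector(h %*% cnt)
  }
  d2 <- cross_dist2(x, codebook)
  bmu <- max.col(-d2, ties.method = "first")
  qe[epochs + 1] <- mean(sqrt(d2[cbind(seq_len(nrow(x)), bmu)]))

  structure(
    list(codebook = codebook, grid = grid, markers = markers,
         grid_rows = grid_rows, grid_cols = grid_cols, epochs = epochs,
         seed = seed, quantisation_error = qe,
         node_counts = tabulate(bmu, n_nodes)),
    class = "gd_som")
}

#' @export
print.gd_som <- function(x, ...) {
  cat(sprintf("<gd_som> %dx%d grid, %d epochs, final QE %.4f\n",
              x$grid_rows, x$grid_cols, x$epochs,
              tail(x$quantisation_error, 1)))
  invisible(x)
}

#' Best-matching unit per event
#'
#' @param som A fitted [som_fit()] model.
#' @param events Transformed event tibble.
#' @return Integer vector of node indices (ties to the lowest index).
#' @export
som_assign <- function(som, events) {
  x <- marker_matrix(events, som$markers)
  max.col(-cross_dist2(x, som$codebook), ties.method = "first")
}

#' Metacluster SOM nodes into k clusters
#'
#' Average-linkage hierarchical agglomeration of the codebook vectors on
#' Euclidean distances, cut at `k`. Only occupied nodes (best-matching unit
#' of at least one training event) enter the agglomeration: unoccupied
#' nodes interpolate between populations and would otherwise soak up
#' clusters; each inherits the label of its nearest occupied node, so every
#' grid node is labelled.
#'
#' @param som A fitted [som_fit()] model.
#' @param k Number of metaclusters, between 1 and the number of grid nodes.
#' @return Integer vector: cluster label per grid node.
#' @export
metacluster <- function(som, k) {
  n_nodes <- nrow(som$codebook)
  if (k < 1 || k > n_nodes) {
    abort(sprintf("k must be in [1, %d]", n_nodes))
  }
  used <- which((som$node_counts %||% rep(1L, n_nodes)) > 0)
  if (length(used) < k) used <- seq_len(n_nodes)
  hc <- hclust(dist(som$codebook[used, , drop = FALSE]), method = "average")
  labels_used <- cutree(hc, k = k)
  labels <- integer(n_nodes)
  labels[used] <- labels_used
  idle <- setdiff(seq_len(n_nodes), used)
  if (length(idle) > 0) {
    nearest <- max.col(-cross_dist2(som$codebook[idle, , drop = FALSE],
                                    som$codebook[used, , drop = FALSE]),
                       ties.method = "first")
    labels[idle] <- labels_used[nearest]
  }
  labels
}

#' Cluster events by SOM metaclustering
#'
#' Convenience wrapper: trains the SOM, metaclusters the grid at `k`, and
#' labels each event with its node's metacluster.
#'
#' @inheritParams som_fit
#' @param k Number of metaclusters (default 7).
#' @return `events` with an added integer `cluster` column; the fitted
#'   model and node labels are attached as attributes `som` and
#'   `node_clusters`.
#' @export
cluster_events <- function(events, k = 7, grid_rows = 10, grid_cols = 10,
                           epochs = 20, seed = 1, markers = gd_markers()) {
  som <- som_fit(events, grid_rows, grid_cols, epochs, seed, markers)
  node_clusters <- metacluster(som, k)
  events$cluster <- node_clusters[som_assign(som, events)]
  attr(events, "som") <- som
  attr(events, "node_clusters") <- node_clusters
  events
}

#' Mean marker profile per cluster
#'
#' @param events Event tibble with a cluster (or stage) label column.
#' @param label Name of the label column (default `"cluster"`).
#' @param markers Channels to profile.
#' @return Tibble: one row per cluster with its size `n` and per-marker
#'   mean intensity. Clusters present as factor levels but empty of events
#'   get `NaN` rows and are flagged in the `empty_clusters` attribute.
#' @export
cluster_profile <- function(events, label = "cluster", markers = gd_markers()) {
  if (!label %in% names(events)) {
    abort(sprintf("no '%s' column in events", label))
  }
  lv <- if (is.factor(events[[label]])) {
    levels(events[[label]])
  } else {
    sort(unique(events[[label]]))
  }
  out <- events |>
    dplyr::group_by(cluster = .data[[label]]) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(markers), mean),
                     .groups = "drop")
  missing <- setdiff(as.character(lv), as.character(out$cluster))
  if (length(missing) > 0) {
    out$cluster <- as.character(out$cluster)
    pad <- tibble::tibble(cluster = missing, n = 0L)
    for (m in markers) pad[[m]] <- NaN
    out <- dplyr::bind_rows(out, pad)
  }
  out <- dplyr::arrange(out, .data$cluster)
  attr(out, "empty_clusters") <- missing
  out
}

#' Match clusters to developmental stages
#'
#' Thresholds each cluster's mean profile and maps it to the stage whose
#' signature the resulting positivity pattern satisfies (strict signature
#' matching, no fall-through). Clusters satisfying no signature are labelled
#' `"unassigned"`. If two clusters map to one stage both are kept and the
#' collision is flagged.
#'
#' @param profile Tibble from [cluster_profile()].
#' @param thresholds Tibble from [fit_positivity_thresholds()].
#' @param signatures Signature table (default [stage_signatures()]).
#' @return Tibble with columns `cluster`, `stage`; collided stages are
#'   recorded in the `collisions` attribute.
#' @export
match_clusters_to_stages <- function(profile, thresholds,
                                     signatures = stage_signatures()) {
  signatures <- validate_signatures(signatures)
  markers <- gd_markers()
  thr <- setNames(thresholds$threshold, thresholds$marker)
  x <- as.matrix(profile[markers])
  positivity <- sweep(x, 2, thr[markers], ">")
  stage <- rep("unassigned", nrow(profile))
  for (s in attr(signatures, "gating_order")) {
    hit <- stage == "unassigned" &
      signature_satisfied(positivity, signatures[signatures$stage == s, ]) &
      stats::complete.cases(x)
    stage[hit] <- s
  }
  out <- tibble::tibble(cluster = profile$cluster, stage = stage)
  dup <- unique(stage[duplicated(stage) & stage != "unassigned"])
  if (length(dup) > 0) {
    warn(sprintf("multiple clusters map to stage(s): %s",
                 paste(dup, collapse = ", ")))
  }
  attr(out, "collisions") <- dup
  out
}
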