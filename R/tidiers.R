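#' Tidy a fitted SOM
#'
#' @param x A `gd_som`.
#' @param ... Unused.
#' @return Long tibble: `node`, `row`, `col`, `marker`, `value` (codebook
#'   weights).
#' @exportS3Method generics::tidy
#' @export
tidy.gd_som <- function(x, ...) {
  dplyr::bind_cols(x$grid, tibble::as_tibble(x$codebook)) |>
    tidyr::pivot_longer(dplyr::all_of(x$markers), names_to = "marker",
                        values_to = "value")
}

#' One-row summary of a fitted SOM
#'
#' @param x A `gd_som`.
#' @param ... Unused.
#' @return Tibble with grid size, epochs, seed and initial/final
#'   quantisation error.
#' @exportS3Method generics::glance
#' @export
glance.gd_som <- function(x, ...) {
  tibble::tibble(grid_rows = x$grid_rows, grid_cols = x$grid_cols,
                 epochs = x$epochs, seed = x$seed,
                 qe_initial = x$quantisation_error[1],
                 qe_final = tail(x$quantisation_error, 1))
}

#' Tidy a lineage graph into its edge list
#'
#' @param x A `lineage_graph`.
#' @param ... Unused.
#' @return Edge tibble (`from`, `to`, `weight`).
#' @exportS3Method generics::tidy
#' @export
tidy.lineage_graph <- function(x, ...) {
  x$edges
}

#' One-row summary of a lineage graph
#'
#' @param x A `lineage_graph`.
#' @param ... Unused.
#' @return Tibble with method, node/edge counts, total weight, leaf and
#'   branch-point counts.
#' @exportS3Method generics::glance
#' @export
glance.lineage_graph <- function(x, ...) {
  tibble::tibble(method = x$method, n_nodes = length(x$nodes),
                 n_edges = nrow(x$edges), total_weight = sum(x$edges$weight),
                 n_leaves = length(x$leaves),
                 n_branch_points = length(x$branch_points))
}

#' Tidy a distance matrix into long form
#'
#' @param x A `gd_dist`.
#' @param ... Unused.
#' @return Long tibble (`from`, `to`, `distance`), upper triangle only.
#' @exportS3Method generics::tidy
#' @export
tidy.gd_dist <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(from = rownames(m)[idx[, 1]], to = colnames(m)[idx[, 2]],
                 distance = m[idx])
}

#' Tidy PCA scores
#'
#' @param x A `gd_pca`.
#' @param ... Unused.
#' @return The score tibble (sample metadata plus components).
#' @exportS3Method generics::tidy
#' @export
tidy.gd_pca <- function(x, ...) {
  x$scores
}

#' One-row-per-component PCA summary
#'
#' @param x A `gd_pca`.
#' @param ... Unused.
#' @return Tibble (`component`, `explained_variance`, `cumulative`).
#' @exportS3Method generics::glance
#' @export
glance.gd_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$explained_variance),
                 explained_variance = x$explained_variance,
                 cumulative = cumsum(x$explained_variance))
}
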