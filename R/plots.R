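#' Stacked stage-composition bar plot
#'
#' @param composition Output of [stage_composition()] (fraction form).
#' @param x Grouping column on the x axis (default `meta_group` if
#'   present).
#' @return A ggplot object.
#' @export
plot_stage_composition <- function(composition, x = NULL) {
  x <- x %||% intersect(c("meta_group", "meta_subset"), names(composition))[1]
  if (is.na(x)) x <- "stage"
  yvar <- if ("fraction" %in% names(composition)) "fraction" else "n"
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = .data[[x]], y = .data[[yvar]],
                               fill = .data$stage)) +
    ggplot2::geom_col(position = if (yvar == "fraction") "stack" else "dodge") +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(y = yvar, fill = "stage") +
    ggplot2::theme_minimal()
}

#' Cluster mean-profile heat map
#'
#' @param profile Output of [cluster_profile()].
#' @return A ggplot object (clusters x markers tile map of mean
#'   intensity).
#' @export
plot_cluster_profile <- function(profile) {
  long <- profile |>
    tidyr::pivot_longer(dplyr::all_of(intersect(gd_markers(), names(profile))),
                        names_to = "marker", values_to = "mean_intensity")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$marker, y = factor(.data$cluster),
                               fill = .data$mean_intensity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(y = "cluster", fill = "mean") +
    ggplot2::theme_minimal()
}

#' 2-D embedding scatter plot
#'
#' Works for t-SNE ([embed_events()]), Isomap and diffusion-map
#' coordinates; the first two coordinate columns are used.
#'
#' @param coords Coordinate tibble.
#' @param colour Column to colour by (default `stage` if present).
#' @return A ggplot object.
#' @export
plot_embedding <- function(coords, colour = NULL) {
  dims <- grep("^(tsne|iso|dc)[12]$", names(coords), value = TRUE)[1:2]
  colour <- colour %||%
    intersect(c("stage", "cluster", "meta_true_stage"), names(coords))[1]
  p <- ggplot2::ggplot(coords,
                       ggplot2::aes(x = .data[[dims[1]]],
                                    y = .data[[dims[2]]]))
  if (!is.na(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data[[colour]])),
                                 size = 0.6, alpha = 0.8) +
      ggplot2::labs(colour = colour)
  } else {
    p <- p + ggplot2::geom_point(size = 0.6, alpha = 0.8)
  }
  p + ggplot2::theme_minimal()
}

#' Distance-matrix heat map
#'
#' @param object A `gd_dist` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gd_dist <- function(object, ...) {
  long <- tibble::as_tibble(unclass(object), rownames = "from") |>
    tidyr::pivot_longer(-"from", names_to = "to", values_to = "distance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$from, y = .data$to,
                                     fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$distance)), size = 2.5) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::theme_minimal()
}

#' Lineage-graph diagram
#'
#' Nodes positioned by classical MDS of graph distances, edges drawn with
#' their transcriptional-distance weights; leaves (candidate export stages)
#' and branch points are emphasised.
#'
#' @param object A `lineage_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lineage_graph <- function(object, ...) {
  g <- igraph::graph_from_data_frame(object$edges, directed = FALSE,
                                     vertices = object$nodes)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  xy <- cmdscale(d, k = 2)
  layout <- tibble::tibble(node = object$nodes, x = xy[, 1], y = xy[, 2],
                           role = dplyr::case_when(
                             object$nodes %in% object$branch_points ~ "branch point",
                             object$nodes %in% object$leaves ~ "leaf",
                             TRUE ~ "internal"))
  seg <- object$edges |>
    dplyr::left_join(layout, by = c("from" = "node")) |>
    dplyr::left_join(layout, by = c("to" = "node"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_to, yend = .data$y_to)) +
    ggplot2::geom_label(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$node,
                                     fill = .data$role)) +
    ggplot2::geom_text(data = seg,
                       ggplot2::aes(x = (.data$x + .data$x_to) / 2,
                                    y = (.data$y + .data$y_to) / 2,
                                    label = round(.data$weight)),
                       colour = "red3", size = 3, vjust = -0.5) +
    ggplot2::scale_fill_brewer(palette = "Pastel1") +
    ggplot2::theme_void()
}

#' Volcano plot of the marker screen
#'
#' @param screened Output of [screen_candidates()].
#' @return A ggplot object; candidates passing all filters are
#'   highlighted.
#' @export
plot_screen <- function(screened) {
  ggplot2::ggplot(screened,
                  ggplot2::aes(x = .data$log2_fc,
                               y = -log10(pmax(.data$q_value, 1e-300)),
                               colour = .data$pass)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "red3")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = "candidate") +
    ggplot2::theme_minimal()
}

#' Stage-accumulation fold-change plot
#'
#' @param folds Output of [fold_changes()].
#' @return A ggplot object (folds per stage and group, log2 y scale).
#' @export
plot_fold_changes <- function(folds) {
  ggplot2::ggplot(folds, ggplot2::aes(x = .data$stage, y = .data$fold,
                                      fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::theme_minimal()
}
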