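#' 2-D t-SNE embedding of events
#'
#' Uniformly downsamples `n_cells` events (seeded) and embeds the six
#' staging markers in two dimensions with Barnes-Hut t-SNE. Deterministic
#' given the seed.
#'
#' @param events Transformed event tibble.
#' @param n_cells Cells to embed (default 10000, capped at the number of
#'   events).
#' @param perplexity t-SNE perplexity; must be below `n_cells / 3`.
#' @param seed Integer seed.
#' @param markers Channels to embed.
#' @return Tibble with `tsne1`, `tsne2` and the sampled events' annotation
#'   columns.
#' @export
embed_events <- function(events, n_cells = 10000, perplexity = 30, seed = 1,
                         markers = gd_markers()) {
  require_transformed(events, "embed_events")
  n_cells <- min(n_cells, nrow(events))
  if (perplexity >= n_cells / 3) {
    abort(sprintf("perplexity must be below n_cells / 3 (= %.1f)", n_cells / 3))
  }
  local_seed(seed, {
    idx <- sort(sample.int(nrow(events), n_cells))
    x <- marker_matrix(events[idx, ], markers)
    fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity,
                        check_duplicates = FALSE, pca = FALSE,
                        num_threads = 1)
    out <- tibble::tibble(tsne1 = fit$Y[, 1], tsne2 = fit$Y[, 2])
    meta <- setdiff(names(events), markers)
    dplyr::bind_cols(out, events[idx, meta, drop = FALSE])
  })
}
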