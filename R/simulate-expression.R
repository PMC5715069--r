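#' Default designed developmental topology
#'
#' The 7-stage tree used by the expression simulator: A-B, B-C, B-D, D-F,
#' F-E, F-G. Stage B branches towards the naive pathway (C) and the
#' TCR-selected pathway (D), and F branches towards the two IFN-gamma
#' end points (E and G), so the leaves A, C, E and G mirror the root plus
#' the three export stages of the three-pathway model.
#'
#' @return Tibble of edges with columns `from`, `to`.
#' @export
default_expression_topology <- function() {
  tibble::tribble(
    ~from, ~to,
    "A", "B",
    "B", "C",
    "B", "D",
    "D", "F",
    "F", "E",
    "F", "G"
  )
}

#' Expression simulation configuration
#'
#' Population-level RNA-Seq emulation: negative-binomial counts per gene and
#' sample around designed per-stage mean profiles, then log2(CPM + 1). Mean
#' profiles are placed along the `topology` tree by giving each edge its own
#' disjoint block of `genes_per_edge` signature genes shifted by
#' `effect_size` log2 units on the child side of the edge; squared Euclidean
#' distance between stage means is then proportional to path length in the
#' tree, so adjacent stages are strictly closer than non-adjacent ones and
#' the designed tree is the unique minimum spanning tree of the noiseless
#' profiles.
#'
#' `signature_panels` optionally plants additional per-stage effects, e.g.
#' a naive-marker panel high in stage C: a named list, each element
#' `list(genes = <indices>, stage_effects = c(A = 0, ..., G = 0))`.
#'
#' @param topology Edge tibble over the 7 stages; must be a spanning tree.
#' @param n_genes Number of genes.
#' @param genes_per_edge Signature-block size per tree edge.
#' @param effect_size Log2 shift per edge block.
#' @param signature_panels Optional extra planted panels (see above).
#' @param baseline Baseline mean log2 expression.
#' @param dispersion Negative-binomial dispersion (0 gives the noiseless
#'   limit in which counts equal their expectations exactly).
#' @param n_replicates Replicates per population (default 2).
#' @param subsets Subset labels (default Vg1.1 and Vg2).
#' @param library_size Expected reads per sample.
#' @param seed Integer seed.
#' @return A list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(topology = default_expression_topology(),
                                  n_genes = 500,
                                  genes_per_edge = 30,
                                  effect_size = 2,
                                  signature_panels = NULL,
                                  baseline = 5,
                                  dispersion = 0.05,
                                  n_replicates = 2,
                                  subsets = c("Vg1.1", "Vg2"),
                                  library_size = 2e5,
                                  seed = 1) {
  stopifnot(n_genes >= 1, genes_per_edge >= 1, dispersion >= 0,
            n_replicates >= 1, library_size > 0)
  check_topology(topology)
  if (n_genes < nrow(topology) * genes_per_edge) {
    abort("n_genes too small for the requested signature blocks")
  }
  structure(
    list(topology = topology, n_genes = as.integer(n_genes),
         genes_per_edge = as.integer(genes_per_edge),
         effect_size = effect_size, signature_panels = signature_panels,
         baseline = baseline, dispersion = dispersion,
         n_replicates = as.integer(n_replicates), subsets = subsets,
         library_size = library_size, seed = as.integer(seed)),
    class = "expression_sim_config")
}

check_topology <- function(topology) {
  stopifnot(all(c("from", "to") %in% names(topology)))
  nodes <- union(topology$from, topology$to)
  if (!setequal(nodes, gd_stages())) {
    abort("topology must span exactly the 7 stages A-G")
  }
  if (nrow(topology) != 6) {
    abort("topology must be a tree over 7 stages (6 edges)")
  }
  g <- igraph::graph_from_data_frame(topology, directed = FALSE)
  if (igraph::components(g)$no != 1) {
    abort("topology is disconnected")
  }
  invisible(topology)
}

# Stages on the child side of each tree edge (the component containing `to`
# after deleting the edge).
edge_sides <- function(topology) {
  lapply(seq_len(nrow(topology)), function(i) {
    g <- igraph::graph_from_data_frame(topology[-i, ], directed = FALSE,
                                       vertices = gd_stages())
    comp <- igraph::components(g)$membership
    names(comp)[comp == comp[[topology$to[i]]]]
  })
}

# Designed mean log2 matrix (genes x stages) before normalization.
designed_log2_means <- function(config) {
  m <- matrix(config$baseline, config$n_genes, 7,
              dimnames = list(sprintf("gene_%03d", seq_len(config$n_genes)),
                              gd_stages()))
  sides <- edge_sides(config$topology)
  for (i in seq_along(sides)) {
    rows <- ((i - 1) * config$genes_per_edge + 1):(i * config$genes_per_edge)
    m[rows, sides[[i]]] <- m[rows, sides[[i]]] + config$effect_size
  }
  for (p in config$signature_panels) {
    fx <- p$stage_effects[gd_stages()]
    m[p$genes, ] <- m[p$genes, ] + rep(fx, each = length(p$genes))
  }
  m
}

#' Simulate a population-level expression matrix with known topology
#'
#' Generates `n_genes x (7 stages x subsets x replicates)` negative-binomial
#' counts around the designed stage means and returns both the raw counts
#' and log2(CPM + 1) values. The ground-truth `means` are the designed
#' profiles pushed through the same CPM normalisation at zero noise, so at
#' `dispersion = 0` the simulated values reproduce them exactly.
#'
#' @param config An [expression_sim_config()].
#' @return List with elements `log2` and `counts` (wide tibbles, `gene`
#'   column plus one column per sample), `samples` (tibble: `sample`,
#'   `subset`, `stage`, `replicate`), and `truth` (list: `topology`,
#'   `means` designed log2 CPM matrix genes x stages).
#' @examples
#' sim <- simulate_expression(expression_sim_config(n_genes = 200, seed = 3))
#' dim(sim$log2)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  m <- designed_log2_means(config)
  # designed relative abundances renormalised so CPMs sum to 1e6, then
  # scaled to the expected library size
  rel <- sweep(2^m - 1, 2, colSums(2^m - 1), "/")
  mu <- rel * config$library_size                # expected counts
  # ground truth: noiseless pass-through of the CPM normalisation
  truth_means <- log2(rel * 1e6 + 1)

  samples <- tidyr::expand_grid(subset = config$subsets, stage = gd_stages(),
                                replicate = seq_len(config$n_replicates))
  samples$sample <- sprintf("V%d%s_%d", match(samples$subset, config$subsets),
                            samples$stage, samples$replicate)
  samples <- samples[c("sample", "subset", "stage", "replicate")]

  counts <- local_seed(config$seed, {
    vapply(seq_len(nrow(samples)), function(j) {
      mu_j <- mu[, samples$stage[j]]
      if (config$dispersion == 0) {
        mu_j
      } else {
        rnbinom(length(mu_j), mu = mu_j, size = 1 / config$dispersion)
      }
    }, numeric(nrow(mu)))
  })
  colnames(counts) <- samples$sample
  rownames(counts) <- rownames(mu)

  log2_mat <- log2(sweep(counts, 2, colSums(counts), "/") * 1e6 + 1)
  wide <- function(x) {
    dplyr::bind_cols(tibble::tibble(gene = rownames(x)),
                     tibble::as_tibble(x))
  }
  list(log2 = wide(log2_mat), counts = wide(counts), samples = samples,
       truth = list(topology = config$topology, means = truth_means))
}
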