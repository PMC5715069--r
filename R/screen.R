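#' Library-size normalisation to log2 CPM
#'
#' `log2(1e6 * count / library_size + pseudocount)` per gene and sample,
#' with library size the column sum of counts. A stand-in for upstream
#' normalisation machinery: the screen expects an already comparable
#' log2-scale matrix.
#'
#' @param counts Wide count tibble (`gene` column plus sample columns) or a
#'   numeric matrix with gene rownames.
#' @param pseudocount Added inside the log (default 1, so zero counts map
#'   to 0).
#' @return Wide log2 expression tibble.
#' @export
normalize_log2 <- function(counts, pseudocount = 1) {
  if (is.data.frame(counts)) {
    genes <- counts$gene
    x <- as.matrix(counts[setdiff(names(counts), "gene")])
  } else {
    genes <- rownames(counts)
    x <- counts
  }
  if (any(x < 0)) abort("counts must be non-negative")
  lib <- colSums(x)
  if (any(lib <= 0)) {
    abort(sprintf("zero library size in sample(s): %s",
                  paste(colnames(x)[lib <= 0], collapse = ", ")))
  }
  out <- log2(sweep(x, 2, lib, "/") * 1e6 + pseudocount)
  dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(out))
}

#' Per-gene one-way ANOVA F-test between stage groups
#'
#' Vectorised parametric one-way ANOVA across all genes: F statistic with
#' (g - 1, n - g) degrees of freedom and its p-value, plus per-group mean
#' log2 expression and, for two groups, the log2 fold change
#' (second group minus first, in group-factor level order). For two groups
#' the F statistic equals the squared equal-variance t statistic.
#'
#' Genes with zero between- and within-group variance are flagged
#' `degenerate` and given `p = 1` by convention.
#'
#' @param expr Wide log2 expression tibble (`gene` plus samples).
#' @param groups Named character vector mapping sample name to group, or a
#'   factor/character vector in column order.
#' @return Tibble: `gene`, per-group `mean_*` columns, `log2_fc` (two-group
#'   case), `f_statistic`, `p_value`, `degenerate`.
#' @export
differential_f_test <- function(expr, groups) {
  genes <- expr$gene
  x <- as.matrix(expr[setdiff(names(expr), "gene")])
  if (!is.null(names(groups))) {
    groups <- groups[colnames(x)]
  }
  g <- factor(groups)
  if (nlevels(g) < 2) abort("at least 2 groups are required")
  n_per <- table(g)
  if (any(n_per < 2)) {
    abort(sprintf("every group needs >= 2 samples (got: %s)",
                  paste(sprintf("%s=%d", names(n_per), n_per), collapse = ", ")))
  }
  n <- ncol(x); k <- nlevels(g)

  means <- t(rowsum(t(x), g) / as.vector(n_per))      # genes x groups
  grand <- rowMeans(x)
  ssb <- as.vector((means - grand)^2 %*% as.vector(n_per))
  ssw <- rowSums((x - means[, as.integer(g)])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  degenerate <- ssb < 1e-300 & ssw < 1e-300
  f[degenerate] <- NA_real_
  p[degenerate] <- 1

  out <- tibble::tibble(gene = genes)
  for (j in seq_len(k)) {
    out[[paste0("mean_", levels(g)[j])]] <- means[, j]
  }
  if (k == 2) {
    out$log2_fc <- unname(means[, 2] - means[, 1])
  }
  out$f_statistic <- f
  out$p_value <- p
  out$degenerate <- degenerate
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p-values, with input
#' validation.
#'
#' @param pvals Numeric vector in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    abort("p-values must lie in [0, 1] and contain no NA")
  }
  p.adjust(pvals, method = "BH")
}

#' Surface-marker candidate filter
#'
#' The four-way screen for surface-marker candidates: a gene passes iff
#' `|log2FC| > fc` (or signed `log2FC > fc` with `signed = TRUE`), its
#' BH-adjusted p-value is below `q`, it is annotated with at least one
#' surface-expression GO term, and its maximal group mean log2 expression
#' exceeds `expr`. All inequalities are strict.
#'
#' @param de Result of [differential_f_test()] (two-group).
#' @param go Long annotation tibble (`gene`, `term`).
#' @param fc Fold-change threshold (log2 units, default 3).
#' @param q Adjusted-p threshold (default 0.05).
#' @param expr Expression threshold (log2 units, default 7).
#' @param surface_terms GO terms counting as surface expression.
#' @param signed Use signed instead of absolute fold change.
#' @return `de` with `q_value`, the four `pass_*` flags and `pass`; genes
#'   absent from `go` are treated as non-members and their count recorded
#'   in the `n_unannotated` attribute. Use `dplyr::filter(., pass)` for the
#'   candidate list.
#' @export
screen_candidates <- function(de, go, fc = 3, q = 0.05, expr = 7,
                              surface_terms = c("GO:0009986", "GO:0005886"),
                              signed = FALSE) {
  if (!"log2_fc" %in% names(de)) {
    abort("`de` must be a two-group screen with a log2_fc column")
  }
  surface_genes <- unique(go$gene[go$term %in% surface_terms])
  n_unannotated <- sum(!de$gene %in% unique(go$gene))
  if (n_unannotated > 0) {
    inform(sprintf("%d gene(s) absent from the GO map; treated as non-members",
                   n_unannotated))
  }
  mean_cols <- grep("^mean_", names(de), value = TRUE)
  out <- de |>
    dplyr::mutate(
      q_value = bh_adjust(.data$p_value),
      pass_fc = if (signed) .data$log2_fc > fc else abs(.data$log2_fc) > fc,
      pass_q = .data$q_value < q,
      pass_go = .data$gene %in% surface_genes,
      pass_expr = do.call(pmax, de[mean_cols]) > expr,
      pass = .data$pass_fc & .data$pass_q & .data$pass_go & .data$pass_expr)
  attr(out, "n_unannotated") <- n_unannotated
  out
}

#' Effector-signature z-score per population
#'
#' Scores a panel of signature genes across populations: each gene's mean
#' log2 expression is z-scored across populations (mean 0, sd 1) and the
#' panel score is the mean z per population. Zero-variance genes get z = 0
#' and are flagged; panel genes missing from the matrix are skipped with a
#' message.
#'
#' @param expr Wide log2 expression tibble.
#' @param samples Sample metadata tibble.
#' @param panel Character vector of panel gene ids.
#' @param subset Optional subset restriction.
#' @return Tibble (`population`, `score`); per-gene z-scores are in the
#'   `gene_z` attribute (long tibble), flagged genes in `flat_genes`.
#' @export
signature_score <- function(expr, samples, panel, subset = NULL) {
  prof <- population_profiles(expr, samples, subset)   # populations x genes
  missing <- setdiff(panel, colnames(prof))
  if (length(missing) > 0) {
    inform(sprintf("panel gene(s) not in matrix, skipped: %s",
                   paste(missing, collapse = ", ")))
  }
  panel <- intersect(panel, colnames(prof))
  if (length(panel) == 0) abort("no panel genes present in the matrix")
  sub <- prof[, panel, drop = FALSE]
  mu <- colMeans(sub)
  sdv <- apply(sub, 2, sd)
  flat <- colnames(sub)[sdv < 1e-300]
  sdv[sdv < 1e-300] <- 1
  z <- sweep(sweep(sub, 2, mu), 2, sdv, "/")
  z[, flat] <- 0
  out <- tibble::tibble(population = rownames(prof),
                        score = unname(rowMeans(z)))
  attr(out, "gene_z") <- tibble::as_tibble(z) |>
    dplyr::mutate(population = rownames(prof), .before = 1) |>
    tidyr::pivot_longer(-"population", names_to = "gene", values_to = "z")
  attr(out, "flat_genes") <- flat
  out
}

#' Construct the planted screen validation fixture
#'
#' A 100-gene two-group expression set in which exactly `n_pass` genes
#' satisfy all four candidate-filter conditions and the remaining genes
#' each fail exactly one (low fold change, non-significant p, no surface
#' GO term, or low expression, in rotation). Values are deterministic
#' patterns plus a small seeded jitter that cannot flip any condition.
#'
#' @param n_pass Genes passing all conditions (default 5).
#' @param n_fail Genes failing exactly one condition (default 95).
#' @param n_rep Samples per group (default 3).
#' @param seed Integer seed.
#' @return List: `expr` (wide log2 tibble), `groups` (named vector), `go`
#'   (long tibble), `truth_pass` (character vector of planted passers).
#' @export
simulate_screen_fixture <- function(n_pass = 5, n_fail = 95, n_rep = 3,
                                    seed = 1) {
  n <- n_pass + n_fail
  genes <- sprintf("gene_%03d", seq_len(n))
  fail_mode <- rep(c("fc", "p", "go", "expr"), length.out = n_fail)
  class_of <- c(rep("pass", n_pass), fail_mode)

  base <- matrix(NA_real_, n, 2 * n_rep,
                 dimnames = list(genes, c(paste0("lo_", seq_len(n_rep)),
                                          paste0("hi_", seq_len(n_rep)))))
  go_member <- rep(TRUE, n)
  for (i in seq_len(n)) {
    cls <- class_of[i]
    if (cls == "pass") {          # fc 4, tight, expressed, annotated
      base[i, ] <- c(rep(5, n_rep), rep(9, n_rep))
    } else if (cls == "fc") {     # fc 2 only
      base[i, ] <- c(rep(7, n_rep), rep(9, n_rep))
    } else if (cls == "p") {      # fc 4 but huge within-group spread
      base[i, ] <- c(2, 6, 10, 6, 10, 14)[seq_len(2 * n_rep)]
    } else if (cls == "go") {     # would pass but unannotated
      base[i, ] <- c(rep(5, n_rep), rep(9, n_rep))
      go_member[i] <- FALSE
    } else {                      # expr: fc 4 but low expression
      base[i, ] <- c(rep(1, n_rep), rep(5, n_rep))
    }
  }
  jitter <- local_seed(seed, matrix(rnorm(length(base), sd = 0.01),
                                    nrow(base)))
  jitter[class_of == "p", ] <- 0    # keep the non-significant class exact
  x <- base + jitter

  go <- tibble::tibble(
    gene = genes,
    term = ifelse(go_member, "GO:0009986", "GO:0005575"))
  expr <- dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(x))
  groups <- setNames(rep(c("CD73neg", "CD73pos"), each = n_rep), colnames(x))
  list(expr = expr, groups = groups, go = go,
       truth_pass = genes[class_of == "pass"])
}
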