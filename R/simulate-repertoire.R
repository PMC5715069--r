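#' Repertoire simulation configuration
#'
#' Clonotype-table emulation with planted ground truth: clone sizes follow a
#' power law, chosen CDR3 amino-acid motifs are planted at exact expected
#' read fractions among in-frame reads, V-segment usage is matched at exact
#' expected read mass, and a set fraction of reads is out of frame (stop
#' `*` or frameshift `_` in the amino-acid field).
#'
#' @param n_clones Number of distinct clonotypes.
#' @param clone_size_law Power-law exponent for clone weights
#'   (`w_i ~ i^-exponent`).
#' @param planted_motifs Named numeric vector, motif string to target read
#'   fraction among in-frame reads; fractions must sum to at most 1.
#' @param v_usage Named fractions over V segments, summing to 1.
#' @param out_of_frame_fraction Expected out-of-frame read fraction.
#' @param total_reads Total reads drawn (multinomial).
#' @param locus Library locus label (`"TRD"` or `"TRG"`).
#' @param seed Integer seed.
#' @return A list of class `repertoire_sim_config`.
#' @export
repertoire_sim_config <- function(n_clones = 200,
                                  clone_size_law = 1,
                                  planted_motifs = NULL,
                                  v_usage = c(TRDV5 = 0.4, TRDV4 = 0.35,
                                              `TRDV6.3` = 0.25),
                                  out_of_frame_fraction = 0.1,
                                  total_reads = 10000,
                                  locus = "TRD",
                                  seed = 1) {
  stopifnot(n_clones >= 2, total_reads >= 1,
            out_of_frame_fraction >= 0, out_of_frame_fraction < 1)
  check_fractions(v_usage, "v_usage")
  planted_motifs <- planted_motifs %||% numeric(0)
  if (length(planted_motifs) > 0) {
    if (is.null(names(planted_motifs)) || any(!nzchar(names(planted_motifs)))) {
      abort("planted_motifs must be named by motif string")
    }
    if (any(planted_motifs < 0) || sum(planted_motifs) > 1) {
      abort("planted motif fractions must be non-negative and sum to at most 1")
    }
  }
  structure(
    list(n_clones = as.integer(n_clones), clone_size_law = clone_size_law,
         planted_motifs = planted_motifs, v_usage = v_usage,
         out_of_frame_fraction = out_of_frame_fraction,
         total_reads = as.integer(total_reads), locus = locus,
         seed = as.integer(seed)),
    class = "repertoire_sim_config")
}

aa_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_cdr3 <- function(n, len_range = 8:16) {
  lens <- sample(len_range, n, replace = TRUE)
  vapply(lens, function(l) {
    paste0("C", paste(sample(aa_alphabet(), l - 2, replace = TRUE),
                      collapse = ""), "F")
  }, character(1))
}

random_nt <- function(n_codons) {
  vapply(n_codons, function(k) {
    paste(sample(c("A", "C", "G", "T"), 3 * k, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a clonotype table with planted motifs and V usage
#'
#' Clone read-probabilities are built so that designed quantities hold in
#' expectation exactly: each planted motif's clones carry exactly its target
#' fraction of the in-frame mass, out-of-frame clones carry exactly
#' `out_of_frame_fraction` of the total mass, and in-frame clones are
#' assigned to V segments by a largest-first greedy fill so that per-segment
#' read mass matches `v_usage` up to one small clone. Read counts are then
#' one multinomial draw of `total_reads`, so measured fractions deviate from
#' targets only by multinomial sampling error. Clones drawn to zero are
#' dropped.
#'
#' @param config A [repertoire_sim_config()].
#' @return List with `table` (clonotype tibble: `count`, `freq`, `cdr3nt`,
#'   `cdr3aa`, `v`, `d`, `j`) and `truth` (designed motif fractions, V
#'   usage, out-of-frame fraction and clone probabilities). The table
#'   carries `locus` as an attribute.
#' @examples
#' sim <- simulate_clonotypes(repertoire_sim_config(
#'   planted_motifs = c(CALWELGF = 0.5), total_reads = 1200, seed = 2))
#' motif_fraction(filter_in_frame(sim$table), "CALWELGF")
#' @export
simulate_clonotypes <- function(config) {
  stopifnot(inherits(config, "repertoire_sim_config"))
  local_seed(config$seed, {
    n <- config$n_clones
    motifs <- config$planted_motifs
    oof <- config$out_of_frame_fraction

    # partition clones into out-of-frame / one group per motif / background
    masses <- c(oof = oof,
                setNames(as.numeric(motifs) * (1 - oof), names(motifs)),
                background = (1 - sum(motifs)) * (1 - oof))
    masses <- masses[masses > 0]
    n_per <- allocate_counts(n, masses / sum(masses))
    n_per[n_per == 0] <- 1L
    group <- rep(names(n_per), n_per)[seq_len(max(n, sum(n_per)))]
    group <- group[!is.na(group)]
    n <- length(group)

    # power-law weights renormalised within each group to its target mass
    w <- (seq_len(n))^(-config$clone_size_law)
    p <- numeric(n)
    for (g in names(n_per)) {
      i <- which(group == g)
      p[i] <- w[i] / sum(w[i]) * masses[[g]]
    }
    p <- p / sum(p)

    # sequences
    aa <- random_cdr3(n)
    for (m in names(motifs)) {
      i <- which(group == m)
      aa[i] <- vapply(i, function(j) {
        base <- aa[j]
        paste0("C", m, substr(base, 2 + nchar(m), nchar(base)))
      }, character(1))
      aa[i] <- paste0(substr(aa[i], 1, nchar(aa[i]) - 1), "F")
    }
    nt <- random_nt(nchar(aa))
    is_oof <- group == "oof"
    if (any(is_oof)) {
      # half stop-containing, half frameshifted
      stop_half <- is_oof & (seq_len(n) %% 2 == 0)
      aa[stop_half] <- vapply(aa[stop_half], function(s) {
        k <- sample(2:(nchar(s) - 1), 1)
        paste0(substr(s, 1, k - 1), "*", substr(s, k + 1, nchar(s)))
      }, character(1))
      shift <- is_oof & !stop_half
      aa[shift] <- paste0(aa[shift], "_")
      nt[shift] <- paste0(nt[shift], "A")  # length not divisible by 3
    }

    # V assignment: greedy largest-first fill of per-segment mass deficits
    v <- rep(NA_character_, n)
    inf <- which(!is_oof)
    deficit <- config$v_usage * sum(p[inf])
    for (i in inf[order(-p[inf])]) {
      g <- names(deficit)[which.max(deficit)]
      v[i] <- g
      deficit[g] <- deficit[g] - p[i]
    }
    v[is_oof] <- sample(names(config$v_usage), sum(is_oof), replace = TRUE,
                        prob = config$v_usage)

    counts <- as.integer(rmultinom(1, config$total_reads, p))
    keep <- counts > 0
    tbl <- tibble::tibble(
      count = counts[keep],
      freq = counts[keep] / sum(counts[keep]),
      cdr3nt = nt[keep],
      cdr3aa = aa[keep],
      v = v[keep],
      d = sample(c("TRDD1", "TRDD2"), sum(keep), replace = TRUE),
      j = sample(c("TRDJ1", "TRDJ2"), sum(keep), replace = TRUE)
    )
    tbl <- dplyr::arrange(tbl, dplyr::desc(.data$count))
    attr(tbl, "locus") <- config$locus
    list(table = tbl,
         truth = list(motif_fractions = motifs, v_usage = config$v_usage,
                      out_of_frame_fraction = oof,
                      clone_probabilities = p[keep]))
  })
}

#' Simulate a gene-to-GO annotation map
#'
#' Assigns each gene either at least one of the given surface-expression
#' terms (with probability `member_fraction`) or a non-surface background
#' term, deterministically given the seed. Every gene appears in the map.
#'
#' @param genes Character vector of gene identifiers.
#' @param surface_terms Terms marking surface expression (defaults to the
#'   cell-surface and plasma-membrane GO terms used by the marker screen).
#' @param member_fraction Probability that a gene is a surface-term member.
#' @param seed Integer seed.
#' @return Long tibble with columns `gene`, `term`; one or two rows per
#'   gene.
#' @export
simulate_go_annotation <- function(genes,
                                   surface_terms = c("GO:0009986", "GO:0005886"),
                                   member_fraction = 0.3,
                                   seed = 1) {
  stopifnot(member_fraction >= 0, member_fraction <= 1, length(genes) > 0)
  background <- c("GO:0005634", "GO:0005739", "GO:0005829")
  local_seed(seed, {
    member <- runif(length(genes)) < member_fraction
    purrr::map2_dfr(genes, member, function(g, m) {
      if (m) {
        k <- sample(1:2, 1)
        tibble::tibble(gene = g, term = sample(surface_terms, k))
      } else {
        tibble::tibble(gene = g, term = sample(background, 1))
      }
    })
  })
}
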