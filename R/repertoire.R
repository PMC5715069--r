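#' Read a clonotype table
#'
#' Tab-separated clonotype table with a header containing at least `count`,
#' `freq`, `cdr3nt`, `cdr3aa`, `v`, `j` (a `d` column is optional; other
#' columns are preserved). Frequencies are recomputed from counts; a stored
#' `freq` column disagreeing by more than 1e-6 triggers a warning.
#'
#' @param path TSV path.
#' @return Clonotype tibble.
#' @export
read_clonotypes <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("count", "freq", "cdr3nt", "cdr3aa", "v", "j")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("clonotype table %s lacks column(s): %s", basename(path),
                  paste(missing, collapse = ", ")))
  }
  bad <- which(is.na(tbl$count) | tbl$count < 1 |
                 is.na(tbl$cdr3nt) | is.na(tbl$cdr3aa))
  if (length(bad) > 0) {
    abort(sprintf("malformed clonotype row at line %d of %s",
                  bad[1] + 1L, basename(path)))
  }
  recomputed <- tbl$count / sum(tbl$count)
  if (any(abs(recomputed - tbl$freq) > 1e-6, na.rm = TRUE) ||
      any(is.na(tbl$freq))) {
    warn("freq column inconsistent with counts; recomputed")
  }
  tbl$freq <- recomputed
  tbl
}

#' Write a clonotype table
#'
#' @param table Clonotype tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clonotypes <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Keep functionally recombined (in-frame) clonotypes
#'
#' Retains rows whose CDR3 nucleotide length is divisible by 3 and whose
#' amino-acid sequence contains neither a stop (`*`) nor a frameshift
#' (`_`), the standard clonotype-tool convention for removing out-of-frame
#' transcripts. Frequencies are renormalised.
#'
#' @param table Clonotype tibble.
#' @return Filtered tibble; if nothing survives, an empty tibble flagged
#'   with attribute `empty = TRUE`.
#' @export
filter_in_frame <- function(table) {
  keep <- nchar(table$cdr3nt) %% 3 == 0 &
    !grepl("[*_]", table$cdr3aa)
  out <- table[keep, ]
  if (nrow(out) == 0) {
    warn("no in-frame clonotypes remain")
    attr(out, "empty") <- TRUE
    return(out)
  }
  out$freq <- out$count / sum(out$count)
  out
}

#' Downsample a library to a fixed read depth
#'
#' Hypergeometric sampling of reads without replacement down to exactly
#' `n_target` total reads (the depth-equalisation step applied before
#' comparing libraries). Clones drawn to zero are removed; deterministic
#' given the seed. Libraries below the target depth raise an error, as an
#' under-depth library must be excluded rather than padded.
#'
#' @param table Clonotype tibble.
#' @param n_target Target total reads (e.g. 1200 for CDR3-delta, 724 for
#'   CDR3-gamma libraries).
#' @param seed Integer seed.
#' @return Downsampled tibble with `sum(count) == n_target`.
#' @export
downsample_reads <- function(table, n_target, seed = 1) {
  total <- sum(table$count)
  if (total < n_target) {
    abort(sprintf(
      "library has %d reads, below the target depth %d; exclude it",
      total, n_target))
  }
  if (total == n_target) {
    return(table)
  }
  new_counts <- local_seed(seed, {
    reads <- rep(seq_len(nrow(table)), table$count)
    tabulate(sample(reads, n_target), nbins = nrow(table))
  })
  out <- table[new_counts > 0, ]
  out$count <- new_counts[new_counts > 0]
  out$freq <- out$count / sum(out$count)
  out
}

#' Read fraction matching a CDR3 amino-acid motif
#'
#' Fraction of reads whose CDR3 amino-acid sequence matches the given
#' regular expression (case-insensitive), over all reads in the (already
#' frame-filtered, locus-restricted) table.
#'
#' @param table Clonotype tibble.
#' @param pattern Regular expression over the amino-acid alphabet.
#' @return Fraction in \[0, 1\].
#' @examples
#' tbl <- tibble::tibble(count = c(3, 7), freq = c(0.3, 0.7),
#'                       cdr3nt = c("TGT", "TGC"),
#'                       cdr3aa = c("CALWELF", "CGGGF"),
#'                       v = "TRDV5", j = "TRDJ1")
#' motif_fraction(tbl, "ALWEL")  # 0.3
#' @export
motif_fraction <- function(table, pattern) {
  hit <- tryCatch(
    grepl(pattern, table$cdr3aa, ignore.case = TRUE, perl = TRUE),
    error = function(e) abort(sprintf("invalid motif pattern '%s': %s",
                                      pattern, conditionMessage(e))),
    warning = function(w) abort(sprintf("invalid motif pattern '%s'", pattern)))
  sum(table$count[hit]) / sum(table$count)
}

#' Read fractions for a set of named motifs
#'
#' @param table Clonotype tibble.
#' @param motifs Named character vector of motif regular expressions.
#' @return Tibble (`motif`, `pattern`, `fraction`).
#' @export
motif_fractions <- function(table, motifs) {
  tibble::tibble(
    motif = names(motifs),
    pattern = unname(motifs),
    fraction = vapply(unname(motifs), function(p) motif_fraction(table, p),
                      numeric(1), USE.NAMES = FALSE))
}

#' V- or J-segment usage by read fraction
#'
#' @param table Clonotype tibble (frame-filtered).
#' @param level `"v"` or `"j"`.
#' @return Tibble (`segment`, `reads`, `fraction`); fractions sum to 1.
#' @export
segment_usage <- function(table, level = c("v", "j")) {
  level <- match.arg(level)
  table |>
    dplyr::group_by(segment = .data[[level]]) |>
    dplyr::summarise(reads = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(fraction = .data$reads / sum(.data$reads)) |>
    dplyr::arrange(dplyr::desc(.data$fraction))
}

#' Inverse Simpson diversity of a clonotype table
#'
#' `D = 1 / sum(p_i^2)` over clone read fractions: the effective number of
#' equally abundant clones, bounded by 1 and the clone count. The default
#' is the plug-in estimator; `unbiased = TRUE` uses the finite-sample
#' unbiased form `n(n-1) / sum(c_i (c_i - 1))`.
#'
#' @param table Clonotype tibble (non-empty).
#' @param unbiased Use the unbiased estimator.
#' @return Diversity value.
#' @examples
#' tbl <- tibble::tibble(count = c(2, 1, 1))
#' inverse_simpson(tbl)  # 1 / 0.375
#' @export
inverse_simpson <- function(table, unbiased = FALSE) {
  if (nrow(table) == 0) abort("cannot compute diversity of an empty table")
  n <- sum(table$count)
  if (unbiased) {
    denom <- sum(table$count * (table$count - 1))
    if (denom == 0) {
      abort("unbiased estimator undefined when every clone has one read")
    }
    return(n * (n - 1) / denom)
  }
  p <- table$count / n
  1 / sum(p^2)
}
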