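#' Default stage signature table
#'
#' Marker positivity patterns defining the seven developmental stages A-G of
#' gamma-delta thymocytes. The scheme reflects the published staging model:
#' the earliest CD371+CD73- progenitors split on CD25 (A vs B), CD371- cells
#' without CD200 are stage C, CD200 induction marks D, CD73 acquisition with
#' or without CD117 marks E or F, and CD24 downregulation marks G.
#'
#' States are `"+"`, `"-"`, `"hi"`, `"lo"` or `"any"`; `"hi"` gates like
#' `"+"` and `"lo"` like `"-"` against the per-marker threshold.
#'
#' The attached `"gating_order"` attribute gives the decision-tree order used
#' by [assign_stages()]: CD24-lo events are G; else CD73+ events are E
#' (CD117+) or F (CD117-); else CD200+ events are D; else CD371+ events are
#' A (CD25+) or B (CD25-); everything else is C. The last stage in the order
#' acts as the fall-through.
#'
#' @param signatures Optional replacement table with the same columns; it is
#'   validated before use.
#' @return A tibble with columns `stage` and one column per marker.
#' @examples
#' stage_signatures()
#' @export
stage_signatures <- function(signatures = NULL) {
  if (is.null(signatures)) {
    signatures <- tibble::tribble(
      ~stage, ~CD24, ~CD25, ~CD73, ~CD117, ~CD200, ~CD371,
      "A",    "hi",  "+",   "-",   "any",  "-",    "+",
      "B",    "hi",  "-",   "-",   "any",  "-",    "+",
      "C",    "hi",  "-",   "-",   "any",  "-",    "-",
      "D",    "hi",  "any", "-",   "any",  "+",    "any",
      "E",    "hi",  "any", "+",   "+",    "any",  "any",
      "F",    "hi",  "any", "+",   "-",    "any",  "any",
      "G",    "lo",  "any", "any", "any",  "any",  "any"
    )
    attr(signatures, "gating_order") <- c("G", "E", "F", "D", "A", "B", "C")
  }
  validate_signatures(signatures)
}

# Validate a signature table: all 7 stages present, legal states, and the
# signature set unambiguous -- over all 2^6 positivity patterns no pattern
# satisfies two stage signatures, and no stage is unreachable under the
# gating order.
validate_signatures <- function(signatures) {
  markers <- gd_markers()
  missing <- setdiff(c("stage", markers), names(signatures))
  if (length(missing) > 0) {
    abort(sprintf("signature table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (!setequal(signatures$stage, gd_stages())) {
    abort("signature table must define exactly the stages A-G")
  }
  states <- unlist(signatures[markers])
  bad <- setdiff(unique(states), c("+", "-", "hi", "lo", "any"))
  if (length(bad) > 0) {
    abort(sprintf("unknown marker state(s): %s", paste(bad, collapse = ", ")))
  }
  order <- attr(signatures, "gating_order") %||% signatures$stage
  if (!setequal(order, signatures$stage)) {
    abort("gating_order must be a permutation of the stages")
  }

  # enumerate every binary positivity pattern
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(markers))))
  colnames(patterns) <- markers
  sat <- vapply(signatures$stage, function(s) {
    signature_satisfied(patterns, signatures[signatures$stage == s, ])
  }, logical(nrow(patterns)))
  n_hit <- rowSums(sat)
  # the fall-through stage (last in gating order) may legitimately catch
  # patterns matching no explicit signature
  multi <- which(n_hit >= 2)
  if (length(multi) > 0) {
    abort(sprintf(
      "ambiguous signature table: positivity pattern %s satisfies stages %s",
      paste(markers[patterns[multi[1], ]], collapse = "/"),
      paste(signatures$stage[sat[multi[1], ]], collapse = ", ")))
  }
  # every stage must be reachable as a first match
  reach <- colSums(sat) > 0
  if (any(!reach)) {
    abort(sprintf("stage(s) %s are unreachable under the gating order",
                  paste(signatures$stage[!reach], collapse = ", ")))
  }
  attr(signatures, "gating_order") <- order
  signatures
}

# positivity: logical matrix (rows x markers). sig_row: one signature row.
signature_satisfied <- function(positivity, sig_row) {
  ok <- rep(TRUE, nrow(positivity))
  for (m in gd_markers()) {
    st <- sig_row[[m]]
    if (st %in% c("+", "hi")) ok <- ok & positivity[, m]
    if (st %in% c("-", "lo")) ok <- ok & !positivity[, m]
  }
  ok
}

# First-match stage per row of a positivity matrix, following the gating
# order; rows matching nothing fall through to the last stage in the order.
gate_patterns <- function(positivity, signatures) {
  order <- attr(signatures, "gating_order")
  out <- rep(NA_character_, nrow(positivity))
  for (s in order) {
    hit <- is.na(out) &
      signature_satisfied(positivity, signatures[signatures$stage == s, ])
    out[hit] <- s
  }
  out[is.na(out)] <- order[length(order)]
  out
}
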