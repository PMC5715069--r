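#' Fit per-marker positivity thresholds
#'
#' Three methods:
#' * `"valley"`: kernel-density estimate per marker; the threshold is the
#'   density minimum between the two highest modes. Markers without two
#'   detectable modes raise an error advising a manual threshold.
#' * `"quantile"`: the `q` quantile of a labelled negative-control
#'   population (`negatives`: a logical row index into `events` or a
#'   separate event tibble on the same scale).
#' * `"manual"`: user-supplied thresholds passed through unchanged.
#'
#' @param events Transformed event tibble with at least 100 rows.
#' @param method `"valley"`, `"quantile"` or `"manual"`.
#' @param markers Markers to threshold.
#' @param thresholds Named numeric vector (manual method).
#' @param negatives Negative-control events (quantile method).
#' @param q Quantile for the quantile method (default 0.999).
#' @return Tibble with columns `marker`, `threshold`, `method`.
#' @export
fit_positivity_thresholds <- function(events,
                                      method = c("valley", "quantile", "manual"),
                                      markers = gd_markers(),
                                      thresholds = NULL,
                                      negatives = NULL,
                                      q = 0.999) {
  method <- match.arg(method)
  if (method == "manual") {
    if (is.null(thresholds) || !all(markers %in% names(thresholds))) {
      abort("manual method requires a named `thresholds` value per marker")
    }
    return(tibble::tibble(marker = markers,
                          threshold = unname(thresholds[markers]),
                          method = "manual"))
  }
  require_transformed(events, "fit_positivity_thresholds")
  if (nrow(events) < 100) {
    abort("at least 100 events are required to fit thresholds")
  }
  if (method == "quantile") {
    if (is.null(negatives)) {
      abort("quantile method requires `negatives` (logical index or event tibble)")
    }
    neg <- if (is.logical(negatives)) events[negatives, ] else negatives
    thr <- vapply(markers, function(m) {
      unname(quantile(neg[[m]], q))
    }, numeric(1))
    return(tibble::tibble(marker = markers, threshold = unname(thr),
                          method = "quantile"))
  }
  thr <- vapply(markers, function(m) valley_threshold(events[[m]], m),
                numeric(1))
  tibble::tibble(marker = markers, threshold = unname(thr), method = "valley")
}

# Density minimum between the two highest modes of a KDE.
valley_threshold <- function(x, marker = "marker") {
  d <- density(x, n = 512)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  if (length(peaks) < 2) {
    abort(sprintf(
      "marker %s looks unimodal; use a manual threshold for it", marker))
  }
  top2 <- sort(peaks[order(-y[peaks])][1:2])
  between <- seq(top2[1], top2[2])
  d$x[between[which.min(y[between])]]
}

#' Assign each event to a developmental stage
#'
#' Thresholds each marker and gates events through the stage decision tree
#' (see [stage_signatures()]): CD24-lo events are G; else CD73+ events are
#' E (CD117+) or F (CD117-); else CD200+ events are D; else CD371+ events
#' are A (CD25+) or B (CD25-); everything else is C. The assignment is a
#' total partition: every event receives exactly one stage.
#'
#' @param events Transformed event tibble.
#' @param thresholds Tibble from [fit_positivity_thresholds()].
#' @param signatures Signature table (default [stage_signatures()]).
#' @return `events` with an added `stage` column (character, levels A-G).
#' @export
assign_stages <- function(events, thresholds, signatures = stage_signatures()) {
  require_transformed(events, "assign_stages")
  signatures <- validate_signatures(signatures)
  markers <- gd_markers()
  thr <- setNames(thresholds$threshold, thresholds$marker)
  if (!all(markers %in% names(thr)) || any(!is.finite(thr[markers]))) {
    abort("thresholds must give one finite value per staging marker")
  }
  x <- marker_matrix(events, markers)
  positivity <- sweep(x, 2, thr[markers], ">")
  events$stage <- gate_patterns(positivity, signatures)
  events
}

#' Stage composition by group and subset
#'
#' Tabulates stage counts or within-group fractions, crossed by any event
#' annotation columns. Fractions sum to 1 within each group combination;
#' absent stages appear as zero rows.
#'
#' @param events Event tibble with a `stage` column.
#' @param by Annotation columns to cross with stage (defaults to the
#'   `meta_group` and `meta_subset` columns where present).
#' @param as `"fraction"` or `"count"`.
#' @return Tibble with `stage`, the `by` columns, and `n` and/or `fraction`.
#' @export
stage_composition <- function(events, by = NULL, as = c("fraction", "count")) {
  as <- match.arg(as)
  if (!"stage" %in% names(events)) {
    abort("events must carry a `stage` column; run assign_stages() first")
  }
  by <- by %||% intersect(c("meta_group", "meta_subset"), names(events))
  out <- events |>
    dplyr::count(dplyr::across(dplyr::all_of(c(by, "stage")))) |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(by)),
      stage = gd_stages(),
      fill = list(n = 0L))
  if (as == "fraction") {
    out <- out |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
    empty <- out |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(total = sum(.data$n), .groups = "drop") |>
      dplyr::filter(.data$total == 0)
    if (nrow(empty) > 0) {
      warn("some group combinations contain no events; their fractions are NaN")
    }
  }
  dplyr::arrange(out, dplyr::across(dplyr::all_of(c(by, "stage"))))
}
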