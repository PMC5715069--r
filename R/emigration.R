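#' Stage-wise fold changes under emigration blockade
#'
#' Fold change of per-stage cell counts in each treatment group relative to
#' the reference group. Replicate counts (e.g. per mouse) are averaged per
#' stage and group before folds are taken.
#'
#' @param counts Long tibble with columns `stage`, `group`, `count` (an
#'   optional `replicate` column is averaged over). [stage_composition()]
#'   output works directly with `count_col = "n"`.
#' @param reference Reference group label (default `"untreated"`).
#' @param count_col Name of the count column.
#' @return Tibble (`stage`, `group`, `count`, `fold`) including the
#'   reference group (fold 1).
#' @export
fold_changes <- function(counts, reference = "untreated", count_col = "count") {
  need <- c("stage", "group", count_col)
  missing <- setdiff(need, names(counts))
  if (length(missing) > 0) {
    abort(sprintf("counts lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!reference %in% counts$group) {
    abort(sprintf("reference group '%s' absent from counts", reference))
  }
  agg <- counts |>
    dplyr::group_by(.data$stage, .data$group) |>
    dplyr::summarise(count = mean(.data[[count_col]]), .groups = "drop")
  ref <- agg |>
    dplyr::filter(.data$group == reference) |>
    dplyr::select("stage", ref_count = "count")
  if (any(ref$ref_count <= 0)) {
    abort(paste("zero reference count for stage(s):",
                paste(ref$stage[ref$ref_count <= 0], collapse = ", "),
                "- add a pseudocount or exclude them"))
  }
  agg |>
    dplyr::left_join(ref, by = "stage") |>
    dplyr::mutate(fold = .data$count / .data$ref_count) |>
    dplyr::select("stage", "group", "count", "fold") |>
    dplyr::arrange(.data$stage, .data$group)
}

#' Call terminal (export-ready) stages from accumulation folds
#'
#' A stage is called terminal when blocking thymic emigration makes it both
#' accumulate strongly (`fold at the final time point >= min_fold`) and
#' keep accumulating between the intermediate and final time points
#' (`fold_final / fold_mid >= min_growth_ratio`). These two criteria
#' separate stages that "continue to accumulate" from stages that rise
#' early and stall.
#'
#' @param folds Output of [fold_changes()].
#' @param final_group Final-time-point group (default `"FTY720_10d"`).
#' @param mid_group Intermediate group (default `"FTY720_5d"`); if absent
#'   the growth-ratio criterion is skipped and flagged.
#' @param min_fold Minimum final fold (default 3).
#' @param min_growth_ratio Minimum sustained-growth ratio (default 1.5).
#' @return Tibble (`stage`, `fold_mid`, `fold_final`, `growth_ratio`,
#'   `terminal`); the `ratio_skipped` attribute records a missing mid
#'   group.
#' @export
call_terminal_stages <- function(folds, final_group = "FTY720_10d",
                                 mid_group = "FTY720_5d", min_fold = 3,
                                 min_growth_ratio = 1.5) {
  if (!final_group %in% folds$group) {
    abort(sprintf("final group '%s' absent from folds", final_group))
  }
  fin <- folds |>
    dplyr::filter(.data$group == final_group) |>
    dplyr::select("stage", fold_final = "fold")
  ratio_skipped <- !mid_group %in% folds$group
  if (ratio_skipped) {
    warn(sprintf("group '%s' absent; growth-ratio criterion skipped", mid_group))
    out <- fin |>
      dplyr::mutate(fold_mid = NA_real_, growth_ratio = NA_real_,
                    terminal = .data$fold_final >= min_fold)
  } else {
    mid <- folds |>
      dplyr::filter(.data$group == mid_group) |>
      dplyr::select("stage", fold_mid = "fold")
    out <- fin |>
      dplyr::left_join(mid, by = "stage") |>
      dplyr::mutate(growth_ratio = .data$fold_final / .data$fold_mid,
                    terminal = .data$fold_final >= min_fold &
                      .data$growth_ratio >= min_growth_ratio)
  }
  out <- out |>
    dplyr::select("stage", "fold_mid", "fold_final", "growth_ratio",
                  "terminal") |>
    dplyr::arrange(.data$stage)
  attr(out, "ratio_skipped") <- ratio_skipped
  out
}

#' Terminal stage set
#'
#' @param called Output of [call_terminal_stages()].
#' @return Sorted character vector of terminal stages.
#' @export
terminal_stages <- function(called) {
  sort(called$stage[called$terminal])
}

#' Two-sample Student's t test
#'
#' Equal-variance two-sided t test (pooled variance, the convention used
#' for all group comparisons here): df `n_x + n_y - 2` unpaired, `n - 1`
#' paired.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @param paired Paired test (requires equal lengths).
#' @return Tibble (`t`, `df`, `p_value`, `mean_x`, `mean_y`).
#' @examples
#' student_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
student_t_test <- function(x, y, paired = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    abort("each sample needs at least 2 observations")
  }
  if (paired && length(x) != length(y)) {
    abort("paired test requires equal-length samples")
  }
  pooled_var <- if (paired) var(x - y) else {
    ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
  }
  if (pooled_var <= 0) {
    abort("zero pooled variance; the t statistic is undefined")
  }
  fit <- t.test(x, y, var.equal = TRUE, paired = paired)
  tibble::tibble(t = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p_value = fit$p.value,
                 mean_x = mean(x), mean_y = mean(y))
}
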