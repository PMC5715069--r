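#' Default per-stage marker intensity model
#'
#' Two-component log-normal intensity model on the raw fluorescence scale:
#' every stage x marker cell is one of four components (`neg`, `pos`, `hi`,
#' `lo`). Component locations/spreads are chosen so that, after the arcsinh
#' transform, positive and negative components sit more than four standard
#' deviations apart, giving an essentially noiseless staging problem at the
#' component level while retaining realistic within-population spread.
#'
#' @return Tibble with columns `stage`, `marker`, `state`, `meanlog`,
#'   `sdlog`.
#' @export
default_marker_model <- function() {
  comp <- tibble::tribble(
    ~state, ~meanlog,   ~sdlog,
    "neg",  log(40),    0.45,
    "pos",  log(4000),  0.35,
    "hi",   log(6000),  0.30,
    "lo",   log(150),   0.45
  )
  states <- tibble::tribble(
    ~stage, ~CD24, ~CD25, ~CD73, ~CD117, ~CD200, ~CD371,
    "A",    "hi",  "pos", "neg", "neg",  "neg",  "pos",
    "B",    "hi",  "neg", "neg", "neg",  "neg",  "pos",
    "C",    "hi",  "neg", "neg", "neg",  "neg",  "neg",
    "D",    "hi",  "neg", "neg", "neg",  "pos",  "pos",
    "E",    "hi",  "neg", "pos", "pos",  "pos",  "neg",
    "F",    "hi",  "neg", "pos", "neg",  "pos",  "neg",
    "G",    "lo",  "neg", "pos", "neg",  "neg",  "neg"
  )
  states |>
    tidyr::pivot_longer(-"stage", names_to = "marker", values_to = "state") |>
    dplyr::left_join(comp, by = "state")
}

#' Cytometry simulation configuration
#'
#' Bundles everything [simulate_cytometry()] needs: the number of events in
#' the reference (untreated) group, the stage mixture, the per-stage marker
#' intensity model, the Vg1.1/Vg2 subset split, optional per-stage
#' accumulation factors for treatment groups, and the seed.
#'
#' `treatment_effects` is a named list, one element per group, each a named
#' numeric vector of per-stage multiplicative expected-count factors. The
#' first element is the reference group and must be all 1.
#'
#' @param n_events Events in the reference group.
#' @param stage_fractions Named fractions over stages A-G, summing to 1.
#' @param marker_model Tibble as returned by [default_marker_model()].
#' @param subset_fractions Named fractions over TCR subsets, summing to 1.
#' @param treatment_effects Named list of per-stage accumulation factors, or
#'   `NULL` for a single untreated group.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `cytometry_sim_config`.
#' @export
cytometry_sim_config <- function(n_events = 10000,
                                 stage_fractions = NULL,
                                 marker_model = default_marker_model(),
                                 subset_fractions = c(Vg1.1 = 0.5, Vg2 = 0.5),
                                 treatment_effects = NULL,
                                 seed = 1) {
  if (is.null(stage_fractions)) {
    stage_fractions <- setNames(rep(1 / 7, 7), gd_stages())
  }
  check_fractions(stage_fractions, "stage_fractions")
  if (!setequal(names(stage_fractions), gd_stages())) {
    abort("stage_fractions must name exactly the stages A-G")
  }
  check_fractions(subset_fractions, "subset_fractions")
  stopifnot(n_events >= 0, all(marker_model$sdlog > 0))
  need <- setdiff(c("stage", "marker", "state", "meanlog", "sdlog"),
                  names(marker_model))
  if (length(need) > 0) {
    abort(sprintf("marker_model lacks column(s): %s", paste(need, collapse = ", ")))
  }
  if (is.null(treatment_effects)) {
    treatment_effects <- list(untreated = setNames(rep(1, 7), gd_stages()))
  }
  for (g in names(treatment_effects)) {
    fx <- treatment_effects[[g]]
    if (!setequal(names(fx), gd_stages()) || any(fx <= 0)) {
      abort(sprintf("treatment_effects[['%s']] must give a positive factor per stage", g))
    }
  }
  ref <- treatment_effects[[1]]
  if (any(abs(ref - 1) > 1e-12)) {
    abort("the first treatment group is the reference and must have all factors equal to 1")
  }
  structure(
    list(n_events = as.integer(n_events),
         stage_fractions = stage_fractions[gd_stages()],
         marker_model = marker_model,
         subset_fractions = subset_fractions,
         treatment_effects = treatment_effects,
         seed = as.integer(seed)),
    class = "cytometry_sim_config")
}

#' Accumulation factors emulating emigration blockade
#'
#' Per-stage expected-count factors for untreated, 5-day and 10-day
#' blockade groups. The exported stages C, E and G keep accumulating
#' (reaching ten-, five- and ten-fold at day 10), while D and F rise early
#' and then stall -- the pattern used to call terminal stages.
#'
#' @return Named list of per-stage factor vectors.
#' @export
blockade_treatment_effects <- function() {
  s <- gd_stages()
  list(
    untreated  = setNames(rep(1, 7), s),
    FTY720_5d  = setNames(c(1, 1, 3.3, 1.5, 2.5, 1.4, 3.3), s),
    FTY720_10d = setNames(c(1, 1, 10, 1.6, 5, 1.8, 10), s)
  )
}

#' Simulate cytometry events with known stage labels
#'
#' Draws per-event intensities for the six staging markers from the
#' stage-specific log-normal mixture in the configuration. Counts per stage
#' in the reference group follow deterministic largest-remainder allocation
#' of `n_events`; treated groups draw Poisson counts around
#' `reference count x accumulation factor`. Each event carries its subset,
#' treatment group and true stage as `meta_` columns.
#'
#' @param config A [cytometry_sim_config()].
#' @return Tibble of raw (untransformed) intensities with columns
#'   `CD24`...`CD371`, `meta_subset`, `meta_group`, `meta_true_stage`.
#' @examples
#' ev <- simulate_cytometry(cytometry_sim_config(n_events = 700, seed = 7))
#' dplyr::count(ev, meta_true_stage)
#' @export
simulate_cytometry <- function(config) {
  stopifnot(inherits(config, "cytometry_sim_config"))
  model <- config$marker_model
  stages <- gd_stages()
  base <- allocate_counts(config$n_events, config$stage_fractions)

  local_seed(config$seed, {
    blocks <- list()
    for (g in names(config$treatment_effects)) {
      fx <- config$treatment_effects[[g]]
      counts <- if (g == names(config$treatment_effects)[1]) {
        base
      } else {
        setNames(rpois(length(stages), base[stages] * fx[stages]), stages)
      }
      for (s in stages) {
        n <- counts[[s]]
        if (n == 0) next
        m <- model[model$stage == s, ]
        vals <- lapply(gd_markers(), function(mk) {
          row <- m[m$marker == mk, ]
          rlnorm(n, meanlog = row$meanlog, sdlog = row$sdlog)
        })
        names(vals) <- gd_markers()
        blk <- tibble::as_tibble(vals)
        blk$meta_group <- g
        blk$meta_true_stage <- s
        blocks[[length(blocks) + 1]] <- blk
      }
    }
    out <- dplyr::bind_rows(blocks)
    out$meta_subset <- sample(names(config$subset_fractions), nrow(out),
                              replace = TRUE, prob = config$subset_fractions)
    out <- out[sample.int(nrow(out)), ]
    out <- out[c(gd_markers(), "meta_subset", "meta_group", "meta_true_stage")]
    attr(out, "transformed") <- FALSE
    out
  })
}
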