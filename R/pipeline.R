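#' Default pipeline configuration
#'
#' A fully synthetic end-to-end run: simulate cytometry events, expression
#' matrix and clonotype libraries; stage and cluster the events; infer the
#' lineage graph; run the marker screen; compute repertoire statistics; and
#' quantify blockade accumulation. Every step's seed and parameters live in
#' one flat list that can also be written/read as YAML.
#'
#' @param out_dir Output directory for all step artifacts.
#' @param seed Master seed; per-step seeds are derived from it.
#' @param n_events Events in the reference cytometry group.
#' @param steps Steps to run, a subset of `simulate`, `stage`, `cluster`,
#'   `lineage`, `screen`, `repertoire`, `emigration`.
#' @return Configuration list.
#' @export
default_pipeline_config <- function(out_dir = tempfile("gdrun"), seed = 1,
                                    n_events = 10000,
                                    steps = c("simulate", "stage", "cluster",
                                              "lineage", "screen",
                                              "repertoire", "emigration")) {
  list(
    out_dir = out_dir,
    steps = steps,
    seed = seed,
    cytometry = list(n_events = n_events, seed = seed + 101),
    expression = list(n_genes = 500, seed = seed + 202),
    repertoire = list(
      n_clones = 150, total_reads = 4000, seed = seed + 303,
      downsample_to = 1200,
      motifs = c(gdNKT_consensus = "GGIRA", T10T22_binding = "WEGYEL")),
    staging = list(cofactor = 150, threshold_method = "valley"),
    clustering = list(k = 7, grid_rows = 10, grid_cols = 10, epochs = 20,
                      seed = seed + 404),
    lineage = list(method = "mst", exclude_genes = character(0)),
    screen = list(fc = 3, q = 0.05, expr = 7,
                  surface_terms = c("GO:0009986", "GO:0005886"),
                  go_member_fraction = 0.3),
    emigration = list(min_fold = 3, min_growth_ratio = 1.5,
                      final_group = "FTY720_10d", mid_group = "FTY720_5d")
  )
}

#' Run the full analysis pipeline
#'
#' Executes the configured steps in dependency order, writing each step's
#' tables under `out_dir` and a `manifest.json` recording the package
#' version, configuration, seeds and an MD5 checksum per output file.
#' Identical configurations produce identical outputs and checksums. A
#' failing step aborts with the step name; files already written by the
#' failing step keep a `.partial` suffix.
#'
#' @param config Configuration list from [default_pipeline_config()], or a
#'   path to a YAML file holding one.
#' @return The manifest (invisibly), as written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  state$written <- character(0)
  manifest <- list(package = "gdstages",
                   version = as.character(utils::packageVersion("gdstages")),
                   config = config, steps_run = character(0),
                   steps_skipped = character(0), outputs = list())

  all_steps <- c("simulate", "stage", "cluster", "lineage", "screen",
                 "repertoire", "emigration")
  todo <- intersect(all_steps, config$steps)
  manifest$steps_skipped <- setdiff(all_steps, todo)

  emit <- function(data, name, writer = readr::write_tsv) {
    path <- file.path(out_dir, name)
    partial <- paste0(path, ".partial")
    writer(data, partial)
    state$written <- c(state$written, path)
    invisible(path)
  }
  finalise_step <- function() {
    for (p in state$written) file.rename(paste0(p, ".partial"), p)
    done <- state$written
    state$written <- character(0)
    done
  }

  run_step <- function(name, fn) {
    if (!name %in% todo) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      abort(sprintf("step '%s' failed: %s", name, conditionMessage(e)))
    })
    paths <- finalise_step()
    manifest$steps_run <<- c(manifest$steps_run, name)
    for (p in paths) {
      manifest$outputs[[basename(p)]] <<- unname(tools::md5sum(p))
    }
    invisible(NULL)
  }

  env <- new.env(parent = emptyenv())

  run_step("simulate", function() {
    cyto_cfg <- cytometry_sim_config(
      n_events = config$cytometry$n_events,
      treatment_effects = blockade_treatment_effects(),
      seed = config$cytometry$seed)
    env$events <- simulate_cytometry(cyto_cfg)
    emit(env$events, "events.csv", readr::write_csv)

    env$expr_sim <- simulate_expression(expression_sim_config(
      n_genes = config$expression$n_genes, seed = config$expression$seed))
    emit(env$expr_sim$log2, "expression_log2.tsv")
    emit(env$expr_sim$samples, "expression_samples.tsv")
    emit(env$expr_sim$truth$topology, "expression_truth_topology.tsv")

    rc <- config$repertoire
    env$rep_sim <- simulate_clonotypes(repertoire_sim_config(
      n_clones = rc$n_clones, total_reads = rc$total_reads,
      planted_motifs = setNames(c(0.3, 0.2), unname(rc$motifs)),
      seed = rc$seed))
    emit(env$rep_sim$table, "clonotypes.tsv")
  })

  run_step("stage", function() {
    ev <- arcsinh_transform(env$events, config$staging$cofactor)
    thr <- fit_positivity_thresholds(ev, config$staging$threshold_method)
    env$staged <- assign_stages(ev, thr)
    env$thresholds <- thr
    emit(thr, "thresholds.tsv")
    emit(tibble::tibble(stage = env$staged$stage), "stages.tsv")
    emit(stage_composition(env$staged), "stage_composition.tsv")
  })

  run_step("cluster", function() {
    cl <- config$clustering
    untreated <- dplyr::filter(env$staged, .data$meta_group == "untreated")
    env$clustered <- cluster_events(untreated, k = cl$k,
                                    grid_rows = cl$grid_rows,
                                    grid_cols = cl$grid_cols,
                                    epochs = cl$epochs, seed = cl$seed)
    prof <- cluster_profile(env$clustered)
    emit(tibble::tibble(cluster = env$clustered$cluster),
         "cluster_labels.tsv")
    emit(prof, "cluster_profile.csv", readr::write_csv)
    emit(match_clusters_to_stages(prof, env$thresholds),
         "cluster_stage_map.tsv")
  })

  run_step("lineage", function() {
    for (s in unique(env$expr_sim$samples$subset)) {
      dm <- distance_matrix(env$expr_sim$log2, env$expr_sim$samples,
                            subset = s,
                            exclude_genes = config$lineage$exclude_genes)
      tag <- gsub("[^A-Za-z0-9]", "", s)
      emit(tibble::as_tibble(unclass(dm), rownames = "population"),
           sprintf("distances_%s.csv", tag), readr::write_csv)
      graph <- build_lineage_graph(dm, method = config$lineage$method)
      emit(graph$edges, sprintf("%s_edges_%s.tsv", graph$method, tag))
    }
  })

  run_step("screen", function() {
    sc <- config$screen
    samples <- env$expr_sim$samples
    two <- samples[samples$stage %in% c("B", "E"), ]   # CD73- vs CD73+ proxy
    groups <- setNames(ifelse(two$stage == "B", "CD73neg", "CD73pos"),
                       two$sample)
    expr_two <- env$expr_sim$log2[c("gene", two$sample)]
    de <- differential_f_test(expr_two, groups)
    go <- simulate_go_annotation(de$gene,
                                 member_fraction = sc$go_member_fraction,
                                 seed = config$expression$seed)
    screened <- screen_candidates(de, go, fc = sc$fc, q = sc$q,
                                  expr = sc$expr,
                                  surface_terms = sc$surface_terms)
    emit(screened, "screen.tsv")
    emit(dplyr::filter(screened, .data$pass), "candidates.tsv")
  })

  run_step("repertoire", function() {
    rc <- config$repertoire
    tbl <- filter_in_frame(env$rep_sim$table)
    tbl <- downsample_reads(tbl, rc$downsample_to, seed = rc$seed)
    summary <- dplyr::bind_rows(
      motif_fractions(tbl, rc$motifs),
      tibble::tibble(motif = "inverse_simpson", pattern = NA_character_,
                     fraction = inverse_simpson(tbl)))
    emit(summary, "repertoire_summary.tsv")
    emit(segment_usage(tbl, "v"), "v_usage.tsv")
  })

  run_step("emigration", function() {
    em <- config$emigration
    comp <- stage_composition(env$staged, by = "meta_group", as = "count")
    folds <- fold_changes(dplyr::rename(comp, group = "meta_group"),
                          count_col = "n")
    called <- call_terminal_stages(folds, final_group = em$final_group,
                                   mid_group = em$mid_group,
                                   min_fold = em$min_fold,
                                   min_growth_ratio = em$min_growth_ratio)
    emit(folds, "fold_changes.tsv")
    emit(called, "terminal_stages.tsv")
  })

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
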