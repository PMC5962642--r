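#' Pipeline configuration
#'
#' @param annotation_path Compound annotation CSV (defaults to the
#'   packaged table).
#' @param subset_compounds Optional character vector of abbreviations to
#'   restrict the screen to (controls are always kept).
#' @param simulate Generate the synthetic screen (`TRUE`) or read an
#'   existing per-cell table from `cells_path`.
#' @param cells_path Per-cell CSV when `simulate = FALSE`.
#' @param effect_config,layout_config,svm Stage settings.
#' @param run_anova Run the functional-ANOVA stage (the permutation tests
#'   dominate runtime on large screens).
#' @param n_perm Permutations per functional-ANOVA test.
#' @param cluster_k Clusters to cut the multi-reporter dendrogram into.
#' @param n_iter Classifier train/test iterations.
#' @param stable_threshold Selection-count threshold for stable features,
#'   scaled to `n_iter` (default 0.75 * n_iter, matching 150/200).
#' @param rng_seed Master seed for every stochastic stage.
#' @param out_dir Output directory for tables, cache and manifest.
#' @return A list of settings with class `stressdyn_pipeline_config`.
#' @export
pipeline_config <- function(annotation_path = stressdyn_annotation_path(),
                            subset_compounds = NULL,
                            simulate = TRUE,
                            cells_path = NULL,
                            effect_config = sim_effect_config(),
                            layout_config = sim_layout_config(),
                            svm = svm_config(),
                            run_anova = TRUE,
                            n_perm = 499,
                            cluster_k = 3,
                            n_iter = 200,
                            stable_threshold = NULL,
                            rng_seed = 1L,
                            out_dir = file.path(tempdir(),
                                                "stressdyn_run")) {
  if (is.null(stable_threshold)) stable_threshold <- 0.75 * n_iter
  structure(as.list(environment()),
            class = "stressdyn_pipeline_config")
}

write_stage_table <- function(x, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  utils::write.csv(x, path, row.names = FALSE, na = "NA")
  path
}

# content-hash keyed stage cache: recompute only when inputs changed
stage_cached <- function(name, key_obj, out_dir, compute) {
  key <- rlang::hash(key_obj)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  cache_file <- file.path(cache_dir, paste0(name, "_", key, ".rds"))
  if (file.exists(cache_file)) {
    return(list(value = readRDS(cache_file), key = key, cached = TRUE))
  }
  value <- tryCatch(compute(), error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
  saveRDS(value, cache_file)
  list(value = value, key = key, cached = FALSE)
}

# compound-level cluster input: condensed courses of the headline
# descriptor, concatenated over concentrations, one vector per reporter
build_cluster_courses <- function(descriptors, n_points = 24, df = 8) {
  headline <- descriptors %>%
    filter((.data$reporter != "ICAM1" & .data$descriptor == "frac_2m") |
             (.data$reporter == "ICAM1" &
                .data$descriptor == "icam_diff_2"))
  headline %>%
    group_by(.data$compound, .data$reporter, .data$conc_xcmax) %>%
    group_modify(function(g, key) {
      condense_course(g, n_points = n_points, df = df)
    }) %>%
    ungroup() %>%
    arrange(.data$compound, .data$reporter, .data$conc_xcmax,
            .data$time_h) %>%
    select(item = "compound", "reporter", "value")
}

#' Run the full screen-analysis pipeline
#'
#' Executes the stages annotation -> (simulate) -> descriptors ->
#' time-course statistics -> concentration-response / BMC -> severity
#' classification -> report, writing each stage's tables and a JSON run
#' manifest (config snapshot, master seed, stage content hashes) to
#' `config$out_dir`.  Stage results are cached by input content hash, so
#' re-running with an unchanged configuration reuses earlier stages.
#'
#' @param config Settings from [pipeline_config()].
#' @return A list with all stage outputs and the manifest, invisibly
#'   classed `stressdyn_pipeline_result`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  note <- function(name, key, cached) {
    stages[[length(stages) + 1]] <<- list(stage = name, input_hash = key,
                                          cached = cached)
  }

  # -- annotation ---------------------------------------------------------
  if (cfg$simulate && is.null(cfg$annotation_path)) {
    abort("missing input: annotation_path is required when simulating")
  }
  if (!cfg$simulate && is.null(cfg$cells_path)) {
    abort("missing input: cells_path is required when simulate = FALSE")
  }
  ann <- read_compound_table(cfg$annotation_path)
  if (!is.null(cfg$subset_compounds)) {
    ann <- ann %>% filter(.data$abbreviation %in% cfg$subset_compounds |
                            .data$is_control)
  }
  write_stage_table(ann, cfg$out_dir, "annotations")
  note("annotation", rlang::hash(ann), FALSE)

  # -- cells --------------------------------------------------------------
  if (cfg$simulate) {
    sim <- stage_cached(
      "simulate",
      list(ann, cfg$effect_config, cfg$layout_config, cfg$rng_seed),
      cfg$out_dir,
      function() simulate_screen(ann, cfg$effect_config,
                                 cfg$layout_config, cfg$rng_seed)
    )
    cells <- sim$value$cells
    truth <- sim$value$truth
    write_stage_table(truth, cfg$out_dir, "truth")
    note("simulate", sim$key, sim$cached)
  } else {
    cells <- read_cell_table(cfg$cells_path)
    truth <- NULL
    note("load_cells", rlang::hash(cells), FALSE)
  }

  # -- descriptors --------------------------------------------------------
  desc <- stage_cached("descriptors", list(cells), cfg$out_dir, function() {
    raw <- compute_descriptors(cells)
    list(raw = raw,
         scaled = scale_descriptors(raw, cells),
         controls = control_descriptor_courses(cells),
         cytotox = cytotox_summary(cells))
  })
  note("descriptors", desc$key, desc$cached)
  descs <- desc$value
  write_stage_table(descs$scaled, cfg$out_dir, "descriptors_scaled")
  write_stage_table(descs$cytotox, cfg$out_dir, "cytotox")

  # -- time-course statistics --------------------------------------------
  tc <- stage_cached(
    "timecourse",
    list(descs$scaled, descs$controls, cfg$run_anova, cfg$n_perm,
         cfg$cluster_k, cfg$rng_seed),
    cfg$out_dir,
    function() {
      anova_tbl <- if (cfg$run_anova) {
        timecourse_anova(descs$scaled, descs$controls,
                         n_perm = cfg$n_perm,
                         rng_seed = cfg$rng_seed + 200000L)
      }
      courses <- build_cluster_courses(descs$scaled)
      dmat <- multireporter_distance(courses)
      clust <- ward_cluster(dmat, k = min(cfg$cluster_k,
                                          nrow(dmat) - 1))
      list(anova = anova_tbl, dist = dmat, clustering = clust)
    }
  )
  note("timecourse", tc$key, tc$cached)
  if (!is.null(tc$value$anova)) {
    write_stage_table(tc$value$anova, cfg$out_dir, "timecourse_anova")
  }
  utils::write.table(round(tc$value$dist, 6),
                     file.path(cfg$out_dir, "distance_matrix.txt"),
                     quote = FALSE)
  writeLines(tc$value$clustering$newick,
             file.path(cfg$out_dir, "dendrogram.nwk"))

  # -- concentration-response / BMC --------------------------------------
  bmc_stage <- stage_cached(
    "bmc", list(descs$scaled, ann), cfg$out_dir,
    function() {
      mx <- max_over_time_table(descs$scaled)
      bmc <- bmc_table(mx, ann)
      list(max_table = mx, bmc = bmc,
           class_stats = bmc_class_stats(bmc, ann))
    }
  )
  note("bmc", bmc_stage$key, bmc_stage$cached)
  write_stage_table(bmc_stage$value$bmc, cfg$out_dir, "bmc")
  write_stage_table(bmc_stage$value$class_stats, cfg$out_dir,
                    "bmc_class_stats")

  # -- classification -----------------------------------------------------
  clf <- stage_cached(
    "classify",
    list(descs$scaled, descs$cytotox, bmc_stage$value$bmc, ann,
         cfg$svm, cfg$n_iter, cfg$rng_seed),
    cfg$out_dir,
    function() {
      features <- extract_dynamic_features(descs$scaled, descs$cytotox,
                                           bmc_stage$value$bmc, ann)
      labels <- classifier_labels(features, ann)
      runs <- run_iterations(features, labels, n_iter = cfg$n_iter,
                             rng_seed = cfg$rng_seed + 300000L,
                             config = cfg$svm)
      stability <- stability_report(runs,
                                    stable_threshold =
                                      cfg$stable_threshold)
      list(features = features,
           manifest = attr(features, "manifest"),
           labels = labels, runs = runs, stability = stability)
    }
  )
  note("classify", clf$key, clf$cached)
  write_stage_table(clf$value$manifest, cfg$out_dir, "feature_manifest")
  write_stage_table(clf$value$runs$runs, cfg$out_dir, "classifier_runs")
  write_stage_table(clf$value$stability$feature_counts, cfg$out_dir,
                    "feature_stability")
  write_stage_table(clf$value$stability$compound_predictions,
                    cfg$out_dir, "compound_predictions")

  # -- report -------------------------------------------------------------
  report <- list(
    class_counts = class_counts(ann),
    classifier_summary = clf$value$runs$summary,
    n_stable_features = length(clf$value$stability$stable_features),
    bmc_class_stats = bmc_stage$value$class_stats
  )
  write_stage_table(report$class_counts, cfg$out_dir, "class_counts")
  write_stage_table(report$classifier_summary, cfg$out_dir,
                    "classifier_summary")
  note("report", rlang::hash(report), FALSE)

  manifest <- list(
    package_version =
      as.character(utils::packageVersion("stressdyn")),
    rng_seed = cfg$rng_seed,
    n_iter = cfg$n_iter,
    n_perm = cfg$n_perm,
    run_anova = cfg$run_anova,
    stages = stages
  )
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(structure(
    list(annotations = ann, cells = cells, truth = truth,
         descriptors = descs, timecourse = tc$value,
         bmc = bmc_stage$value, classification = clf$value,
         report = report, manifest = manifest, config = cfg),
    class = "stressdyn_pipeline_result"
  ))
}

#' @export
print.stressdyn_pipeline_result <- function(x, ...) {
  cat("stressdyn pipeline run (", length(x$manifest$stages),
      " stages)\n", sep = "")
  print(x$report$classifier_summary)
  invisible(x)
}
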