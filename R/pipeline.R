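#' Pipeline configuration
#'
#' Collects every threshold, seed and mode switch of the cluster-discovery
#' pipeline in one validated object.  Defaults mirror the motivating design:
#' 1:10 matching, 183-day washout, 0.5% condition prevalence, 0.25% pair
#' co-occurrence prevalence, q < 0.05 throughout, at most two nested
#' controls per case.
#'
#' @param exposure_codes ICD-10 prefixes defining the index diagnosis.
#' @param mode "exploration" (full pipeline) or "validation" (no trajectory;
#'   clusters are the comorbidity modules).
#' @param exclusion_codes history-exclusion prefixes for cohort entry.
#' @param match_ratio controls per exposed person.
#' @param washout_days washout between index date and follow-up start.
#' @param condition_prevalence PheWAS prevalence floor.
#' @param pair_prevalence pair co-occurrence prevalence floor.
#' @param alpha FDR threshold used by every stage.
#' @param nested_controls controls per case in the nested case-control step.
#' @param seeds named list with integer seeds `cohort`, `louvain`, `nested`.
#' @param covariates PheWAS covariates (cohort column names), or NULL.
#' @param logistic_covariates covariates of the pair logistic model.
#' @param q_rule pair retention rule, see [screen_pairs()].
#' @param phi_max_rule see [pair_z()].
#' @param louvain_restarts restarts of the Louvain search.
#' @param direction_alpha FDR gate for orientation assignment, or NULL to
#'   orient every untied pair.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(exposure_codes = c("F40", "F41", "F43"),
                            mode = c("exploration", "validation"),
                            exclusion_codes = character(),
                            match_ratio = 10L,
                            washout_days = 183L,
                            condition_prevalence = 0.005,
                            pair_prevalence = 0.0025,
                            alpha = 0.05,
                            nested_controls = 2L,
                            seeds = list(cohort = 1L, louvain = 1L,
                                         nested = 1L),
                            covariates = NULL,
                            logistic_covariates = c("sex", "birth_year"),
                            q_rule = "both",
                            phi_max_rule = "printed",
                            louvain_restarts = 20L,
                            direction_alpha = 0.05) {
  mode <- match.arg(mode)
  for (th in c(condition_prevalence, pair_prevalence, alpha))
    if (th <= 0 || th >= 1) stopf("thresholds must lie in (0, 1)")
  for (s in c("cohort", "louvain", "nested"))
    if (is.null(seeds[[s]])) stopf("`seeds` must name an integer `%s` seed", s)
  structure(list(exposure_codes = exposure_codes, mode = mode,
                 exclusion_codes = exclusion_codes,
                 match_ratio = assert_count(match_ratio, "match_ratio", 1L),
                 washout_days = as.integer(washout_days),
                 condition_prevalence = condition_prevalence,
                 pair_prevalence = pair_prevalence, alpha = alpha,
                 nested_controls = assert_count(nested_controls,
                                                "nested_controls", 1L),
                 seeds = lapply(seeds, as.integer),
                 covariates = covariates,
                 logistic_covariates = logistic_covariates,
                 q_rule = q_rule, phi_max_rule = phi_max_rule,
                 louvain_restarts = assert_count(louvain_restarts,
                                                 "louvain_restarts", 1L),
                 direction_alpha = direction_alpha),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a YAML mapping whose keys are [pipeline_config()] arguments.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("the `yaml` package is required to read config files")
  args <- yaml::read_yaml(path)
  do.call(pipeline_config, args)
}

#' Run the full cluster-discovery pipeline
#'
#' Executes cohort construction, the PheWAS screen, pair screening, the
#' comorbidity network with Louvain modules and, in exploration mode, the
#' trajectory stage, then merges the views into disease clusters and scores
#' every exposed patient.  Validation mode skips the trajectory and takes
#' the comorbidity modules themselves as clusters.  When `out_dir` is given,
#' every intermediate table is written as tab-delimited text together with a
#' `manifest.json` recording the configuration, seeds and per-stage row
#' counts, so a run can be audited and reproduced stage by stage.
#'
#' @param registry a `registry` object, or a directory path readable by
#'   [read_registry()].
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param verbose emit stage progress.
#' @return list with elements cohort, phewas, pairs, edges, network,
#'   partition, directions (exploration only), traj_edges (exploration
#'   only), trajectory (exploration only), clusters, scores, manifest.
#' @export
run_pipeline <- function(registry, config = pipeline_config(),
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(registry)) registry <- read_registry(registry)
  stopifnot(inherits(registry, "registry"))

  ccfg <- cohort_config(exposure_codes = config$exposure_codes,
                        match_ratio = config$match_ratio,
                        washout_days = config$washout_days,
                        exclusion_codes = config$exclusion_codes,
                        seed = config$seeds$cohort)
  msgf(verbose, "stage: cohort")
  cohort <- build_cohort(registry, ccfg)
  log <- list(n_exposed = cohort[role == "exposed", .N],
              n_controls = cohort[role == "control", .N],
              n_unmatched_sets = attr(cohort, "n_unmatched") %||% 0L,
              n_dropped_followup = attr(cohort, "n_dropped") %||% 0L)

  msgf(verbose, "stage: phewas")
  phewas <- if (log$n_exposed > 0L)
    run_phewas(cohort, registry, config$exposure_codes,
               config$condition_prevalence, config$alpha,
               covariates = config$covariates, verbose = verbose)
  else data.table(code = character(), selected = logical())
  selected <- phewas[selected == TRUE, code]
  log$n_conditions_tested <- nrow(phewas)
  log$n_conditions_selected <- length(selected)

  msgf(verbose, "stage: pairs")
  pairs <- screen_pairs(cohort, registry, selected, config$pair_prevalence,
                        config$alpha, config$q_rule, config$phi_max_rule)
  log$n_pairs_evaluated <- nrow(pairs)
  log$n_pairs_retained <- pairs[retained == TRUE, .N]

  msgf(verbose, "stage: network")
  edges <- confirm_edges(cohort, registry, pairs, config$alpha,
                         config$logistic_covariates)
  log$n_edges_confirmed <- edges[confirmed == TRUE, .N]
  network <- build_network(edges)
  partition <- if (igraph::vcount(network) > 0L)
    louvain_partition(network, config$seeds$louvain,
                      config$louvain_restarts)
  else structure(list(membership = setNames(integer(), character()),
                      modularity = NA_real_, seed = config$seeds$louvain,
                      n_restarts = config$louvain_restarts),
                 class = "module_partition")
  log$n_modules <- length(unique(partition$membership))

  directions <- NULL; traj_edges <- NULL; trajectory <- NULL
  if (config$mode == "exploration") {
    msgf(verbose, "stage: trajectory")
    directions <- test_directions(cohort, registry, pairs,
                                  config$direction_alpha)
    traj_edges <- trajectory_edges(cohort, registry, directions,
                                   config$nested_controls,
                                   config$seeds$nested, config$alpha)
    trajectory <- build_trajectory(traj_edges)
    log$n_directed_pairs <- directions[direction != "none", .N]
    log$n_trajectory_edges <- traj_edges[retained == TRUE, .N]
    clusters <- merge_clusters(trajectory, partition)
  } else {
    clusters <- network_only_clusters(partition, selected)
  }
  log$n_clusters <- length(clusters)

  msgf(verbose, "stage: scores")
  scores <- susceptibility_scores(registry, cohort, clusters)

  manifest <- list(mode = config$mode,
                   config = config[setdiff(names(config), "seeds")],
                   seeds = config$seeds,
                   counts = log,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  out <- list(cohort = cohort, phewas = phewas, pairs = pairs,
              edges = edges, network = network, partition = partition,
              directions = directions, traj_edges = traj_edges,
              trajectory = trajectory, clusters = clusters, scores = scores,
              manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

clusters_to_json <- function(clusters) {
  lapply(unclass(clusters), function(cl)
    list(cluster_id = cl$cluster_id, module_id = cl$module_id,
         roots = as.list(cl$roots), members = as.list(cl$members),
         size = cl$size))
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  fwrite(out$cohort, fp("cohort.tsv"), sep = "\t")
  fwrite(out$phewas, fp("phewas.tsv"), sep = "\t")
  fwrite(out$pairs, fp("pairs.tsv"), sep = "\t")
  fwrite(out$edges, fp("edges.tsv"), sep = "\t")
  fwrite(data.table(code = names(out$partition$membership),
                    module_id = as.integer(out$partition$membership)),
         fp("modules.tsv"), sep = "\t")
  if (!is.null(out$directions)) {
    fwrite(out$directions, fp("directions.tsv"), sep = "\t")
    fwrite(out$traj_edges, fp("trajectory_edges.tsv"), sep = "\t")
    writeLines(out$trajectory$d1, fp("d1.txt"))
  }
  jsonlite::write_json(clusters_to_json(out$clusters), fp("clusters.json"),
                       auto_unbox = TRUE, digits = NA)
  fwrite(out$scores, fp("scores.tsv"), sep = "\t")
  jsonlite::write_json(out$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
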