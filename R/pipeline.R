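#' Run the full index-sort marker-ranking and panel-discovery pipeline
#'
#' Orchestrates, deterministically given the seeds in the configuration:
#' well scoring, replicate exclusion, outlier exclusion, per-replicate rank
#' normalization, per-replicate SMOTE augmentation and bagged-tree
#' training, first-occurrence rank profiling, cross-replicate rank
#' aggregation, Wilcoxon marker testing, sequential panel discovery on the
#' combined normalized data, and panel evaluation. Artifacts (combined
#' table, rank profiles, summary, panel JSON, evaluation metrics and a
#' manifest with parameters and output hashes) are written to the output
#' directory.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `plates` (path to an index-sort table) *or* `simulate` (arguments for
#'   [sim_config()]); optional `n_trees` (default 1000), `n_bins` (60),
#'   `min_colonies` (5), `k_mad` (5), `smote_k` (5), `seed` (1),
#'   `out_dir` (required).
#' @return invisibly, a list with the panel, rank summary, evaluation
#'   metrics and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("plates", "simulate", "n_trees", "n_bins", "min_colonies",
             "k_mad", "smote_k", "seed", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$out_dir)) stop("config must set out_dir")
  n_trees <- config$n_trees %||% 1000
  n_bins <- config$n_bins %||% 60
  seed <- as.integer(config$seed %||% 1L)

  dataset <- if (!is.null(config$plates)) {
    read_index_sort(config$plates)
  } else if (!is.null(config$simulate)) {
    args <- config$simulate
    args$seed <- args$seed %||% seed
    if (!is.null(args$truth_panel)) {
      tp <- args$truth_panel
      args$truth_panel <- if (is.data.frame(tp)) {
        unname(Map(gate_spec, tp$marker, tp$direction, tp$percentile))
      } else {
        lapply(tp, function(g) {
          if (inherits(g, "gate_spec")) g else
            gate_spec(g$marker, g$direction, g$percentile)
        })
      }
    }
    simulate_index_sort(do.call(sim_config, args))
  } else {
    stop("config must provide either `plates` or `simulate`")
  }

  res <- rank_and_build(dataset,
                        n_trees = n_trees, n_bins = n_bins,
                        min_colonies = config$min_colonies %||% 5,
                        k_mad = config$k_mad %||% 5,
                        smote_k = config$smote_k %||% 5,
                        seed = seed)

  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_index_sort(res$combined, file.path(out_dir, "combined.tsv"))
  utils::write.table(res$rank_summary, file.path(out_dir, "rank_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  profile_rows <- do.call(rbind, lapply(names(res$profiles), function(pid) {
    cbind(replicate = pid, res$profiles[[pid]]$summary)
  }))
  utils::write.table(profile_rows, file.path(out_dir, "rank_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_panel(res$panel, file.path(out_dir, "panel.json"))
  jsonlite::write_json(res$evaluation, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  outputs <- c("combined.tsv", "rank_summary.tsv", "rank_profiles.tsv",
               "panel.json", "evaluation.json")
  manifest <- list(
    parameters = list(n_trees = n_trees, n_bins = n_bins,
                      min_colonies = config$min_colonies %||% 5,
                      k_mad = config$k_mad %||% 5,
                      smote_k = config$smote_k %||% 5, seed = seed,
                      simulate = config$simulate, plates = config$plates),
    exclusions = list(
      replicates = attr(res$scored_excluded, "exclusion_log"),
      outlier_wells = attr(res$outlier_excluded, "exclusion_log")
    ),
    outputs = as.list(tools::md5sum(file.path(out_dir, outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(res, list(manifest = manifest)))
}

#' Rank markers and discover a panel from a scored or raw index-sort table
#'
#' The in-memory core of [run_pipeline()]: scores wells, drops sparse
#' replicates and outlier wells, rank-normalizes per replicate, then per
#' replicate SMOTE-augments to a 1:1 class balance, fits a bagged ensemble
#' and profiles first-occurrence ranks; finally aggregates the profiles
#' (tie-broken by Wilcoxon p-values on the combined data) and runs
#' sequential cutoff discovery on the combined normalized dataset.
#'
#' @param dataset index-sort data.frame (scored or not).
#' @param n_trees trees per replicate ensemble (default 1000).
#' @param n_bins enrichment-curve bins (default 60).
#' @param min_colonies replicate-exclusion floor (default 5).
#' @param k_mad outlier threshold in robust SDs (default 5).
#' @param smote_k SMOTE neighbour count (default 5).
#' @param seed integer seed; per-replicate seeds are derived from it.
#' @return list: `panel`, `rank_summary`, `profiles`, `wilcoxon`,
#'   `combined` (normalized combined table), `evaluation`, plus the
#'   intermediate `scored_excluded` and `outlier_excluded` tables.
#' @export
rank_and_build <- function(dataset, n_trees = 1000, n_bins = 60,
                           min_colonies = 5, k_mad = 5, smote_k = 5,
                           seed = 1L) {
  if (is.null(dataset$outcome)) dataset <- score_wells(dataset)
  scored <- exclude_replicates(dataset, min_colonies = min_colonies)
  cleaned <- exclude_outliers(scored, k_mad = k_mad)
  combined <- normalize_replicates(cleaned)
  markers <- marker_names(combined)

  plate_ids <- unique(combined$plate_id)
  profiles <- stats::setNames(vector("list", length(plate_ids)), plate_ids)
  for (i in seq_along(plate_ids)) {
    rep_data <- combined[combined$plate_id == plate_ids[i], , drop = FALSE]
    aug <- smote_augment(as.matrix(rep_data[markers]), rep_data$outcome,
                         target_ratio = 1.0, k_neighbors = smote_k,
                         seed = seed + i)
    ens <- fit_bagging(aug$features, aug$outcomes, n_trees = n_trees,
                       seed = seed + 10000L + i)
    profiles[[i]] <- first_occurrence_ranks(ens)
  }
  wilcox <- wilcoxon_marker_test(combined)
  summary <- rank_summary(profiles, p_values = wilcox)
  panel <- build_panel(combined, marker_order = summary$marker,
                       n_bins = n_bins)
  list(panel = panel, rank_summary = summary, profiles = profiles,
       wilcoxon = wilcox, combined = combined,
       evaluation = evaluate_panel(panel, combined),
       scored_excluded = scored, outlier_excluded = cleaned)
}
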