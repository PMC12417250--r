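# End-to-end pipeline: (read | simulate) -> project/resample ->
# features -> standardize/invert -> cluster -> compounds -> outlier screen
# -> mixed ANCOVA + post-hocs + correlations + BF01.

#' Run the full exploration analysis pipeline
#'
#' Takes either a simulated panel ([simulate_study()] output / a
#' [sim_config]) or file paths (trajectory CSV, metadata CSV, environment
#' JSON), computes the thirteen measures, fits the variable-clustering
#' model, builds compound scores, screens outliers, and runs the
#' inferential stack. Every stage is also available as a standalone
#' function.
#'
#' @param input a `sim_panel`, a `sim_config`, or a named list of paths
#'   `list(trajectories =, metadata =, environment =)`.
#' @param cfg a [metric_config].
#' @param k_forced cluster count used for the cut (default 3; the kneedle
#'   selection is always reported alongside).
#' @param strict error when kneedle disagrees with `k_forced`.
#' @param threshold_sd outlier screen threshold.
#' @param assignment `"reference"` (default) builds the compound scores
#'   from the established three-dimension membership
#'   ([reference_clusters()]), with the data-driven clustering reported as
#'   validation; `"fitted"` uses the partition from the dendrogram cut.
#' @param up_axis vertical axis convention for 3-coordinate logs.
#' @param out_dir optional directory; when given, feature table, compound
#'   scores, cluster report and results JSON are written there.
#' @return an object of class `exploration_analysis`: list with
#'   `features`, `cluster`, `scores`, `excluded`, `long`, `stats`, `log`.
#' @export
run_pipeline <- function(input, cfg = metric_config(), k_forced = 3,
                         strict = FALSE, threshold_sd = 3,
                         assignment = c("reference", "fitted"),
                         up_axis = "second", out_dir = NULL) {
  assignment <- match.arg(assignment)
  log <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (inherits(input, "sim_config")) input <- simulate_study(input)
  if (inherits(input, "sim_panel")) {
    trajs <- input$trajectories
    env <- input$environment
    meta <- input$meta
    log$seed <- input$config$seed
    log$source <- "simulated"
  } else if (is.list(input) && !is.null(input$trajectories)) {
    trajs <- read_trajectories(input$trajectories)
    env <- read_environment(input$environment)
    meta <- read_metadata(input$metadata)
    trajs <- lapply(trajs, project_ground_plane, up_axis = up_axis)
    log$source <- "files"
    log$config_hash <- unname(tools::md5sum(input$trajectories))
  } else {
    et_error("input must be a sim_panel, sim_config, or list of paths",
             "et_contract_error")
  }

  features <- compute_feature_table(trajs, env, cfg)
  complete <- stats::complete.cases(
    features[, setdiff(names(features), "participant_id")])
  if (any(!complete)) {
    et_warn(sprintf("%d participant(s) with undefined measures dropped: %s",
                    sum(!complete),
                    paste(features$participant_id[!complete],
                          collapse = ", ")), "et_quality_warning")
    log$dropped_undefined <- features$participant_id[!complete]
    features <- features[complete, , drop = FALSE]
  }

  cluster <- fit_cluster_model(features, k_forced = k_forced,
                               strict = strict)
  assign_vec <- if (assignment == "reference") {
    ref <- reference_clusters()
    setNames(rep(names(ref), lengths(ref)), unlist(ref))
  } else {
    cluster$assignment
  }
  log$assignment <- assignment
  scores_all <- compound_scores(cluster$table_z, assign_vec)
  scores <- outlier_screen(scores_all, threshold_sd = threshold_sd)
  excluded <- attr(scores, "excluded")
  log$n_excluded_outliers <- nrow(excluded)

  long <- to_long(scores, meta)
  stats_out <- group_statistics(long)

  res <- structure(
    list(features = features, cluster = cluster, scores = scores,
         excluded = excluded, long = long, stats = stats_out, log = log),
    class = "exploration_analysis")
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

#' @exportS3Method base::print
print.exploration_analysis <- function(x, ...) {
  cat(sprintf("<exploration_analysis: %d participants analyzed, %d excluded>\n",
              x$stats$n, nrow(x$excluded)))
  cat(sprintf("  clustering: k = %d (kneedle %d)\n", x$cluster$k,
              x$cluster$k_kneedle))
  a <- x$stats$ancova
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-14s F(%.2f, %.1f) = %6.2f, p = %.4f, eta2p = %.3f\n",
                a$effect[i], a$df_num[i], a$df_den[i], a$F[i], a$p[i],
                a$partial_eta_sq[i]))
  }
  cat(sprintf("  BF01 (no sex:age) = %.2f\n", x$stats$bf01))
  invisible(x)
}

#' Write the analysis artifacts of a pipeline run
#'
#' @param res an `exploration_analysis`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(res$features, file.path(out_dir, "features.csv"))
  comp <- res$scores
  comp$excluded <- FALSE
  if (nrow(res$excluded)) {
    exc <- res$excluded
    exc_rows <- data.frame(participant_id = exc$participant_id,
                           stringsAsFactors = FALSE)
    for (col in setdiff(names(comp), c("participant_id", "excluded"))) {
      exc_rows[[col]] <- NA_real_
    }
    exc_rows$excluded <- TRUE
    comp <- rbind(comp, exc_rows)
  }
  write_numeric_csv(comp, file.path(out_dir, "compounds.csv"))
  cl <- res$cluster
  cluster_report <- list(
    merge = unclass(cl$tree$merge), heights = cl$heights,
    k_kneedle = cl$k_kneedle, k = cl$k,
    assignment = as.list(cl$assignment), inverted = cl$inverted)
  jsonlite::write_json(cluster_report,
                       file.path(out_dir, "cluster.json"),
                       auto_unbox = TRUE, digits = NA)
  results <- list(
    n = res$stats$n,
    ancova = res$stats$ancova,
    posthoc = res$stats$posthoc,
    correlations = res$stats$correlations,
    bf01 = res$stats$bf01,
    excluded = res$excluded,
    log = res$log[setdiff(names(res$log), "timestamp")])
  write_results(results, file.path(out_dir, "results.json"))
  invisible(out_dir)
}

#' Run the pipeline from a YAML configuration file
#'
#' The YAML file may contain `sim:` (any [sim_config] field), `metrics:`
#' (any [metric_config] field), and `pipeline:` (`k_forced`, `strict`,
#' `threshold_sd`, `out_dir`) sections; a `seed` at the top level
#' overrides `sim$seed`.
#'
#' @param path YAML config path.
#' @param seed optional seed overriding the file.
#' @param out_dir optional output directory overriding the file.
#' @return an `exploration_analysis`.
#' @export
run_pipeline_yaml <- function(path, seed = NULL, out_dir = NULL) {
  cfg <- yaml::read_yaml(path)
  sim_args <- cfg$sim %||% list()
  if (!is.null(seed)) sim_args$seed <- seed
  else if (!is.null(cfg$seed)) sim_args$seed <- cfg$seed
  scfg <- do.call(sim_config, sim_args)
  mcfg <- do.call(metric_config, cfg$metrics %||% list())
  pl <- cfg$pipeline %||% list()
  run_pipeline(scfg, cfg = mcfg,
               k_forced = pl$k_forced %||% 3,
               strict = isTRUE(pl$strict),
               threshold_sd = pl$threshold_sd %||% 3,
               out_dir = out_dir %||% pl$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
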