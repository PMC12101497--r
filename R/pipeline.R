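#' Run the end-to-end synthetic prediction pipeline
#'
#' Orchestrates simulate -> connect -> predict -> importance ->
#' (optional) lesion scan from one flat configuration, writing
#' tab-separated result tables and a JSON run manifest to `out_dir`.
#' All randomness flows from the single master seed, so rerunning the
#' same configuration reproduces identical numerical outputs.
#'
#' @param config a list (or path to a JSON file) with elements:
#'   * `seed`: master seed (required),
#'   * `out_dir`: output directory (required),
#'   * `simulate`: arguments for [simulate_cohort()] (optional),
#'   * `prediction`: arguments for [prediction_config()] (optional),
#'   * `lesion`: `TRUE` for a full scan, a character vector of networks,
#'     or `FALSE`/`NULL` to skip (default),
#'   * `component`: label used in output tables (default `"EVENT"`).
#' @return The manifest, invisibly. On stage failure the manifest (and
#'   `manifest.json`) records the failing stage and the error message.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (field in c("seed", "out_dir")) {
    if (is.null(config[[field]])) {
      stop(sprintf("config is missing '%s'", field), call. = FALSE)
    }
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  component <- config$component %||% "EVENT"

  manifest <- list(
    package = "wmconn",
    version = as.character(utils::packageVersion("wmconn")),
    seed = as.integer(config$seed),
    component = component,
    config = config[setdiff(names(config), "out_dir")],
    started = format(Sys.time(), tz = "UTC"),
    stages = list(),
    outputs = list(),
    status = "running"
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  run_stage <- function(name, fun) {
    result <- tryCatch(fun(), error = function(e) e)
    if (inherits(result, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(result))
      manifest$status <<- paste0("failed at stage '", name, "'")
      write_manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(result)), call. = FALSE)
    }
    manifest$stages[[name]] <<- list(status = "ok")
    result
  }

  sim_args <- config$simulate %||% list()
  sim_args$seed <- config$seed
  cohort <- run_stage("simulate", function() {
    do.call(simulate_cohort, sim_args)
  })
  write_atlas(cohort$atlas, file.path(out_dir, "atlas.tsv"))
  write_scores(data.frame(subject_id = names(cohort$y), score = cohort$y),
               file.path(out_dir, "behavior.tsv"))
  jsonlite::write_json(unclass(cohort$truth),
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$outputs$atlas <- "atlas.tsv"
  manifest$outputs$behavior <- "behavior.tsv"
  manifest$outputs$ground_truth <- "ground_truth.json"

  pred_args <- config$prediction %||% list()
  pred_args$seed <- pred_args$seed %||% config$seed
  pcfg <- do.call(prediction_config, pred_args)
  pred <- run_stage("predict", function() {
    cpm_predict(cohort$X, cohort$y, pcfg)
  })
  summary_tab <- cbind(component = component, pred$summary)
  write.table(summary_tab, file.path(out_dir, "prediction.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$outputs$prediction <- "prediction.tsv"

  importance <- run_stage("importance", function() {
    best <- which.max(pred$summary$r)
    consensus <- suppressWarnings(consensus_features(pred$folds[[best]]))
    E <- network_edge_matrix(consensus, cohort$map, cohort$atlas)
    rd <- suppressWarnings(relative_degree(E))
    top_net <- names(rd)[which.max(rd)]
    degrees <- node_degree(consensus, cohort$map, cohort$atlas, top_net)
    list(best_per_mille = pred$summary$per_mille[best],
         consensus = consensus, E = E, rd = rd, degrees = degrees)
  })
  write.table(importance$E, file.path(out_dir, "network_edge_matrix.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  write.table(data.frame(network = names(importance$rd),
                         rd = as.numeric(importance$rd)),
              file.path(out_dir, "relative_degree.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(importance$degrees, file.path(out_dir, "node_degree.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$outputs$network_edge_matrix <- "network_edge_matrix.tsv"
  manifest$outputs$relative_degree <- "relative_degree.tsv"
  manifest$outputs$node_degree <- "node_degree.tsv"

  lesion <- config$lesion %||% FALSE
  if (!identical(lesion, FALSE)) {
    networks <- if (isTRUE(lesion)) NULL else as.character(lesion)
    scan <- run_stage("lesion_scan", function() {
      lesion_scan(cohort$X, cohort$y, cohort$atlas, pcfg,
                  networks = networks)
    })
    scan_tab <- cbind(component = component, scan$summary)
    write.table(scan_tab, file.path(out_dir, "lesion_scan.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs$lesion_scan <- "lesion_scan.tsv"
  }

  manifest$status <- "ok"
  manifest$finished <- format(Sys.time(), tz = "UTC")
  write_manifest()
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
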