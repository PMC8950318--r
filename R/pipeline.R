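#' Pipeline configuration
#'
#' A flat, validated configuration for [run_pipeline()]. Unknown keys are
#' rejected so a typo cannot silently fall back to a default. The whole
#' configuration is echoed into the run manifest, making reruns
#' reproducible from the manifest alone.
#'
#' @param simulate Generate inputs with [simulate_feature_table()]
#'   (`TRUE`) or read them from `input_path`.
#' @param input_path Sample-table CSV/TSV, required when
#'   `simulate = FALSE`.
#' @param out_dir Output directory, created if absent.
#' @param seed Integer seed driving every stochastic stage.
#' @param n_features,n_responders,effect_size,noise_sd,donor_sd Passed to
#'   [simulation_config()] when simulating.
#' @param pseudo Pseudo-intensity for fold changes (`NULL` = data-driven
#'   default).
#' @param lfc_threshold,r_threshold,alpha,dose_encoding Selection gates,
#'   see [select_responders()].
#' @param k_min,k_max Candidate cluster range for [optimal_partition()].
#' @param quiet Suppress progress messages.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, input_path = NULL,
                            out_dir = tempfile("catechoflux_run_"),
                            seed = 1L, n_features = 500, n_responders = 40,
                            effect_size = 2, noise_sd = 0.1, donor_sd = 0.2,
                            pseudo = NULL, lfc_threshold = 1,
                            r_threshold = 0.8, alpha = 0.05,
                            dose_encoding = "ordinal",
                            k_min = 2, k_max = 12, quiet = FALSE) {
  cfg <- as.list(environment())
  if (!simulate && is.null(input_path)) {
    abort("input_path is required when simulate = FALSE")
  }
  if (k_min < 2 || k_max < k_min) abort("invalid cluster range")
  if (alpha <= 0 || alpha > 1) abort("alpha must lie in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys must be a subset of the [pipeline_config()] arguments; unknown keys
#' raise an error naming them.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("missing config file: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

#' Run the dose-response pipeline end to end
#'
#' Executes simulate (or read) -> quantile normalize -> log2 fold change ->
#' select responders -> cluster -> optimal partition, writes every stage
#' table plus a JSON manifest (configuration echo, input hashes, package
#' version) to `config$out_dir`, and returns the results.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list `samples`, `normalized`, `fold_changes`,
#'   `responders`, `partition`, `truth` (when simulated), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  say <- function(stage) {
    if (!config$quiet) {
      message(sprintf("[%s] %.1fs elapsed", stage,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  truth <- NULL
  if (config$simulate) {
    sim <- simulate_feature_table(simulation_config(
      n_features = config$n_features, n_responders = config$n_responders,
      effect_size = config$effect_size, noise_sd = config$noise_sd,
      donor_sd = config$donor_sd, seed = config$seed))
    samples <- sim$samples
    truth <- sim$truth
    say("simulate")
  } else {
    samples <- read_sample_table(config$input_path)
    say("read")
  }
  write_sample_table(samples, file.path(config$out_dir, "samples.csv"))

  normalized <- quantile_normalize(samples)
  write_sample_table(normalized, file.path(config$out_dir, "normalized.csv"))
  say("normalize")

  fc <- log2_fold_change(normalized, pseudo = config$pseudo)
  write_delim_auto(fc, file.path(config$out_dir, "fold_changes.csv"))
  say("foldchange")

  responders <- select_responders(
    fc, normalized, lfc_threshold = config$lfc_threshold,
    r_threshold = config$r_threshold, alpha = config$alpha,
    dose_encoding = config$dose_encoding, pseudo = config$pseudo)
  write_delim_auto(responders, file.path(config$out_dir, "responders.tsv"))
  say("select")

  selected <- selected_features(responders)
  partition <- NULL
  if (length(selected) > max(3, config$k_min)) {
    profiles <- profile_matrix(fc, features = selected)
    k_max <- min(config$k_max, nrow(profiles) - 1)
    partition <- optimal_partition(profiles,
                                   k_range = seq(config$k_min, k_max))
    jsonlite::write_json(
      list(k = partition$k, db_index = partition$db_index,
           labels = as.list(partition$labels),
           db_by_k = partition$db_by_k),
      file.path(config$out_dir, "partition.json"), auto_unbox = TRUE,
      digits = NA)
    say("cluster")
  } else if (!config$quiet) {
    message("too few selected features to cluster; skipping partition")
  }

  if (!is.null(truth)) {
    jsonlite::write_json(
      list(responder_ids = truth$responder_ids,
           archetype_of = as.list(truth$archetype_of)),
      file.path(config$out_dir, "ground_truth.json"), auto_unbox = TRUE)
  }

  manifest <- list(
    package = "catechoflux",
    version = as.character(utils::packageVersion("catechoflux")),
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(
      list.files(config$out_dir, pattern = "\\.(csv|tsv)$",
                 full.names = TRUE))),
    n_selected = length(selected),
    k = if (!is.null(partition)) partition$k else NA
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  say("done")

  invisible(list(samples = samples, normalized = normalized,
                 fold_changes = fc, responders = responders,
                 partition = partition, truth = truth,
                 manifest = manifest))
}

#' Compare a selection against planted ground truth
#'
#' Sensitivity (fraction of planted responders recovered) and precision
#' (fraction of selected features that were planted) of a feature
#' selection.
#'
#' @param selected Character vector of selected feature ids.
#' @param truth Ground-truth list from [simulate_feature_table()] (or any
#'   list with a `responder_ids` element).
#' @return A one-row tibble `sensitivity`, `precision`, `n_selected`,
#'   `n_planted`.
#' @export
selection_performance <- function(selected, truth) {
  planted <- truth$responder_ids
  tp <- length(intersect(selected, planted))
  tibble(
    sensitivity = if (length(planted) == 0) NA_real_ else
      tp / length(planted),
    precision = if (length(selected) == 0) NA_real_ else
      tp / length(selected),
    n_selected = length(selected),
    n_planted = length(planted)
  )
}
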