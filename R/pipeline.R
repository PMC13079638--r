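#' Pipeline configuration
#'
#' Bundles either input paths (survey CSV + codebook) or the synthetic flag
#' with a generator configuration, together with every stage parameter, into
#' a validated object whose hash stamps the output manifest.
#'
#' @param out_dir output directory for the report bundle.
#' @param survey,codebook input file paths (ignored when `synthetic`).
#' @param synthetic generate the dataset instead of reading files.
#' @param generator a `ohs_generator_config` (default
#'   [default_generator_config()]) when `synthetic`.
#' @param seed seed recorded in the manifest and used for the synthetic
#'   dataset (overrides the generator's own seed).
#' @param node_min_prevalence,edge_quantile network-stage parameters.
#' @param alpha significance level for breadth tests.
#' @param crs_weights,cpe_weights composite-score weights.
#' @param k_max,kmeans_seed,restarts clustering-stage parameters.
#' @param power_d,power_target power-analysis parameters.
#' @param missing missingness policy for [load_survey()].
#' @return A validated `ohs_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, survey = NULL, codebook = NULL,
                            synthetic = FALSE, generator = NULL, seed = 42,
                            node_min_prevalence = 0.20, edge_quantile = 0.30,
                            alpha = 0.05,
                            crs_weights = c(es = 0.5, baps = 0.3, ep = 0.2),
                            cpe_weights = c(ir = 0.4, mpe = 0.6),
                            k_max = 8, kmeans_seed = 42, restarts = 10,
                            power_d = 0.5, power_target = 0.80,
                            missing = "error") {
  if (!(edge_quantile > 0 && edge_quantile <= 1))
    stop_ohs("edge_quantile must lie in (0, 1]")
  if (!(node_min_prevalence >= 0 && node_min_prevalence <= 1))
    stop_ohs("node_min_prevalence must lie in [0, 1]")
  if (!(alpha > 0 && alpha < 1)) stop_ohs("alpha must lie in (0, 1)")
  if (abs(sum(crs_weights) - 1) > 1e-9 || abs(sum(cpe_weights) - 1) > 1e-9)
    stop_ohs("composite weights must sum to 1")
  if (k_max < 3) stop_ohs("k_max must be at least 3")
  if (!synthetic) {
    if (is.null(survey) || is.null(codebook))
      stop_ohs("survey and codebook paths are required unless synthetic = TRUE")
    if (!file.exists(survey)) stop_ohs("survey file not found: ", survey)
    if (!file.exists(codebook)) stop_ohs("codebook file not found: ", codebook)
  } else if (is.null(generator)) {
    generator <- default_generator_config(seed = seed)
  }
  structure(list(out_dir = out_dir, survey = survey, codebook = codebook,
                 synthetic = synthetic, generator = generator, seed = seed,
                 node_min_prevalence = node_min_prevalence,
                 edge_quantile = edge_quantile, alpha = alpha,
                 crs_weights = crs_weights, cpe_weights = cpe_weights,
                 k_max = k_max, kmeans_seed = kmeans_seed,
                 restarts = restarts, power_d = power_d,
                 power_target = power_target, missing = missing),
            class = "ohs_pipeline_config")
}

#' Demographic summary table
#'
#' Counts and percentages (rounded half-up to 1 decimal) per level of each
#' categorical demographic variable. Levels absent from the data report
#' 0 (0.0%). Level counts sum to the respondent total within each variable.
#'
#' @param demographics data.frame of categorical fields.
#' @param levels optional named list of controlled vocabularies (e.g. the
#'   codebook's `demographic_levels`) fixing level order.
#' @return data.frame with `variable`, `level`, `n`, `percent`.
#' @export
summarize_demographics <- function(demographics, levels = NULL) {
  total <- nrow(demographics)
  rows <- lapply(names(demographics), function(v) {
    lev <- levels[[v]] %||% sort(unique(demographics[[v]]))
    cnt <- table(factor(demographics[[v]], levels = lev))
    data.frame(variable = v, level = lev, n = as.integer(cnt),
               percent = round_half_up(100 * as.integer(cnt) / total, 1),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or generate the dataset; demographic summary;
#' per-item and per-system symptom tables and burden; co-occurrence network
#' (CSV edge list, GraphML, metrics JSON); risk-factor ranking with
#' per-system p-values; protective-measure ranking with category summary;
#' standardization, elbow selection, K-means at the selected k and cluster
#' profiles; reliability report; power report. Constant system-score
#' columns are dropped from the clustering input with a logged warning.
#' All outputs are written to a staging directory and moved into
#' `out_dir` only on success, so a failed stage leaves no partial bundle;
#' the stage name is reported on error. The JSON manifest records the
#' configuration hash and seeds; identical configurations produce identical
#' bundles.
#'
#' @param config an `ohs_pipeline_config`.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ohs_pipeline_config"))
  stage <- "setup"
  warnings_log <- character()
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, paste0("[", stage, "] ",
                                            conditionMessage(w)))
    invokeRestart("muffleWarning")
  }
  staging <- tempfile("ohs_bundle_")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  result <- withCallingHandlers(
    tryCatch({
      stage <- "load"
      if (config$synthetic) {
        gen <- config$generator
        gen$seed <- as.integer(config$seed)
        cb <- gen$codebook
        ds <- generate_survey(gen)
      } else {
        cb <- load_codebook(config$codebook)
        ds <- load_survey(config$survey, cb, missing = config$missing)
      }
      n <- length(ds$respondent_ids)

      stage <- "demographics"
      demo_tab <- summarize_demographics(ds$demographics,
                                         levels = cb$demographic_levels)

      stage <- "symptoms"
      prev_tab <- item_prevalence(ds$symptoms)
      sev_tab <- severity_scores(ds$symptoms)
      sys_prev <- system_prevalence(ds$symptoms, cb)
      tsb <- total_symptom_burden(ds$symptoms)
      sys <- system_scores(ds$symptoms, cb)
      burden_tab <- data.frame(respondent_id = ds$respondent_ids, tsb = tsb,
                               stringsAsFactors = FALSE)

      stage <- "network"
      net <- cooccurrence_network(ds$symptoms, cb,
                                  node_min_prevalence = config$node_min_prevalence,
                                  edge_quantile = config$edge_quantile)
      export_network(net, graphml = file.path(staging, "network.graphml"),
                     edges_csv = file.path(staging, "network_edges.csv"),
                     metrics_json = file.path(staging, "network_metrics.json"))

      stage <- "risk"
      risk_tab <- rank_risk_factors(ds, cb, alpha = config$alpha,
                                    weights = config$crs_weights)
      system_p <- attr(risk_tab, "system_p")

      stage <- "protection"
      prot_tab <- rank_measures(ds, cb, weights = config$cpe_weights)
      prot_cat <- attr(prot_tab, "category_summary")

      stage <- "clustering"
      keep <- apply(sys, 2, function(col) stats::sd(col) > 0)
      if (!all(keep))
        warning("dropping constant system column(s) before clustering: ",
                paste(colnames(sys)[!keep], collapse = ", "), call. = FALSE)
      z <- standardize_scores(sys[, keep, drop = FALSE])
      el <- elbow(z, k_max = config$k_max, seed = config$kmeans_seed,
                  restarts = config$restarts)
      km <- kmeans_fit(z, el$selected_k, seed = config$kmeans_seed,
                       restarts = config$restarts)
      prof <- cluster_profiles(km$labels, sys, tsb)
      labels_tab <- data.frame(respondent_id = ds$respondent_ids,
                               cluster = prof$labels, stringsAsFactors = FALSE)
      centers_tab <- data.frame(cluster = seq_len(nrow(km$centers)) - 1L,
                                km$centers, check.names = FALSE)

      stage <- "reliability"
      rel_tab <- reliability_report(ds$symptoms, cb)

      stage <- "power"
      n1 <- ceiling(n / 2); n2 <- n - n1
      power_tab <- data.frame(
        d = config$power_d, alpha = config$alpha, n1 = n1, n2 = n2,
        power = posthoc_power(n1, n2, config$power_d, alpha = config$alpha),
        target_power = config$power_target,
        required_total_n = required_sample_size(config$power_target,
                                                config$power_d,
                                                alpha = config$alpha))

      stage <- "report"
      # Hash the analysis parameters, not the destination path.
      cfg_for_hash <- unclass(config)
      cfg_for_hash$out_dir <- NULL
      cfg_for_hash$generator <- if (config$synthetic)
        config$generator[setdiff(names(config$generator), "codebook")]
      hash <- hash_config(cfg_for_hash)
      tables <- list(demographics = demo_tab, item_prevalence = prev_tab,
                     item_severity = sev_tab, system_prevalence = sys_prev,
                     symptom_burden = burden_tab, risk_scores = risk_tab,
                     risk_system_p = system_p, protection_scores = prot_tab,
                     protection_categories = prot_cat,
                     cluster_labels = labels_tab, cluster_centers = centers_tab,
                     cluster_profiles = prof$profiles,
                     wcss_curve = el$wcss_curve, reliability = rel_tab,
                     power = power_tab)
      manifest <- write_results(tables, staging, config_hash = hash)
      manifest$seed <- config$seed
      manifest$kmeans_seed <- config$kmeans_seed
      manifest$n_respondents <- n
      manifest$selected_k <- el$selected_k
      manifest$warnings <- warnings_log
      manifest$extra_files <- c("network.graphml", "network_edges.csv",
                                "network_metrics.json")
      jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      manifest
    }, error = function(e) {
      stop_ohs("pipeline failed at stage '", stage, "': ",
               conditionMessage(e))
    }),
    warning = log_warning)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in list.files(staging))
    file.copy(file.path(staging, f), file.path(config$out_dir, f),
              overwrite = TRUE)
  invisible(result)
}
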