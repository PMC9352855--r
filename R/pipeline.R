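# End-to-end orchestration: simulate (or load) -> two-stage search ->
# network metrics -> multimodal correlations, with a reproducible output
# bundle and manifest.

#' Pipeline configuration
#'
#' @param seed Master integer seed. Stage seeds are derived from it
#'   (truth: `seed`, simulation: `seed + 1`, covariates: `seed + 2`), so
#'   identical configurations and seeds reproduce every output.
#' @param outdir Output directory for the report bundle.
#' @param generator A [truth_config()] (ignored when `input_dir` is
#'   given).
#' @param hormones A [hormone_behavior_params()].
#' @param search A [search_config()].
#' @param count_ar_in Counting rule for AR paths in
#'   [compute_metrics()].
#' @param correlation_method `"pearson"` or `"spearman"`.
#' @param input_dir Optional existing dataset directory
#'   ([load_dataset()]); when given, no data are simulated.
#' @param write_inputs Write the simulated dataset under
#'   `outdir/data/`.
#' @param log_level One of `"debug"`, `"info"`, `"warn"`, `"quiet"`.
#'
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            outdir = tempfile("usemnet_run_"),
                            generator = truth_config(),
                            hormones = hormone_behavior_params(),
                            search = search_config(),
                            count_ar_in = c("complexity", "densities", "neither"),
                            correlation_method = c("pearson", "spearman"),
                            input_dir = NULL,
                            write_inputs = TRUE,
                            log_level = c("warn", "info", "debug", "quiet")) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) || seed != round(seed)) {
    config_error("seed must be a single integer")
  }
  if (abs(seed) > .Machine$integer.max - 10L) config_error("seed is out of integer range")
  if (!inherits(generator, "truth_config")) config_error("generator must be a truth_config()")
  if (!inherits(hormones, "hb_params")) config_error("hormones must be hormone_behavior_params()")
  if (!inherits(search, "search_config")) config_error("search must be a search_config()")
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    config_error(sprintf("input_dir '%s' does not exist", input_dir))
  }
  structure(
    list(
      seed = as.integer(seed),
      outdir = outdir,
      generator = generator,
      hormones = hormones,
      search = search,
      count_ar_in = match.arg(count_ar_in),
      correlation_method = match.arg(correlation_method),
      input_dir = input_dir,
      write_inputs = isTRUE(write_inputs),
      log_level = match.arg(log_level)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `generator`,
#' `search` and `hormones` are nested maps passed to [truth_config()],
#' [search_config()] and [hormone_behavior_params()]. A `generator$rois`
#' map with `labels` and `membership` vectors defines a custom ROI set.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file '%s' does not exist", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) config_error("config file must contain a mapping")

  call_with <- function(fun, args) {
    if (is.null(args)) args <- list()
    known <- intersect(names(args), names(formals(fun)))
    unknown <- setdiff(names(args), names(formals(fun)))
    if (length(unknown)) {
      config_error(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
    }
    do.call(fun, lapply(args[known], function(x) if (is.list(x)) unlist(x) else x))
  }

  gen_args <- raw$generator
  if (!is.null(gen_args$rois)) {
    gen_args$rois <- roi_set(
      unlist(gen_args$rois$labels),
      stats::setNames(unlist(gen_args$rois$membership), unlist(gen_args$rois$labels))
    )
  }
  generator <- if (is.null(gen_args)) truth_config() else {
    rois <- gen_args$rois
    gen_args$rois <- NULL
    args <- c(if (!is.null(rois)) list(rois = rois), gen_args)
    known <- intersect(names(args), names(formals(truth_config)))
    unknown <- setdiff(names(args), names(formals(truth_config)))
    if (length(unknown)) {
      config_error(sprintf("unknown generator field(s): %s", paste(unknown, collapse = ", ")))
    }
    do.call(truth_config, lapply(args[known], function(x) {
      if (is.list(x) && is.null(names(x))) unlist(x) else if (is.list(x)) unlist(x) else x
    }))
  }

  top <- raw[setdiff(names(raw), c("generator", "search", "hormones"))]
  unknown <- setdiff(names(top), names(formals(pipeline_config)))
  if (length(unknown)) {
    config_error(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, c(
    top,
    list(
      generator = generator,
      search = call_with(search_config, raw$search),
      hormones = call_with(hormone_behavior_params, raw$hormones)
    )
  ))
}

config_as_json <- function(config) {
  cfg <- unclass(config)
  cfg$generator <- unclass(cfg$generator)
  cfg$search <- unclass(cfg$search)
  cfg$hormones <- unclass(cfg$hormones)
  cfg$generator$rois <- list(
    labels = config$generator$rois$labels,
    membership = unname(config$generator$rois$membership)
  )
  jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
}

#' Run the full pipeline: simulate/load, search, metrics, correlate
#'
#' Executes every stage and writes a report bundle under
#' `config$outdir`: the (simulated) input data, the group structure and
#' per-participant edge lists, fit indices, network metrics with sample
#' summary, covariate descriptives, the multimodal correlation matrix,
#' the search traces, and a `manifest.json` with the seed, configuration
#' checksum, package and R versions, per-stage timings, and checksums of
#' every output — enough to verify a bit-identical rerun of the
#' deterministic stages.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the truth (when simulated), dataset,
#'   search result, metrics, summaries, correlation matrix, and output
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config_error("config must be a pipeline_config()")
  old_opt <- options(usemnet.log_level = config$log_level)
  on.exit(options(old_opt))

  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "networks"), recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  stamp <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, usemnet_error = function(e) {
      usem_abort(class(e)[1], sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  cfg_path <- file.path(outdir, "config.json")
  writeLines(config_as_json(config), cfg_path)

  data_stage <- stamp("data", {
    if (!is.null(config$input_dir)) {
      list(dataset = load_dataset(config$input_dir), truth = NULL)
    } else {
      truth <- generate_truth(config$generator, config$seed)
      ts <- simulate_timeseries(truth, seed = config$seed + 1L)
      covariates <- generate_covariates(truth, config$hormones, seed = config$seed + 2L)
      if (config$write_inputs) {
        write_dataset(file.path(outdir, "data"), ts, config$generator$rois,
          covariates = covariates, truth = truth)
      }
      list(
        dataset = structure(
          list(
            ts = ts, rois = config$generator$rois, covariates = covariates,
            run_lengths = lapply(ts, function(x) vapply(x$runs, nrow, 0L))
          ),
          class = "usem_dataset"
        ),
        truth = truth
      )
    }
  })
  dataset <- data_stage$dataset
  truth <- data_stage$truth

  search <- stamp("search", run_sample_search(dataset, config$search))
  metrics <- stamp("metrics", sample_metrics(search$networks, dataset$rois,
    count_ar_in = config$count_ar_in))
  summary_tab <- summarize_sample(metrics)

  correlations <- NULL
  descriptives <- NULL
  if (!is.null(dataset$covariates)) {
    correlations <- stamp("correlate", correlate_multimodal(
      dataset$covariates, metrics, method = config$correlation_method))
    descriptives <- describe_sample(dataset$covariates)
  }

  stamp("write", {
    write_csv_plain(search$group_structure$paths, file.path(outdir, "group_structure.csv"))
    all_edges <- do.call(rbind, lapply(search$networks, network_edge_table))
    rownames(all_edges) <- NULL
    write_csv_plain(all_edges, file.path(outdir, "networks.csv"))
    for (nw in search$networks) {
      write_csv_plain(
        network_edge_table(nw),
        file.path(outdir, "networks", sprintf("%s_edges.csv", nw$participant_id))
      )
    }
    write_csv_plain(fit_index_table(search$networks), file.path(outdir, "fit_indices.csv"))
    write_csv_plain(metrics, file.path(outdir, "metrics.csv"))
    write_csv_plain(summary_tab, file.path(outdir, "metrics_summary.csv"))
    if (!is.null(descriptives)) {
      write_csv_plain(descriptives, file.path(outdir, "descriptives.csv"))
    }
    if (!is.null(correlations)) {
      r_df <- data.frame(variable = rownames(correlations$r), correlations$r,
        check.names = FALSE, stringsAsFactors = FALSE)
      write_csv_plain(r_df, file.path(outdir, "correlations.csv"))
      n_df <- data.frame(variable = rownames(correlations$n), correlations$n,
        check.names = FALSE, stringsAsFactors = FALSE)
      write_csv_plain(n_df, file.path(outdir, "correlation_n.csv"))
    }
    jsonlite::write_json(
      list(group = search$group_trace, individual = search$individual_traces),
      file.path(outdir, "trace.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows"
    )
  })

  outputs <- sort(setdiff(
    list.files(outdir, recursive = TRUE),
    "manifest.json"
  ))
  manifest <- list(
    package = "usemnet",
    package_version = as.character(utils::packageVersion("usemnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_file = "config.json",
    config_md5 = unname(tools::md5sum(cfg_path)),
    timings_sec = timings,
    outputs = lapply(stats::setNames(outputs, outputs), function(f) {
      unname(tools::md5sum(file.path(outdir, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    truth = truth, dataset = dataset, search = search,
    metrics = metrics, metrics_summary = summary_tab,
    descriptives = descriptives, correlations = correlations,
    outdir = outdir, manifest = manifest
  ))
}
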