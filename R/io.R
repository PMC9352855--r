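# Delimited-text input and output: time-series runs, ROI tables, truth
# edge lists, covariates, estimated networks, metrics, correlations.

write_csv_plain <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic (or loaded) dataset as delimited text
#'
#' Lays out a dataset directory: one CSV per run under `timeseries/`
#' (rows = time points, columns = labeled ROIs, header mandatory), an
#' ROI-membership table `rois.csv`, optionally `covariates.csv`, and —
#' when a synthetic truth is supplied — `truth_edges.csv` (participant,
#' source, target, lag, level, weight) with a JSON sidecar `truth.json`
#' holding the seed and generator configuration.
#'
#' @param dir Output directory (created if needed).
#' @param ts_list Named list of [participant_ts()] objects.
#' @param rois An [roi_set()].
#' @param covariates Optional covariate data frame
#'   ([generate_covariates()]).
#' @param truth Optional [generate_truth()] result.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dir, ts_list, rois, covariates = NULL, truth = NULL) {
  tsdir <- file.path(dir, "timeseries")
  dir.create(tsdir, recursive = TRUE, showWarnings = FALSE)
  for (ts in ts_list) {
    for (k in seq_along(ts$runs)) {
      run <- as.data.frame(ts$runs[[k]])
      names(run) <- ts$labels %||% rois$labels
      write_csv_plain(run, file.path(tsdir, sprintf("%s_run%d.csv", ts$participant_id, k)))
    }
  }
  roi_df <- data.frame(
    label = rois$labels, network = unname(rois$membership),
    stringsAsFactors = FALSE
  )
  if (!is.null(rois$coordinates)) {
    roi_df <- cbind(roi_df, as.data.frame(rois$coordinates))
    names(roi_df)[3:5] <- c("x", "y", "z")
  }
  write_csv_plain(roi_df, file.path(dir, "rois.csv"))
  if (!is.null(covariates)) {
    write_csv_plain(covariates, file.path(dir, "covariates.csv"))
  }
  if (!is.null(truth)) {
    write_csv_plain(truth_edges(truth), file.path(dir, "truth_edges.csv"))
    cfg <- unclass(truth$config)
    cfg$rois <- list(labels = truth$rois$labels, membership = unname(truth$rois$membership))
    jsonlite::write_json(
      list(seed = truth$seed, config = cfg),
      file.path(dir, "truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(dir)
}

read_roi_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "network") %in% names(df))) {
    load_error(sprintf("%s must have columns label, network", path))
  }
  coords <- if (all(c("x", "y", "z") %in% names(df))) as.matrix(df[, c("x", "y", "z")])
  roi_set(df$label, stats::setNames(df$network, df$label), coordinates = coords)
}

#' Load a dataset directory of time-series runs and covariates
#'
#' Reads the layout written by [write_dataset()]: run CSVs named
#' `<participant>_run<k>.csv` under `timeseries/`, an optional
#' `rois.csv`, and an optional `covariates.csv`. Headers must match the
#' ROI set exactly (any unknown column is a load error naming the file
#' and column); ragged rows and non-numeric cells are load errors naming
#' the file and line. Run boundaries are preserved. Participants without
#' covariate rows are kept and flagged in the `missing_covariates`
#' attribute.
#'
#' @param dir Dataset directory.
#' @param rois Optional [roi_set()] overriding `rois.csv`; when neither
#'   is available the header of the first run defines an error.
#' @return A list of class `usem_dataset` with `ts`, `rois`,
#'   `covariates`, `run_lengths`.
#' @export
load_dataset <- function(dir, rois = NULL) {
  if (!dir.exists(dir)) load_error(sprintf("dataset directory '%s' does not exist", dir))
  roi_path <- file.path(dir, "rois.csv")
  if (is.null(rois)) {
    if (!file.exists(roi_path)) {
      load_error(sprintf("no ROI definition: supply `rois` or provide %s", roi_path))
    }
    rois <- read_roi_csv(roi_path)
  }
  tsdir <- file.path(dir, "timeseries")
  files <- sort(list.files(tsdir, pattern = "\\.csv$"))
  if (!length(files)) load_error(sprintf("no run CSVs found under %s", tsdir))
  m <- regmatches(files, regexec("^(.+)_run(\\d+)\\.csv$", files))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) {
    load_error(sprintf(
      "file name(s) not matching '<participant>_run<k>.csv': %s",
      paste(files[bad], collapse = ", ")
    ))
  }
  pid <- vapply(m, `[`, "", 2L)
  runno <- as.integer(vapply(m, `[`, "", 3L))

  read_run <- function(f) {
    path <- file.path(tsdir, f)
    df <- tryCatch(
      utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) load_error(sprintf("failed to read %s: %s", path, conditionMessage(e)))
    )
    unknown <- setdiff(names(df), rois$labels)
    if (length(unknown)) {
      load_error(sprintf("%s: unknown ROI column '%s'", path, unknown[1]))
    }
    if (!setequal(names(df), rois$labels)) {
      load_error(sprintf(
        "%s: header does not cover the ROI set (missing %s)",
        path, paste(setdiff(rois$labels, names(df)), collapse = ", ")
      ))
    }
    df <- df[, rois$labels, drop = FALSE]
    for (v in names(df)) {
      if (!is.numeric(df[[v]])) {
        line <- which(is.na(suppressWarnings(as.numeric(df[[v]]))))[1]
        load_error(sprintf(
          "%s: non-numeric value in column '%s' at data line %d", path, v,
          if (is.na(line)) 1L else line
        ))
      }
      if (anyNA(df[[v]])) {
        load_error(sprintf(
          "%s: missing value in column '%s' at data line %d", path, v, which(is.na(df[[v]]))[1]
        ))
      }
    }
    as.matrix(df)
  }

  ids <- unique(pid)
  ts <- lapply(ids, function(id) {
    sel <- which(pid == id)
    sel <- sel[order(runno[sel])]
    participant_ts(id, lapply(files[sel], read_run))
  })
  names(ts) <- ids
  run_lengths <- lapply(ts, function(x) vapply(x$runs, nrow, 0L))

  cov_path <- file.path(dir, "covariates.csv")
  covariates <- NULL
  missing_cov <- character(0)
  if (file.exists(cov_path)) {
    covariates <- utils::read.csv(cov_path, stringsAsFactors = FALSE)
    if (!"participant_id" %in% names(covariates)) {
      load_error(sprintf("%s must have a participant_id column", cov_path))
    }
    missing_cov <- setdiff(ids, covariates$participant_id)
    if (length(missing_cov)) {
      log_msg("warn", "participants without covariates: ", paste(missing_cov, collapse = ", "))
    }
  }

  out <- structure(
    list(ts = ts, rois = rois, covariates = covariates, run_lengths = run_lengths),
    class = "usem_dataset"
  )
  attr(out, "missing_covariates") <- missing_cov
  out
}

#' @export
print.usem_dataset <- function(x, ...) {
  cat(sprintf(
    "uSEM dataset: %d participants, %d ROIs, runs per participant: %s\n",
    length(x$ts), length(x$rois$labels),
    paste(unique(vapply(x$run_lengths, function(r) paste(r, collapse = "+"), "")), collapse = "; ")
  ))
  invisible(x)
}

# Long edge table of an estimated network (one row per path).
network_edge_table <- function(network) {
  cbind(
    data.frame(participant = network$participant_id, stringsAsFactors = FALSE),
    network$estimates
  )
}

# One fit-index row per participant.
fit_index_table <- function(networks) {
  out <- lapply(networks, function(nw) {
    f <- nw$fit
    data.frame(
      participant = nw$participant_id, chi2 = f$chi2, df = f$df,
      pvalue = f$pvalue, rmsea = f$rmsea, srmr = f$srmr,
      cfi = f$cfi, nnfi = f$nnfi, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
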