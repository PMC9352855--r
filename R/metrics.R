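# Network complexity and subnetwork density metrics.

#' Complexity and subnetwork densities of a person's network
#'
#' Complexity is the total number of estimated connections. Each non-AR
#' connection is classified by the subnetwork membership of its
#' endpoints: within-MRN when both ROIs belong to the MRN, within-DMN
#' when both belong to the DMN, and between-network otherwise; lag-0 and
#' lag-1 connections count identically. Densities are the counts divided
#' by complexity.
#'
#' Under the default counting rule (`count_ar_in = "complexity"`) the
#' lag-1 self (AR) paths count toward complexity but toward none of the
#' three subnetwork counts, so the three densities sum to less than one
#' and the counts (including AR) sum to complexity. `"densities"` also
#' credits each AR path to its own subnetwork's count; `"neither"`
#' excludes AR paths everywhere.
#'
#' @param network A [fit_usem()] `person_network` or a
#'   [network_structure()].
#' @param rois An [roi_set()] giving the MRN/DMN membership.
#' @param count_ar_in Counting rule for AR self-paths (see Details).
#'
#' @return A one-row data frame of class `network_metrics` with the
#'   participant id, `complexity`, the three densities, and the raw
#'   counts. When complexity is 0 the densities are 0 and the attribute
#'   `degenerate` is set.
#' @export
compute_metrics <- function(network, rois,
                            count_ar_in = c("complexity", "densities", "neither")) {
  count_ar_in <- match.arg(count_ar_in)
  if (inherits(network, "person_network")) {
    paths <- network$structure$paths
    pid <- network$participant_id
  } else if (inherits(network, "network_structure")) {
    paths <- network$paths
    pid <- NA_character_
  } else {
    input_error("network must be a person_network or network_structure")
  }
  if (!inherits(rois, "roi_set")) input_error("rois must be a roi_set")
  unknown <- setdiff(unique(c(paths$source, paths$target)), rois$labels)
  if (length(unknown)) {
    input_error(sprintf("unknown ROI label(s): %s", paste(unknown, collapse = ", ")))
  }

  is_ar <- paths$source == paths$target & paths$lag == 1L
  mem_s <- rois$membership[paths$source]
  mem_t <- rois$membership[paths$target]
  block <- ifelse(mem_s == "MRN" & mem_t == "MRN", "mrn",
    ifelse(mem_s == "DMN" & mem_t == "DMN", "dmn", "between")
  )

  n_ar <- sum(is_ar)
  n_mrn <- sum(!is_ar & block == "mrn")
  n_dmn <- sum(!is_ar & block == "dmn")
  n_btw <- sum(!is_ar & block == "between")
  if (count_ar_in == "densities") {
    n_mrn <- n_mrn + sum(is_ar & block == "mrn")
    n_dmn <- n_dmn + sum(is_ar & block == "dmn")
  }
  complexity <- if (count_ar_in == "neither") n_mrn + n_dmn + n_btw else nrow(paths)

  degenerate <- complexity == 0L
  dens <- function(k) if (degenerate) 0 else k / complexity
  out <- data.frame(
    participant_id = pid,
    complexity = as.integer(complexity),
    density_mrn = dens(n_mrn),
    density_dmn = dens(n_dmn),
    density_between = dens(n_btw),
    n_within_mrn = as.integer(n_mrn),
    n_within_dmn = as.integer(n_dmn),
    n_between = as.integer(n_btw),
    n_ar = as.integer(n_ar),
    stringsAsFactors = FALSE
  )
  class(out) <- c("network_metrics", class(out))
  attr(out, "degenerate") <- degenerate
  attr(out, "count_ar_in") <- count_ar_in
  out
}

#' Metrics for every network in a sample
#'
#' @param networks A named list of `person_network`s (e.g.
#'   `run_sample_search()$networks`).
#' @inheritParams compute_metrics
#' @return A data frame with one [compute_metrics()] row per participant.
#' @export
sample_metrics <- function(networks, rois,
                           count_ar_in = c("complexity", "densities", "neither")) {
  count_ar_in <- match.arg(count_ar_in)
  out <- do.call(rbind, lapply(networks, compute_metrics, rois = rois,
    count_ar_in = count_ar_in))
  rownames(out) <- NULL
  out
}

#' Sample means and standard deviations of network metrics
#'
#' @param metrics A data frame of per-participant metrics
#'   ([sample_metrics()]).
#' @return A data frame with columns `metric`, `mean`, `sd` (sample SD,
#'   n-1 denominator) for complexity and the three densities.
#' @export
summarize_sample <- function(metrics) {
  metrics <- as.data.frame(metrics)
  if (nrow(metrics) < 2L) input_error("summaries need at least 2 participants")
  vars <- c("complexity", "density_mrn", "density_dmn", "density_between")
  data.frame(
    metric = vars,
    mean = vapply(vars, function(v) mean(metrics[[v]]), 0),
    sd = vapply(vars, function(v) stats::sd(metrics[[v]]), 0),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
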