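# Joining hormone/behavior records with network metrics: descriptives
# and the multimodal correlation matrix.

multimodal_vars <- c("estradiol", "progesterone", "testosterone", "pct_correct")
metric_vars <- c("complexity", "density_mrn", "density_dmn", "density_between")

validate_records <- function(records) {
  records <- as.data.frame(records)
  need <- c("participant_id", multimodal_vars)
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    input_error(sprintf("records are missing column(s): %s", paste(missing, collapse = ", ")))
  }
  for (v in c("estradiol", "progesterone", "testosterone")) {
    if (any(records[[v]] < 0, na.rm = TRUE)) input_error(sprintf("%s must be nonnegative", v))
  }
  if (any(records$pct_correct < 0 | records$pct_correct > 100, na.rm = TRUE)) {
    input_error("pct_correct must lie in [0, 100]")
  }
  records
}

#' Descriptive statistics of hormone and behavior records
#'
#' @param records A data frame with columns `participant_id`,
#'   `estradiol`, `progesterone`, `testosterone` (pg/mL) and
#'   `pct_correct` (mental rotations % correct).
#' @return A data frame with columns `variable`, `mean`, `sd` (sample
#'   SD).
#' @export
describe_sample <- function(records) {
  records <- validate_records(records)
  if (nrow(records) < 2L) input_error("descriptives need at least 2 records")
  data.frame(
    variable = multimodal_vars,
    mean = vapply(multimodal_vars, function(v) mean(records[[v]], na.rm = TRUE), 0),
    sd = vapply(multimodal_vars, function(v) stats::sd(records[[v]], na.rm = TRUE), 0),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Correlations among behavior, hormones, and network metrics
#'
#' Joins the hormone/behavior records with the per-participant network
#' metrics on `participant_id` (the join must be total) and computes the
#' pairwise correlation matrix among task performance, the three
#' hormones, network complexity, and the three subnetwork densities.
#' Missing values are handled pairwise-complete, with the per-cell n
#' recorded. Zero-variance variables yield missing coefficients with a
#' warning.
#'
#' @param records See [describe_sample()].
#' @param metrics Per-participant metrics ([sample_metrics()]).
#' @param method `"pearson"` (default) or `"spearman"`.
#'
#' @return An object of class `correlation_matrix`: list with the
#'   symmetric coefficient matrix `r` (unit diagonal), per-cell counts
#'   `n`, and `method`.
#' @export
correlate_multimodal <- function(records, metrics, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  records <- validate_records(records)
  metrics <- as.data.frame(metrics)
  joined <- merge(records, metrics, by = "participant_id", all = FALSE)
  if (nrow(joined) < nrow(records) || nrow(joined) < nrow(metrics)) {
    input_error("join on participant_id must be total: some participants are unmatched")
  }
  if (nrow(joined) < 3L) input_error("correlations need at least 3 joined rows")
  vars <- c("pct_correct", "estradiol", "progesterone", "testosterone", metric_vars)
  X <- as.matrix(joined[, vars])
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  flat <- vars[!is.na(sds) & sds == 0]
  if (length(flat)) {
    warning(sprintf(
      "zero-variance variable(s): %s; their correlations are undefined",
      paste(flat, collapse = ", ")
    ), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs", method = method))
  r[flat, ] <- NA_real_
  r[, flat] <- NA_real_
  diag(r) <- 1
  n <- crossprod(!is.na(X))
  structure(
    list(r = r, n = n, method = method, variables = vars),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Multimodal %s correlation matrix (%d variables):\n", x$method, ncol(x$r)))
  print(round(x$r, digits))
  invisible(x)
}

#' Heatmap of a multimodal correlation matrix
#'
#' Base-graphics red-to-blue heatmap: dark red for strong inverse
#' relations through dark blue for strong positive relations.
#'
#' @param x A [correlate_multimodal()] result.
#' @param ... Ignored.
#' @export
plot.correlation_matrix <- function(x, ...) {
  r <- x$r
  k <- ncol(r)
  pal <- grDevices::colorRampPalette(c("#67001F", "#F7F7F7", "#053061"))(201)
  op <- graphics::par(mar = c(7, 7, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(
    seq_len(k), seq_len(k), t(r[rev(seq_len(k)), , drop = FALSE]),
    zlim = c(-1, 1), col = pal, axes = FALSE, xlab = "", ylab = ""
  )
  graphics::axis(1, at = seq_len(k), labels = colnames(r), las = 2, cex.axis = 0.8)
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(r)), las = 2, cex.axis = 0.8)
  graphics::box()
  invisible(x)
}
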