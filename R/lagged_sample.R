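# Per-participant time series and the lagged sample they induce.

#' Bundle one participant's runs of ROI time series
#'
#' @param participant_id Character scalar.
#' @param runs List of numeric matrices, one per acquisition run; rows are
#'   time points (volumes), columns are ROIs in a shared order. Column
#'   names, when present, must agree across runs.
#'
#' @return An object of class `participant_ts`.
#' @export
participant_ts <- function(participant_id, runs) {
  if (!is.list(runs) || !length(runs)) input_error("runs must be a non-empty list of matrices")
  runs <- lapply(runs, function(r) {
    r <- as.matrix(r)
    storage.mode(r) <- "double"
    r
  })
  p <- ncol(runs[[1]])
  labels <- colnames(runs[[1]])
  for (i in seq_along(runs)) {
    if (ncol(runs[[i]]) != p) input_error("all runs must share the same number of ROI columns")
    if (!is.null(labels) && !is.null(colnames(runs[[i]])) &&
      !identical(colnames(runs[[i]]), labels)) {
      input_error("run column names disagree across runs")
    }
    if (anyNA(runs[[i]])) {
      input_error(sprintf(
        "missing values in run %d of participant %s", i, participant_id
      ))
    }
  }
  structure(
    list(participant_id = as.character(participant_id), runs = runs, labels = labels),
    class = "participant_ts"
  )
}

#' @export
print.participant_ts <- function(x, ...) {
  cat(sprintf(
    "Participant %s: %d run(s) of lengths %s, %d ROIs\n",
    x$participant_id, length(x$runs),
    paste(vapply(x$runs, nrow, 0L), collapse = ", "), ncol(x$runs[[1]])
  ))
  invisible(x)
}

#' Build the lagged sample for uSEM estimation
#'
#' Pairs each time point with its predecessor *within a run* (no lagged
#' pair spans a run boundary), stacks the pairs over runs, mean-centers
#' each column over the pooled sample, and summarizes the result by its
#' covariance matrix. The 2p-dimensional observation is
#' `(eta[t-1], eta[t])`: columns `1..p` are the lagged block, columns
#' `p+1..2p` the current block. The effective sample size is
#' `sum(T_r - 1)` over runs.
#'
#' @param ts A [participant_ts()] (or a single numeric matrix, treated as
#'   one run).
#'
#' @return An object of class `lagged_sample` with elements `C` (2p x 2p
#'   covariance, n-1 denominator), `n_eff`, `p`, `labels`,
#'   `participant_id`, and cached baseline quantities.
#' @export
build_lagged_sample <- function(ts) {
  if (is.matrix(ts)) ts <- participant_ts("participant", list(ts))
  if (!inherits(ts, "participant_ts")) input_error("ts must be a participant_ts or matrix")
  lens <- vapply(ts$runs, nrow, 0L)
  if (any(lens < 2L)) {
    input_error(sprintf(
      "every run needs at least 2 time points (run lengths: %s)",
      paste(lens, collapse = ", ")
    ))
  }
  p <- ncol(ts$runs[[1]])
  blocks <- lapply(ts$runs, function(r) cbind(r[-nrow(r), , drop = FALSE],
                                             r[-1, , drop = FALSE]))
  Z <- do.call(rbind, blocks)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  n_eff <- nrow(Z)
  labels <- ts$labels %||% paste0("V", seq_len(p))
  colnames(Z) <- c(paste0(labels, "_lag1"), labels)
  C <- crossprod(Z) / (n_eff - 1)

  i1 <- seq_len(p)
  i2 <- p + i1
  S11 <- C[i1, i1, drop = FALSE]
  S22 <- C[i2, i2, drop = FALSE]
  S21 <- C[i2, i1, drop = FALSE]
  # conditional covariance of the current block given the lagged block
  S221 <- S22 - S21 %*% solve(S11, t(S21))
  ld <- determinant(S221, logarithm = TRUE)
  if (ld$sign <= 0) {
    input_error("lagged sample covariance is singular; series too short or collinear")
  }
  logdet_s221 <- as.numeric(ld$modulus)
  baseline_F <- sum(log(diag(S22))) - logdet_s221

  structure(
    list(
      C = C, n_eff = n_eff, p = p, labels = labels,
      participant_id = ts$participant_id,
      run_lengths = lens,
      logdet_s221 = logdet_s221,
      baseline_F = baseline_F
    ),
    class = "lagged_sample"
  )
}

#' @export
print.lagged_sample <- function(x, ...) {
  cat(sprintf(
    "Lagged sample for %s: %d ROIs, effective N = %d (runs %s)\n",
    x$participant_id, x$p, x$n_eff, paste(x$run_lengths, collapse = ", ")
  ))
  invisible(x)
}
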