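# Synthetic study generator: a known uSEM truth (shared group structure
# plus person-unique paths, individualized weights), time series simulated
# from it, and hormone/behavior covariates with plantable coupling to the
# networks. Stands in for the restricted participant data so that every
# downstream stage is testable against a known ground truth.

#' Generator settings for a synthetic study
#'
#' Defaults reproduce the study design emulated by the package: 11
#' participants, the default 10-ROI set (6 MRN, 4 DMN), two runs of 134
#' volumes, 12 group-level non-AR paths (6 within-MRN, 3 within-DMN, 3
#' between-network), 10-15 individual paths per person placed with block
#' probabilities 0.48/0.24/0.28, path weights of magnitude 0.3-0.6 with
#' random sign, positive AR weights 0.3-0.6, and unit innovation
#' variances — so that total estimated connections land near a complexity
#' of about 35 with within-MRN density exceeding the between-network and
#' within-DMN densities.
#'
#' @param n_participants Number of participants.
#' @param rois An [roi_set()].
#' @param run_lengths Integer vector of run lengths (volumes per run).
#' @param group_counts Named integer vector `c(mrn=, dmn=, between=)` of
#'   group-level non-AR path counts per block.
#' @param individual_range Inclusive integer range for the number of
#'   person-unique paths per participant.
#' @param individual_block_probs Block placement probabilities for
#'   individual paths.
#' @param prop_lagged Probability that a sampled non-AR path is lagged
#'   (lag 1) rather than contemporaneous (lag 0).
#' @param weight_range Magnitude range (subset of (0, 1)) for non-AR path
#'   weights; signs are random.
#' @param ar_range Magnitude range for the (positive) AR weights.
#' @param noise_var Innovation variance, scalar or per-ROI vector
#'   (diagonal Psi).
#' @param allow_reciprocal Allow both contemporaneous directions of a
#'   pair in the same truth (default `FALSE`).
#' @param spectral_bound Rejection bound on the spectral radius of the
#'   lag-1 companion system (stationarity margin, strictly below 1).
#' @param max_tries Weight resampling attempts per participant before a
#'   generation error.
#'
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(n_participants = 11L,
                         rois = default_roi_set(),
                         run_lengths = c(134L, 134L),
                         group_counts = c(mrn = 6L, dmn = 3L, between = 3L),
                         individual_range = c(10L, 15L),
                         individual_block_probs = c(mrn = 0.48, dmn = 0.24, between = 0.28),
                         prop_lagged = 0.25,
                         weight_range = c(0.3, 0.6),
                         ar_range = c(0.3, 0.6),
                         noise_var = 1,
                         allow_reciprocal = FALSE,
                         spectral_bound = 0.95,
                         max_tries = 200L) {
  cfg <- list(
    n_participants = as.integer(n_participants), rois = rois,
    run_lengths = as.integer(run_lengths),
    group_counts = group_counts,
    individual_range = as.integer(individual_range),
    individual_block_probs = individual_block_probs,
    prop_lagged = prop_lagged,
    weight_range = weight_range, ar_range = ar_range,
    noise_var = noise_var,
    allow_reciprocal = isTRUE(allow_reciprocal),
    spectral_bound = spectral_bound,
    max_tries = as.integer(max_tries)
  )
  class(cfg) <- "truth_config"
  cfg
}

# All admissible non-AR paths, classified by subnetwork block.
path_pool <- function(rois, prop_lagged) {
  labels <- rois$labels
  grid <- expand.grid(
    source = labels, target = labels, lag = c(0L, 1L),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[grid$source != grid$target, , drop = FALSE]
  ms <- rois$membership[grid$source]
  mt <- rois$membership[grid$target]
  grid$block <- ifelse(ms == "MRN" & mt == "MRN", "mrn",
    ifelse(ms == "DMN" & mt == "DMN", "dmn", "between")
  )
  grid$weight <- ifelse(grid$lag == 1L, prop_lagged, 1 - prop_lagged)
  rownames(grid) <- NULL
  grid
}

# Draw `n` paths (without replacement) from the pool rows `eligible`,
# honoring taken paths and, optionally, forbidding contemporaneous
# reciprocals of already-taken lag-0 paths. `use_count` (uses of each
# pool slot by other participants) down-weights already-used slots so
# that individual-level paths stay person-unique wherever the pool
# allows it.
draw_paths <- function(pool, eligible, n, taken_keys, allow_reciprocal,
                       use_count = NULL) {
  picked <- integer(0)
  keys <- sprintf("%d:%s>%s", pool$lag, pool$source, pool$target)
  rev0 <- sprintf("%d:%s>%s", pool$lag, pool$target, pool$source)
  for (k in seq_len(n)) {
    ok <- eligible & !(keys %in% taken_keys)
    if (!allow_reciprocal) {
      ok <- ok & !(pool$lag == 0L & rev0 %in% taken_keys)
    }
    idx <- which(ok)
    if (!length(idx)) {
      config_error("requested path counts are infeasible for this ROI set")
    }
    w <- pool$weight[idx]
    if (!is.null(use_count)) {
      # relative down-weighting, anchored at the least-used eligible slot
      # so the weights cannot underflow for large samples
      u <- use_count[idx] - min(use_count[idx])
      w <- w * 0.25^pmin(u, 300L)
    }
    j <- if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L, prob = w)]
    picked <- c(picked, j)
    taken_keys <- c(taken_keys, keys[j])
  }
  list(rows = picked, taken_keys = taken_keys)
}

#' Generate a synthetic uSEM ground truth
#'
#' Samples a shared group-level directed structure and person-unique
#' additions, then draws individualized weights for every participant,
#' rejection-resampling until each participant's system is stationary
#' (spectral radius of the induced lag-1 system strictly below the
#' configured bound) and `(I - A)` is invertible. Every participant's
#' path set is a superset of the group paths, contains all lag-1
#' self-paths (AR), and contains no contemporaneous self-path.
#'
#' @param config A [truth_config()].
#' @param seed Integer seed; identical config and seed give identical
#'   truths.
#'
#' @return An object of class `synthetic_truth` with the group and
#'   per-participant path sets, per-participant coefficient matrices `A`
#'   (contemporaneous) and `Phi` (lagged), innovation variances, and the
#'   configuration.
#' @export
generate_truth <- function(config = truth_config(), seed) {
  if (!inherits(config, "truth_config")) config_error("config must be a truth_config")
  rois <- config$rois
  p <- length(rois$labels)
  if (p < 2L) config_error("the ROI set needs at least 2 regions")
  if (config$n_participants < 1L) config_error("n_participants must be positive")
  wr <- config$weight_range
  ar <- config$ar_range
  if (any(wr <= 0) || any(wr >= 1) || wr[1] > wr[2]) {
    config_error("weight_range magnitudes must lie in (0, 1)")
  }
  if (any(ar <= 0) || any(ar >= 1) || ar[1] > ar[2]) {
    config_error("ar_range magnitudes must lie in (0, 1)")
  }
  if (!all(c("mrn", "dmn", "between") %in% names(config$group_counts))) {
    config_error("group_counts needs entries mrn, dmn, between")
  }
  ir <- config$individual_range
  if (length(ir) != 2L || any(ir < 0) || ir[1] > ir[2]) {
    config_error("individual_range must be a nondecreasing pair of nonnegative counts")
  }
  psi <- rep_len(config$noise_var, p)
  if (any(psi <= 0)) config_error("noise variances must be positive")
  names(psi) <- rois$labels

  pool <- path_pool(rois, config$prop_lagged)
  # feasibility: per-block group demand against the block's path slots
  for (b in c("mrn", "dmn", "between")) {
    n_slots <- sum(pool$block == b)
    if (config$group_counts[[b]] > n_slots) {
      config_error(sprintf(
        "group_counts['%s'] = %d exceeds the %d admissible paths in that block",
        b, config$group_counts[[b]], n_slots
      ))
    }
  }
  if (sum(config$group_counts) + ir[2] > nrow(pool)) {
    config_error("requested path counts exceed the admissible path pool")
  }

  with_seed(seed, {
    ids <- sprintf("P%02d", seq_len(config$n_participants))
    taken <- character(0)
    grp_rows <- integer(0)
    for (b in c("mrn", "dmn", "between")) {
      d <- draw_paths(pool, pool$block == b, config$group_counts[[b]], taken,
        config$allow_reciprocal)
      grp_rows <- c(grp_rows, d$rows)
      taken <- d$taken_keys
    }
    group_paths <- pool[grp_rows, c("source", "target", "lag"), drop = FALSE]
    group_paths$level <- rep("group", nrow(group_paths))
    rownames(group_paths) <- NULL
    group_taken <- taken

    blocks <- c("mrn", "dmn", "between")
    probs <- config$individual_block_probs[blocks]
    individual_paths <- stats::setNames(vector("list", length(ids)), ids)
    use_count <- integer(nrow(pool)) # uses by other participants
    for (id in ids) {
      n_i <- if (ir[1] == ir[2]) ir[1] else sample(seq(ir[1], ir[2]), 1L)
      taken_i <- group_taken
      rows_i <- integer(0)
      if (n_i > 0) {
        blk <- sample(blocks, n_i, replace = TRUE, prob = probs)
        for (b in blk) {
          d <- tryCatch(
            draw_paths(pool, pool$block == b, 1L, taken_i, config$allow_reciprocal,
              use_count = use_count),
            usemnet_config_error = function(e) {
              draw_paths(pool, rep(TRUE, nrow(pool)), 1L, taken_i,
                config$allow_reciprocal, use_count = use_count)
            }
          )
          rows_i <- c(rows_i, d$rows)
          taken_i <- d$taken_keys
        }
      }
      use_count[rows_i] <- use_count[rows_i] + 1L
      ip <- pool[rows_i, c("source", "target", "lag"), drop = FALSE]
      ip$level <- rep("individual", nrow(ip))
      rownames(ip) <- NULL
      individual_paths[[id]] <- ip
    }

    A <- list()
    Phi <- list()
    for (id in ids) {
      paths_i <- rbind(group_paths, individual_paths[[id]])
      ok <- FALSE
      for (try in seq_len(config$max_tries)) {
        Ai <- matrix(0, p, p, dimnames = list(rois$labels, rois$labels))
        Pi_i <- matrix(0, p, p, dimnames = list(rois$labels, rois$labels))
        diag(Pi_i) <- stats::runif(p, ar[1], ar[2])
        if (nrow(paths_i)) {
          w <- stats::runif(nrow(paths_i), wr[1], wr[2]) *
            sample(c(-1, 1), nrow(paths_i), replace = TRUE)
          for (k in seq_len(nrow(paths_i))) {
            ti <- match(paths_i$target[k], rois$labels)
            si <- match(paths_i$source[k], rois$labels)
            if (paths_i$lag[k] == 0L) Ai[ti, si] <- w[k] else Pi_i[ti, si] <- w[k]
          }
        }
        M <- tryCatch(solve(diag(p) - Ai), error = function(e) NULL)
        if (is.null(M)) next
        rho <- max(Mod(eigen(M %*% Pi_i, only.values = TRUE)$values))
        if (rho < config$spectral_bound) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        generation_error(sprintf(
          "no stationary weight assignment found for %s after %d tries",
          id, config$max_tries
        ))
      }
      A[[id]] <- Ai
      Phi[[id]] <- Pi_i
    }

    structure(
      list(
        rois = rois,
        participants = ids,
        group_paths = group_paths,
        individual_paths = individual_paths,
        A = A, Phi = Phi,
        noise_variances = psi,
        seed = as.integer(seed),
        n_participants = config$n_participants,
        n_rois = p,
        run_lengths = config$run_lengths,
        config = config
      ),
      class = "synthetic_truth"
    )
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  n_ind <- vapply(x$individual_paths, nrow, 0L)
  cat(sprintf(
    "Synthetic uSEM truth: %d participants, %d ROIs, %d group paths, %.1f individual paths/person (seed %d)\n",
    x$n_participants, x$n_rois, nrow(x$group_paths), mean(n_ind), x$seed
  ))
  invisible(x)
}

#' True network structure of one participant
#'
#' @param truth A [generate_truth()] result.
#' @param participant_id One of `truth$participants`.
#' @return A [network_structure()] with the AR, group, and individual
#'   paths of that participant.
#' @export
truth_structure <- function(truth, participant_id) {
  if (!participant_id %in% truth$participants) {
    input_error(sprintf("unknown participant '%s'", participant_id))
  }
  network_structure(
    rbind(truth$group_paths, truth$individual_paths[[participant_id]]),
    truth$rois,
    include_ar = TRUE
  )
}

# Truth weights as a long edge table (participant, source, target, lag,
# level, weight), AR paths included.
truth_edges <- function(truth) {
  out <- lapply(truth$participants, function(id) {
    st <- truth_structure(truth, id)
    paths <- st$paths
    w <- numeric(nrow(paths))
    for (k in seq_len(nrow(paths))) {
      ti <- match(paths$target[k], truth$rois$labels)
      si <- match(paths$source[k], truth$rois$labels)
      w[k] <- if (paths$lag[k] == 0L) truth$A[[id]][ti, si] else truth$Phi[[id]][ti, si]
    }
    cbind(data.frame(participant = id, stringsAsFactors = FALSE), paths, weight = w)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate ROI time series from a synthetic truth
#'
#' Generates each participant's runs from the structural recursion
#' `eta_t = (I - A)^{-1} (Phi eta_{t-1} + zeta_t)` with mean-zero
#' Gaussian innovations and diagonal covariance. Runs are independent
#' realizations: each starts fresh and discards its own burn-in.
#'
#' @param truth A [generate_truth()] result.
#' @param run_lengths Run lengths (default: the truth's configured runs);
#'   all must be at least 10.
#' @param burn_in Burn-in steps discarded per run (at least 50).
#' @param seed Integer seed (default `truth$seed + 1`).
#'
#' @return A named list of [participant_ts()] objects.
#' @export
simulate_timeseries <- function(truth, run_lengths = NULL, burn_in = 50L, seed = NULL) {
  if (!inherits(truth, "synthetic_truth")) input_error("truth must be a synthetic_truth")
  run_lengths <- as.integer(run_lengths %||% truth$run_lengths)
  if (any(run_lengths < 10L)) input_error("all run lengths must be at least 10")
  burn_in <- max(as.integer(burn_in), 50L)
  seed <- as.integer(seed %||% (truth$seed + 1L))
  p <- truth$n_rois
  sdv <- sqrt(truth$noise_variances)
  labels <- truth$rois$labels

  with_seed(seed, {
    out <- lapply(truth$participants, function(id) {
      M <- tryCatch(solve(diag(p) - truth$A[[id]]), error = function(e) {
        generation_error(sprintf("(I - A) is singular for participant %s", id))
      })
      Phi <- truth$Phi[[id]]
      runs <- lapply(run_lengths, function(Tn) {
        total <- burn_in + Tn
        Z <- matrix(stats::rnorm(total * p), total, p) %*% diag(sdv, p)
        X <- matrix(0, total, p)
        eta <- numeric(p)
        for (t in seq_len(total)) {
          eta <- as.numeric(M %*% (Phi %*% eta + Z[t, ]))
          X[t, ] <- eta
        }
        X <- X[(burn_in + 1L):total, , drop = FALSE]
        colnames(X) <- labels
        X
      })
      participant_ts(id, runs)
    })
    stats::setNames(out, truth$participants)
  })
}

#' Hormone and behavior population parameters
#'
#' Target means and SDs (pg/mL for the hormones, percent correct for the
#' mental rotations task) of the simulated sample, plus the coupling of
#' each variable to the participant's true number of individual-level
#' paths. Coupling is the correlation planted between the (standardized)
#' individual path count and the variable; the default couples task
#' performance positively (0.5) and leaves hormones uncoupled.
#'
#' @param means,sds Named vectors over `estradiol`, `progesterone`,
#'   `testosterone`, `pct_correct`.
#' @param coupling Named vector of planted correlations in `[-1, 1]`.
#' @return A list of class `hb_params`.
#' @export
hormone_behavior_params <- function(means = c(estradiol = 1.33, progesterone = 239.01,
                                              testosterone = 132.82, pct_correct = 75),
                                    sds = c(estradiol = 0.71, progesterone = 124.99,
                                            testosterone = 64.88, pct_correct = 8.39),
                                    coupling = c(estradiol = 0, progesterone = 0,
                                                 testosterone = 0, pct_correct = 0.5)) {
  vars <- c("estradiol", "progesterone", "testosterone", "pct_correct")
  for (nm in list(means, sds, coupling)) {
    if (!all(vars %in% names(nm))) {
      config_error("means, sds and coupling must name all four variables")
    }
  }
  if (any(sds[vars] < 0)) config_error("SDs must be nonnegative")
  if (means[["pct_correct"]] <= 0 || means[["pct_correct"]] > 100) {
    config_error("pct_correct mean must lie in (0, 100]")
  }
  if (any(abs(coupling[vars]) > 1)) config_error("coupling must lie in [-1, 1]")
  structure(
    list(means = means[vars], sds = sds[vars], coupling = coupling[vars]),
    class = "hb_params"
  )
}

# Mean of the underlying Gaussian such that its zero-truncated version
# has the requested mean.
truncated_gaussian_mu <- function(target, sd) {
  if (sd == 0) return(target)
  if (target <= 0) config_error("truncated-at-zero targets must be positive")
  f <- function(m) m + sd * stats::dnorm(m / sd) / stats::pnorm(m / sd) - target
  stats::uniroot(f, lower = target - 10 * sd, upper = target, extendInt = "upX")$root
}

#' Generate hormone and behavior covariates for a synthetic truth
#'
#' Hormones are drawn from zero-truncated Gaussians whose truncated mean
#' equals the target mean (the underlying Gaussian mean is
#' moment-matched); task performance is Gaussian clipped to `[0, 100]`.
#' Non-zero coupling makes a variable correlate with the participant's
#' true individual-level path count, planting brain-behavior
#' associations that downstream correlation analyses can recover.
#'
#' @param truth A [generate_truth()] result.
#' @param params A [hormone_behavior_params()].
#' @param seed Integer seed (default `truth$seed + 2`).
#'
#' @return A data frame with columns `participant_id`, `estradiol`,
#'   `progesterone`, `testosterone`, `pct_correct`.
#' @export
generate_covariates <- function(truth, params = hormone_behavior_params(), seed = NULL) {
  if (!inherits(truth, "synthetic_truth")) input_error("truth must be a synthetic_truth")
  if (!inherits(params, "hb_params")) config_error("params must be hormone_behavior_params()")
  seed <- as.integer(seed %||% (truth$seed + 2L))
  n <- truth$n_participants
  ic <- vapply(truth$individual_paths, nrow, 0L)
  z <- if (n > 1 && stats::sd(ic) > 0) as.numeric(scale(ic)) else rep(0, n)

  with_seed(seed, {
    draw <- function(var, truncate) {
      mu <- params$means[[var]]
      sd <- params$sds[[var]]
      rho <- params$coupling[[var]]
      if (sd == 0) return(rep(mu, n))
      mu0 <- if (truncate) truncated_gaussian_mu(mu, sd) else mu
      cmean <- mu0 + sd * rho * z
      csd <- sd * sqrt(1 - rho^2)
      x <- cmean + csd * stats::rnorm(n)
      if (truncate) {
        for (rep_i in seq_len(1000L)) {
          bad <- x < 0
          if (!any(bad)) break
          x[bad] <- cmean[bad] + csd * stats::rnorm(sum(bad))
        }
        x[x < 0] <- 0
      }
      x
    }
    data.frame(
      participant_id = truth$participants,
      estradiol = draw("estradiol", TRUE),
      progesterone = draw("progesterone", TRUE),
      testosterone = draw("testosterone", TRUE),
      pct_correct = pmin(pmax(draw("pct_correct", FALSE), 0), 100),
      stringsAsFactors = FALSE
    )
  })
}

#' Stationary covariance of a uSEM system
#'
#' Analytic lag-0 and lag-1 covariance of the stationary process
#' `eta_t = (I - A)^{-1} (Phi eta_{t-1} + zeta_t)` with diagonal
#' innovation covariance `psi`.
#'
#' @param A,Phi Contemporaneous and lagged coefficient matrices.
#' @param psi Innovation variance vector (diagonal of Psi).
#' @return A list with `gamma0` (contemporaneous covariance) and `gamma1`
#'   (`Cov(eta_t, eta_{t-1})`).
#' @export
stationary_covariance <- function(A, Phi, psi) {
  p <- nrow(A)
  M <- solve(diag(p) - A)
  Pi <- M %*% Phi
  Om <- M %*% (psi * t(M))
  rho <- max(Mod(eigen(Pi, only.values = TRUE)$values))
  if (rho >= 1) input_error("system is not stationary (spectral radius >= 1)")
  g0 <- matrix(solve(diag(p^2) - Pi %x% Pi, as.vector(Om)), p, p)
  g0 <- (g0 + t(g0)) / 2
  list(gamma0 = g0, gamma1 = Pi %*% g0)
}

#' Score recovered structures against a synthetic truth
#'
#' Compares an estimated [run_sample_search()] result with the planted
#' truth: recall and precision of the group-level non-AR paths, and the
#' per-participant F1 of all non-AR edges (group plus individual),
#' averaged over participants. AR paths are present in both truth and
#' estimate by construction and are excluded from scoring.
#'
#' @param truth A [generate_truth()] result.
#' @param search A [run_sample_search()] result on data simulated from
#'   that truth.
#' @return A list with `group_recall`, `group_precision`, `edge_f1`, and
#'   a per-participant data frame.
#' @export
score_edge_recovery <- function(truth, search) {
  key_of <- function(paths) sprintf("%d:%s>%s", paths$lag, paths$source, paths$target)
  true_grp <- key_of(truth$group_paths)
  est_paths <- search$group_structure$paths
  est_grp <- key_of(est_paths[est_paths$level == "group", , drop = FALSE])
  group_recall <- if (length(true_grp)) mean(true_grp %in% est_grp) else 1
  group_precision <- if (length(est_grp)) mean(est_grp %in% true_grp) else 1

  per <- lapply(truth$participants, function(id) {
    tp <- rbind(truth$group_paths, truth$individual_paths[[id]])
    true_keys <- key_of(tp)
    nw <- search$networks[[id]]
    ep <- nw$estimates[nw$estimates$level != "ar", , drop = FALSE]
    est_keys <- key_of(ep)
    tp_n <- sum(est_keys %in% true_keys)
    prec <- if (length(est_keys)) tp_n / length(est_keys) else 1
    rec <- if (length(true_keys)) tp_n / length(true_keys) else 1
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(
      participant_id = id, precision = prec, recall = rec, f1 = f1,
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  list(
    group_recall = group_recall,
    group_precision = group_precision,
    edge_f1 = mean(per$f1),
    per_participant = per
  )
}
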