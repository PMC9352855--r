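# Two-stage data-driven structure search: group-level paths shared by
# most of the sample first, then person-unique paths until fit indices
# are satisfactory, with final per-person estimation.

#' Configuration for the two-stage network search
#'
#' @param group_threshold Fraction of the sample (in `(0.5, 1]`) for which
#'   a candidate must be significant to enter (and stay in) the group
#'   structure; the participant count criterion is
#'   `ceiling(group_threshold * n)`. Default 0.75.
#' @param alpha_mi Significance level for a modification index
#'   (chi-square with 1 df). Default 0.05.
#' @param alpha_prune Significance level for the two-sided z-test used
#'   when pruning estimated paths. Default 0.05.
#' @param fit_rule Number of "excellent" fit indices (out of 4) required
#'   to declare a person's model well-fitting. Default 2.
#' @param fit_cutoffs Named numeric vector of excellent-fit cutoffs:
#'   `rmsea` and `srmr` at or below, `cfi` and `nnfi` at or above.
#' @param max_iterations Cap on path additions per search stage.
#' @param prune_group Prune group paths that lose sample-wide
#'   significance after the additions (AR paths are never pruned).
#' @param mi_correction `"none"` (default) or `"bonferroni"` across the
#'   candidate set.
#'
#' @return An object of class `search_config`.
#' @export
search_config <- function(group_threshold = 0.75,
                          alpha_mi = 0.05,
                          alpha_prune = 0.05,
                          fit_rule = 2L,
                          fit_cutoffs = c(rmsea = 0.05, srmr = 0.05, cfi = 0.95, nnfi = 0.95),
                          max_iterations = 50L,
                          prune_group = TRUE,
                          mi_correction = c("none", "bonferroni")) {
  mi_correction <- match.arg(mi_correction)
  if (!is.numeric(group_threshold) || group_threshold <= 0.5 || group_threshold > 1) {
    config_error("group_threshold must lie in (0.5, 1]")
  }
  for (a in c(alpha_mi, alpha_prune)) {
    if (!is.numeric(a) || a <= 0 || a >= 1) config_error("alpha levels must lie in (0, 1)")
  }
  if (!is_count(fit_rule) || fit_rule < 1 || fit_rule > 4) {
    config_error("fit_rule must be an integer in 1..4")
  }
  if (!all(c("rmsea", "srmr", "cfi", "nnfi") %in% names(fit_cutoffs))) {
    config_error("fit_cutoffs needs entries rmsea, srmr, cfi, nnfi")
  }
  if (!is_count(max_iterations) || max_iterations < 1) {
    config_error("max_iterations must be a positive integer")
  }
  structure(
    list(
      group_threshold = group_threshold,
      alpha_mi = alpha_mi,
      alpha_prune = alpha_prune,
      fit_rule = as.integer(fit_rule),
      fit_cutoffs = fit_cutoffs,
      max_iterations = as.integer(max_iterations),
      prune_group = isTRUE(prune_group),
      mi_correction = mi_correction
    ),
    class = "search_config"
  )
}

# Does a person's model satisfy the excellent-fit rule?
fit_rule_met <- function(fit, config) {
  cut <- config$fit_cutoffs
  n_excellent <- sum(
    fit$rmsea <= cut[["rmsea"]],
    is.finite(fit$srmr) && fit$srmr <= cut[["srmr"]],
    fit$cfi >= cut[["cfi"]],
    fit$nnfi >= cut[["nnfi"]]
  )
  n_excellent >= config$fit_rule
}

empty_trace <- function() {
  data.frame(
    step = integer(), stage = character(), action = character(),
    source = character(), target = character(), lag = integer(),
    n_significant = integer(), score_sum = numeric(),
    chi2_before = numeric(), chi2_after = numeric(),
    stringsAsFactors = FALSE
  )
}

trace_row <- function(step, stage, action, source, target, lag,
                      n_significant = NA_integer_, score_sum = NA_real_,
                      chi2_before = NA_real_, chi2_after = NA_real_) {
  data.frame(
    step = step, stage = stage, action = action,
    source = source, target = target, lag = as.integer(lag),
    n_significant = as.integer(n_significant), score_sum = score_sum,
    chi2_before = chi2_before, chi2_after = chi2_after,
    stringsAsFactors = FALSE
  )
}

safe_fit <- function(sample, structure, compute_se = TRUE) {
  tryCatch(fit_usem(sample, structure, compute_se = compute_se),
    usemnet_estimation_error = function(e) NULL
  )
}

effective_alpha <- function(config, n_candidates) {
  if (config$mi_correction == "bonferroni" && n_candidates > 0) {
    config$alpha_mi / n_candidates
  } else {
    config$alpha_mi
  }
}

#' Group-level structure search
#'
#' Starting from the null structure (AR paths only), iteratively scores
#' every admissible candidate path in every participant, counts the
#' participants for whom the candidate's modification index is
#' significant, and adds the best-supported candidate to *all*
#' participants' structures whenever that count reaches
#' `ceiling(group_threshold * n)`. Ties on the participant count are
#' broken by the larger sum of modification indices, then
#' lexicographically by (lag, source, target). After the additions, group
#' paths whose estimated weight is significant for fewer than the
#' criterion count of participants are pruned to a fixed point (AR paths
#' never prune).
#'
#' @param samples A list of [build_lagged_sample()] results (one per
#'   participant) sharing the same ROI labels.
#' @param config A [search_config()].
#' @param rois Optional [roi_set()]; defaults to the samples' labels.
#'
#' @return A list of class `group_search` with the shared
#'   `network_structure`, the search `trace`, the criterion count
#'   `n_required`, and participants excluded for non-convergence.
#' @export
group_search <- function(samples, config = search_config(), rois = NULL) {
  if (length(samples) < 2L) input_error("group search needs at least 2 participants")
  labels <- samples[[1]]$labels
  for (s in samples) {
    if (!identical(s$labels, labels)) input_error("all samples must share the ROI set")
  }
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- vapply(samples, function(s) s$participant_id, "")
  }
  n <- length(samples)
  required <- ceiling(config$group_threshold * n)
  structure <- null_structure(rois %||% labels)
  trace <- empty_trace()
  step <- 0L

  # per-participant cache of the current fit and candidate scores;
  # after each shared addition only the scores the added path could have
  # changed are recomputed (exactly the same values as a full rescore)
  state <- lapply(samples, mi_state_init, structure = structure)
  for (iter in seq_len(config$max_iterations)) {
    failed <- vapply(state, is.null, TRUE)
    if (any(failed)) {
      for (k in which(failed)) { # retry once per iteration
        state[[k]] <- mi_state_init(samples[[k]], structure)
      }
      failed <- vapply(state, is.null, TRUE)
    }
    if (sum(failed) > 0.25 * n) {
      estimation_error(
        sprintf(
          "group search aborted: %d of %d participants failed to converge (%s)",
          sum(failed), n, paste(names(samples)[failed], collapse = ", ")
        )
      )
    }
    if (any(failed)) {
      log_msg("warn", "group step ", iter, ": excluded non-converged participant(s) ",
        paste(names(samples)[failed], collapse = ", "))
    }
    active <- which(!failed)
    all_mi <- do.call(rbind, lapply(active, function(k) state[[k]]$mi))
    if (is.null(all_mi) || !nrow(all_mi)) break
    all_mi <- all_mi[is.finite(all_mi$mi), , drop = FALSE]
    if (!nrow(all_mi)) break
    # candidates are identical across participants (shared structure)
    cand <- candidate_paths(structure)
    ckey <- sprintf("%d:%s>%s", cand$lag, cand$source, cand$target)
    alpha <- effective_alpha(config, nrow(cand))
    key <- sprintf("%d:%s>%s", all_mi$lag, all_mi$source, all_mi$target)
    n_sig <- tapply(all_mi$pvalue < alpha, key, sum)
    mi_sum <- tapply(all_mi$mi, key, sum)
    cand$n_sig <- as.integer(ifelse(is.na(n_sig[ckey]), 0L, n_sig[ckey]))
    cand$mi_sum <- as.numeric(ifelse(is.na(mi_sum[ckey]), 0, mi_sum[ckey]))
    ord <- order(-cand$n_sig, -cand$mi_sum, cand$lag,
      match(cand$source, labels), match(cand$target, labels))
    best <- cand[ord[1L], ]
    if (best$n_sig < required) break
    chi2_before <- sum(vapply(state[active], function(st) st$fit$fit$chi2, 0))
    structure <- st_add_path(structure, best$source, best$target, best$lag, "group")
    state <- lapply(seq_len(n), function(k) {
      mi_state_update(state[[k]], samples[[k]], structure, best)
    })
    chi2_after <- sum(vapply(state[active], function(st) {
      if (is.null(st)) NA_real_ else st$fit$fit$chi2
    }, 0))
    step <- step + 1L
    trace <- rbind(trace, trace_row(
      step, "group", "add", best$source, best$target, best$lag,
      n_significant = best$n_sig, score_sum = best$mi_sum,
      chi2_before = chi2_before, chi2_after = chi2_after
    ))
    log_msg("info", sprintf(
      "group add %s %s %s (lag %d), significant for %d/%d",
      best$source, if (best$lag == 0L) "->" else "=>", best$target,
      best$lag, best$n_sig, n
    ))
  }

  if (config$prune_group) {
    # stepwise backward pruning: among the paths failing the sample-wide
    # significance criterion, drop the one whose removal costs the least
    # likelihood (smallest summed chi-square increase), refit, and
    # re-judge. Estimates shift when a collinear path — e.g. the reverse
    # direction of the same pair, whose z tests are distorted by weak
    # identification — leaves the model, so one path leaves at a time
    # and the fit itself arbitrates which one.
    zcrit <- stats::qnorm(1 - config$alpha_prune / 2)
    repeat {
      grp <- structure$paths[structure$paths$level == "group", , drop = FALSE]
      if (!nrow(grp)) break
      fits <- lapply(samples, safe_fit, structure = structure, compute_se = TRUE)
      ok <- !vapply(fits, is.null, TRUE)
      gkey <- path_key(grp)
      counts <- integer(nrow(grp))
      for (i in seq_len(nrow(grp))) {
        counts[i] <- sum(vapply(fits[ok], function(f) {
          z <- f$estimates$z[path_key(f$estimates) == gkey[i]]
          is.finite(z) && abs(z) >= zcrit
        }, TRUE))
      }
      weak <- which(counts < required)
      if (!length(weak)) break
      zsum <- vapply(weak, function(i) {
        sum(vapply(fits[ok], function(f) {
          z <- f$estimates$z[path_key(f$estimates) == gkey[i]]
          if (is.finite(z)) abs(z) else 0
        }, 0))
      }, 0)
      ord <- order(counts[weak], zsum,
        grp$lag[weak], match(grp$source[weak], labels), match(grp$target[weak], labels))
      i <- weak[ord[1L]]
      # when the reciprocal contemporaneous twin is also in the model the
      # pair is weakly identified and the z tests cannot tell the
      # directions apart; the likelihood can — drop whichever direction
      # costs the sample fit less
      if (grp$lag[i] == 0L) {
        j <- which(gkey == sprintf("0:%s>%s", grp$target[i], grp$source[i]))
        if (length(j) == 1L) {
          cost <- vapply(c(i, j), function(k) {
            st2 <- st_drop_keys(structure, gkey[k])
            f2 <- lapply(samples[ok], safe_fit, structure = st2, compute_se = FALSE)
            if (any(vapply(f2, is.null, TRUE))) return(Inf)
            sum(vapply(f2, function(f) f$fit$chi2, 0))
          }, 0)
          if (is.finite(cost[2]) && cost[2] < cost[1]) i <- j
        }
      }
      step <- step + 1L
      trace <- rbind(trace, trace_row(
        step, "group", "prune", grp$source[i], grp$target[i], grp$lag[i],
        n_significant = counts[i]
      ))
      structure <- st_drop_keys(structure, gkey[i])
    }
  }

  structure(
    list(structure = structure, trace = trace, n_required = required,
      n_participants = n),
    class = "group_search"
  )
}

#' Individual-level structure search for one participant
#'
#' Starting from the fitted group structure, repeatedly adds the
#' participant's largest significant modification-index candidate until
#' the excellent-fit rule is satisfied, no significant candidate remains,
#' or `max_iterations` additions have been made; then prunes
#' non-significant individual-level paths (never group or AR paths) to a
#' fixed point and refits.
#'
#' @param sample A [build_lagged_sample()] result.
#' @param group_structure The [group_search()] structure (or any
#'   `network_structure` to extend).
#' @param config A [search_config()].
#'
#' @return A list of class `individual_search` with the final
#'   `person_network`, the `trace`, and a `converged` flag (`FALSE` when
#'   a non-converged addition was rolled back).
#' @export
individual_search <- function(sample, group_structure, config = search_config()) {
  structure <- group_structure
  state <- mi_state_init(sample, structure)
  if (is.null(state)) {
    estimation_error(sprintf(
      "participant %s: group-structure model did not converge", sample$participant_id
    ))
  }
  fit <- state$fit
  trace <- empty_trace()
  step <- 0L
  converged <- TRUE

  while (step < config$max_iterations && !fit_rule_met(fit$fit, config)) {
    mi <- state$mi[is.finite(state$mi$mi), , drop = FALSE]
    if (!nrow(mi)) break
    alpha <- effective_alpha(config, nrow(mi))
    sig <- sort_mi(mi[mi$pvalue < alpha, , drop = FALSE], sample$labels)
    if (!nrow(sig)) break
    best <- sig[1L, ] # largest score; ties broken by (lag, source, target)
    st2 <- st_add_path(structure, best$source, best$target, best$lag, "individual")
    s2 <- mi_state_update(state, sample, st2, best)
    if (is.null(s2)) {
      converged <- FALSE
      log_msg("warn", sprintf(
        "participant %s: rolled back addition %s>%s (lag %d) after non-convergence",
        sample$participant_id, best$source, best$target, best$lag
      ))
      break
    }
    step <- step + 1L
    trace <- rbind(trace, trace_row(
      step, "individual", "add", best$source, best$target, best$lag,
      score_sum = best$mi, chi2_before = fit$fit$chi2, chi2_after = s2$fit$fit$chi2
    ))
    structure <- st2
    state <- s2
    fit <- state$fit
  }
  # the pruning z-tests need standard errors
  f_se <- safe_fit(sample, structure, compute_se = TRUE)
  if (!is.null(f_se)) fit <- f_se

  # stepwise backward pruning of nonsignificant individual paths: the
  # least significant path leaves first, then the model is refit, since
  # a collinear removal can restore the significance of the rest
  zcrit <- stats::qnorm(1 - config$alpha_prune / 2)
  labels <- sample$labels
  repeat {
    est <- fit$estimates
    ind <- est[est$level == "individual", , drop = FALSE]
    absz <- ifelse(is.finite(ind$z), abs(ind$z), 0)
    weak <- which(absz < zcrit)
    if (!length(weak)) break
    ord <- order(absz[weak], ind$lag[weak],
      match(ind$source[weak], labels), match(ind$target[weak], labels))
    i <- weak[ord[1L]]
    # reciprocal-twin adjudication as in the group stage: if both
    # directions are individual-level paths, keep the one the
    # likelihood prefers
    ikey <- path_key(ind)
    if (ind$lag[i] == 0L) {
      j <- which(ikey == sprintf("0:%s>%s", ind$target[i], ind$source[i]))
      if (length(j) == 1L) {
        cost <- vapply(c(i, j), function(k) {
          f2 <- safe_fit(sample, st_drop_keys(structure, ikey[k]), compute_se = FALSE)
          if (is.null(f2)) Inf else f2$fit$chi2
        }, 0)
        if (is.finite(cost[2]) && cost[2] < cost[1]) i <- j
      }
    }
    step <- step + 1L
    trace <- rbind(trace, trace_row(
      step, "individual", "prune", ind$source[i], ind$target[i], ind$lag[i]
    ))
    structure <- st_drop_keys(structure, path_key(ind[i, , drop = FALSE]))
    f2 <- safe_fit(sample, structure, compute_se = TRUE)
    if (is.null(f2)) {
      converged <- FALSE
      break
    }
    fit <- f2
  }

  structure(
    list(network = fit, trace = trace, converged = converged,
      participant_id = sample$participant_id),
    class = "individual_search"
  )
}

#' Run the full two-stage search over a sample
#'
#' Builds each participant's lagged sample, runs [group_search()] across
#' the sample, then [individual_search()] for every participant. The
#' procedure is deterministic given the dataset and configuration, and
#' every final network contains every group path.
#'
#' @param dataset Either a list of [participant_ts()] objects or a
#'   dataset list with elements `ts` (list of `participant_ts`) and
#'   optionally `rois` (see [load_dataset()]).
#' @param config A [search_config()].
#'
#' @return An object of class `sample_search`: named list `networks` of
#'   `person_network`s, the shared `group_structure`, `group_trace`,
#'   per-participant `individual_traces`, `n_required`, and `config`.
#' @export
run_sample_search <- function(dataset, config = search_config()) {
  if (inherits(dataset, "usem_dataset") ||
    (is.list(dataset) && !is.null(dataset$ts))) {
    ts_list <- dataset$ts
    rois <- dataset$rois
  } else {
    ts_list <- dataset
    rois <- NULL
  }
  if (!length(ts_list)) input_error("dataset contains no time series")
  samples <- lapply(ts_list, build_lagged_sample)
  names(samples) <- vapply(samples, function(s) s$participant_id, "")
  grp <- group_search(samples, config, rois = rois)
  searches <- lapply(samples, function(s) {
    tryCatch(
      individual_search(s, grp$structure, config),
      usemnet_estimation_error = function(e) {
        estimation_error(sprintf(
          "individual search failed for participant %s: %s",
          s$participant_id, conditionMessage(e)
        ))
      }
    )
  })
  networks <- lapply(searches, function(x) x$network)
  structure(
    list(
      networks = networks,
      group_structure = grp$structure,
      group_trace = grp$trace,
      individual_traces = lapply(searches, function(x) x$trace),
      converged = vapply(searches, function(x) x$converged, TRUE),
      n_required = grp$n_required,
      config = config
    ),
    class = "sample_search"
  )
}

#' @export
print.sample_search <- function(x, ...) {
  n_grp <- sum(x$group_structure$paths$level == "group")
  n_ind <- vapply(x$networks, function(nw) sum(nw$estimates$level == "individual"), 0L)
  cat(sprintf(
    "Two-stage uSEM search: %d participants, %d group paths (criterion %d/%d), %.1f individual paths/person\n",
    length(x$networks), n_grp, x$n_required, length(x$networks), mean(n_ind)
  ))
  invisible(x)
}
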