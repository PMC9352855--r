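# Lagrange-multiplier-style scoring of candidate paths. Each score is the
# chi-square drop from freeing that single path, computed by exact refit.
# Because the profiled likelihood separates over equations and over the
# strongly connected components of the contemporaneous graph, only the
# part of the model the candidate touches is recomputed: a one-equation
# least-squares update in the typical case, a small joint re-optimization
# of the affected cycle block when the candidate enters or creates one.
# The same separability drives the incremental cache used by the searches:
# after one path is added, only candidates whose target equation lies in
# the affected component, or whose cycle-closure status changed, are
# rescored.

# Can one more free parameter be afforded?
mi_room <- function(structure, p, n_eff) {
  usem_df(p, nrow(structure$paths) + p + 1L) >= 0 &&
    n_eff - 1 > nrow(structure$paths) + p + 1L
}

# Exact chi-square drop for each candidate row (NA on refit failure).
score_candidates <- function(sample, structure, fit, cands) {
  if (!nrow(cands)) return(numeric(0))
  p <- sample$p
  C <- sample$C
  n_eff <- sample$n_eff
  labels <- sample$labels
  eqinfo <- fit$internal$eqinfo
  comps <- fit$internal$comps
  beta <- fit$internal$beta
  psi <- unname(fit$psi)
  comp_fit <- list()
  for (cf in fit$internal$comp_fits) {
    comp_fit[[as.character(comps$comp_id[cf$members[1]])]] <- cf
  }
  in_cycle <- comps$comp_id %in% as.integer(names(comp_fit))

  mi <- numeric(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    s <- match(cands$source[i], labels)
    t <- match(cands$target[i], labels)
    lag <- cands$lag[i]
    col <- if (lag == 1L) s else p + s
    creates_cycle <- lag == 0L && comps$R[t, s]

    if (!creates_cycle && !in_cycle[t]) {
      # only equation `t` changes; all determinant blocks are untouched
      P <- c(eqinfo$eqs[[t]]$pred, col)
      y <- p + t
      Cpp <- C[P, P, drop = FALSE]
      cpy <- C[P, y]
      g_new <- tryCatch(
        C[y, y] - sum(solve(Cpp, cpy) * cpy),
        error = function(e) NA_real_
      )
      mi[i] <- if (is.finite(g_new) && g_new > 0) {
        (n_eff - 1) * (log(psi[t]) - log(g_new))
      } else {
        NA_real_
      }
    } else {
      if (!creates_cycle) {
        # target sits in an existing cycle block; re-optimize that block
        cf_old <- comp_fit[[as.character(comps$comp_id[t])]]
        nodes <- cf_old$members
        old_contrib <- cf_old$value
      } else {
        # the new edge closes a cycle: merge every component on a
        # directed walk t ~> s together with {s, t}
        on_path <- which(comps$R[t, ] & comps$R[, s])
        ids <- unique(comps$comp_id[c(t, s, on_path)])
        nodes <- sort(which(comps$comp_id %in% ids))
        old_logdet <- sum(vapply(comp_fit[as.character(ids)], function(cf) {
          if (is.null(cf)) 0 else cf$logdet
        }, 0))
        old_contrib <- sum(log(psi[nodes])) - 2 * old_logdet
      }
      cf_new <- tryCatch(
        fit_component(C, eqinfo, p, n_eff, nodes, beta,
          extra = list(t = t, col = col)),
        error = function(e) NULL
      )
      mi[i] <- if (is.null(cf_new)) NA_real_ else (n_eff - 1) * (old_contrib - cf_new$value)
    }
  }
  ifelse(is.finite(mi), pmax(mi, 0), NA_real_)
}

#' Score candidate paths by expected chi-square decrease
#'
#' For every admissible absent path (no contemporaneous self-paths, no
#' duplicates), computes the decrease in model chi-square that freeing
#' that single path would produce, with a p-value from the chi-square
#' distribution with 1 degree of freedom. Scores are exact single-path
#' refit statistics (likelihood-ratio form of the modification index).
#'
#' @param sample A [build_lagged_sample()] result.
#' @param structure The current [network_structure()].
#' @param fit Optional pre-computed [fit_usem()] result for `structure`
#'   (refit internally when omitted).
#'
#' @return A data frame with columns `source`, `target`, `lag`, `mi`,
#'   `pvalue`, sorted by decreasing `mi`. Candidates whose refit failed
#'   (or that no remaining degree of freedom can absorb) carry `NA`
#'   scores.
#' @export
modification_indices <- function(sample, structure, fit = NULL) {
  if (is.null(fit) || is.null(fit$internal)) {
    fit <- fit_usem(sample, structure, compute_se = FALSE)
  }
  cands <- candidate_paths(structure)
  if (!nrow(cands)) {
    return(data.frame(
      source = character(), target = character(), lag = integer(),
      mi = numeric(), pvalue = numeric(), stringsAsFactors = FALSE
    ))
  }
  cands$mi <- if (mi_room(structure, sample$p, sample$n_eff)) {
    score_candidates(sample, structure, fit, cands)
  } else {
    NA_real_
  }
  cands$pvalue <- stats::pchisq(cands$mi, df = 1, lower.tail = FALSE)
  sort_mi(cands, sample$labels)
}

sort_mi <- function(cands, labels) {
  cands[order(-cands$mi, cands$lag, match(cands$source, labels),
    match(cands$target, labels),
    na.last = TRUE
  ), , drop = FALSE]
}

# --- incremental cache used by the searches ----------------------------

mi_state_init <- function(sample, structure) {
  fit <- tryCatch(fit_usem(sample, structure, compute_se = FALSE),
    usemnet_estimation_error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  cands <- candidate_paths(structure)
  room <- mi_room(structure, sample$p, sample$n_eff)
  cands$mi <- if (room) score_candidates(sample, structure, fit, cands) else NA_real_
  cands$pvalue <- stats::pchisq(cands$mi, df = 1, lower.tail = FALSE)
  list(fit = fit, mi = cands, room = room)
}

# Candidates whose exact refit problem changed after `added` entered the
# structure: target in the (possibly merged) component of the added
# path's target, cycle-closure status changed, or a cycle-closing merge
# set touching that component.
mi_stale <- function(fit_old, fit_new, cands, labels, added) {
  comps_old <- fit_old$internal$comps
  comps_new <- fit_new$internal$comps
  t_star <- match(added$target, labels)
  affected <- which(comps_new$comp_id == comps_new$comp_id[t_star])
  s_idx <- match(cands$source, labels)
  t_idx <- match(cands$target, labels)
  lag0 <- cands$lag == 0L
  cyc_new <- lag0 & comps_new$R[cbind(t_idx, s_idx)]
  cyc_old <- lag0 & comps_old$R[cbind(t_idx, s_idx)]
  stale <- (t_idx %in% affected) | (cyc_new != cyc_old)
  for (i in which(cyc_new & !stale)) {
    on_path <- comps_new$R[t_idx[i], ] & comps_new$R[, s_idx[i]]
    ids <- unique(comps_new$comp_id[c(t_idx[i], s_idx[i], which(on_path))])
    if (comps_new$comp_id[t_star] %in% ids) stale[i] <- TRUE
  }
  stale
}

# Advance a cache past the addition of `added` (a one-row path spec).
# Returns NULL when the refit under the new structure fails.
mi_state_update <- function(state, sample, structure_new, added) {
  f2 <- tryCatch(fit_usem(sample, structure_new, compute_se = FALSE),
    usemnet_estimation_error = function(e) NULL
  )
  if (is.null(f2)) return(NULL)
  room_new <- mi_room(structure_new, sample$p, sample$n_eff)
  cands <- candidate_paths(structure_new)
  if (is.null(state) || !identical(room_new, state$room)) {
    cands$mi <- if (room_new) score_candidates(sample, structure_new, f2, cands) else NA_real_
    cands$pvalue <- stats::pchisq(cands$mi, df = 1, lower.tail = FALSE)
    return(list(fit = f2, mi = cands, room = room_new))
  }
  key_new <- sprintf("%d:%s>%s", cands$lag, cands$source, cands$target)
  key_old <- sprintf("%d:%s>%s", state$mi$lag, state$mi$source, state$mi$target)
  cands$mi <- state$mi$mi[match(key_new, key_old)]
  if (room_new) {
    stale <- mi_stale(state$fit, f2, cands, sample$labels, added)
    if (any(stale)) {
      cands$mi[stale] <- score_candidates(sample, structure_new, f2,
        cands[stale, , drop = FALSE])
    }
  }
  cands$pvalue <- stats::pchisq(cands$mi, df = 1, lower.tail = FALSE)
  list(fit = f2, mi = cands, room = room_new)
}
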