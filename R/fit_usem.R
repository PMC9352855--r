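# Maximum-likelihood estimation of the unified SEM
#   eta_t = A eta_t + Phi eta_{t-1} + zeta_t,   zeta_t ~ N(0, Psi diagonal)
# on a participant's lagged sample. Estimation works on the 2p-dimensional
# lagged-augmented covariance with the lagged (predictor) block saturated.
# Profiling the saturated block (V-hat = S11) and the diagonal Psi
# (psi_j-hat = residual variance of equation j) reduces the ML discrepancy
# to
#   F(A, Phi) = sum_j log g_jj(A, Phi) - 2 log|det(I - A)| - log|S22.1|
# where g_jj is the structural residual variance of equation j and S22.1
# the sample conditional covariance of the current block given the lagged
# block.
#
# The objective separates over the strongly connected components (SCCs)
# of the contemporaneous graph: det(I - A) factors into the determinants
# of the nontrivial SCC blocks, and g_jj involves only equation j's own
# parameters. Equations outside any contemporaneous cycle are therefore
# solved exactly by per-equation least squares (the classic recursive
# path-model result), and only the equations inside each cycle block are
# optimized jointly by quasi-Newton iteration from a least-squares warm
# start. This also makes single-path refits (modification indices) cheap
# and exact: only the affected equation or cycle block is recomputed.

usem_df <- function(p, n_free_params) {
  p * (2L * p + 1L) - p * (p + 1L) / 2L - n_free_params
}

# Predictor column (in the 2p frame) of each path, split by target equation.
build_equations <- function(structure) {
  labels <- structure$labels
  p <- length(labels)
  paths <- structure$paths
  pred <- ifelse(paths$lag == 1L, match(paths$source, labels),
    p + match(paths$source, labels)
  )
  tgt <- match(paths$target, labels)
  src <- match(paths$source, labels)
  eqs <- lapply(seq_len(p), function(j) {
    rows <- which(tgt == j)
    list(rows = rows, pred = pred[rows])
  })
  list(eqs = eqs, pred = pred, tgt = tgt, src = src, lag = paths$lag)
}

# Strongly connected components of the contemporaneous graph.
structure_components <- function(structure) {
  R <- lag0_reachability(structure)
  p <- nrow(R)
  same <- R & t(R)
  diag(same) <- TRUE
  comp_id <- integer(p)
  cid <- 0L
  for (i in seq_len(p)) {
    if (comp_id[i] == 0L) {
      cid <- cid + 1L
      comp_id[same[i, ]] <- cid
    }
  }
  sizes <- tabulate(comp_id)
  nontrivial <- lapply(which(sizes >= 2L), function(k) which(comp_id == k))
  list(R = R, comp_id = comp_id, nontrivial = nontrivial)
}

# beta vector (aligned with structure$paths rows) -> A and Phi matrices.
coef_matrices <- function(structure, beta) {
  labels <- structure$labels
  p <- length(labels)
  paths <- structure$paths
  A <- matrix(0, p, p, dimnames = list(labels, labels))
  Phi <- matrix(0, p, p, dimnames = list(labels, labels))
  c0 <- paths$lag == 0L
  if (any(c0)) A[cbind(match(paths$target[c0], labels), match(paths$source[c0], labels))] <- beta[c0]
  if (any(!c0)) Phi[cbind(match(paths$target[!c0], labels), match(paths$source[!c0], labels))] <- beta[!c0]
  list(A = A, Phi = Phi)
}

# Exact per-equation least squares for every equation (ML solution for
# all equations outside contemporaneous cycles; warm start for the rest).
fit_equations_ols <- function(C, eqinfo, p, n_eff, compute_se = TRUE) {
  eqs <- eqinfo$eqs
  n_par <- length(eqinfo$pred)
  beta <- numeric(n_par)
  se <- rep(NA_real_, n_par)
  psi <- numeric(p)
  for (j in seq_len(p)) {
    P <- eqs[[j]]$pred
    y <- p + j
    if (length(P)) {
      Cpp <- C[P, P, drop = FALSE]
      cpy <- C[P, y]
      b <- tryCatch(solve(Cpp, cpy), error = function(e) {
        estimation_error(sprintf("singular predictor covariance in equation %d", j))
      })
      g <- C[y, y] - sum(b * cpy)
      beta[eqs[[j]]$rows] <- b
      if (compute_se) {
        se[eqs[[j]]$rows] <- sqrt(pmax(diag(solve(Cpp)), 0) * g / (n_eff - 1))
      }
    } else {
      g <- C[y, y]
    }
    if (g <= 0) estimation_error(sprintf("non-positive residual variance in equation %d", j))
    psi[j] <- g
  }
  list(beta = beta, se = se, psi = psi)
}

# Jointly optimize the equations of one contemporaneous cycle block.
#
# members: equation indices in the block. Free parameters are all path
# parameters targeting a member equation, plus (optionally) one extra
# candidate predictor `extra = list(t = equation, col = predictor column)`.
# The determinant term uses the contemporaneous entries with BOTH
# endpoints among `members` (block-restricted det is exact because the
# condensation of the graph is acyclic).
#
# Returns the minimized block contribution
#   value = sum_{j in members} log g_jj - 2 log|det(I - A_block)|
# along with the parameter values, residual variances, and optionally
# the block covariance matrix of the parameters.
fit_component <- function(C, eqinfo, p, n_eff, members, start_beta,
                          extra = NULL, compute_se = FALSE) {
  eqs <- eqinfo$eqs
  rows <- unlist(lapply(members, function(j) eqs[[j]]$rows), use.names = FALSE)
  preds <- lapply(members, function(j) eqs[[j]]$pred)
  n_extra <- if (is.null(extra)) 0L else 1L
  n_par <- length(rows) + n_extra

  # position of each equation's parameters inside theta
  pos <- vector("list", length(members))
  off <- 0L
  for (k in seq_along(members)) {
    nk <- length(preds[[k]])
    pos[[k]] <- if (nk) off + seq_len(nk) else integer(0)
    off <- off + nk
  }
  extra_pos <- if (n_extra) n_par else integer(0)
  if (n_extra) {
    k_ex <- match(extra$t, members)
    pos[[k_ex]] <- c(pos[[k_ex]], extra_pos)
    preds[[k_ex]] <- c(preds[[k_ex]], extra$col)
  }

  eq_data <- lapply(seq_along(members), function(k) {
    P <- preds[[k]]
    y <- p + members[k]
    list(Cpp = C[P, P, drop = FALSE], cpy = C[P, y], cyy = C[y, y])
  })

  # contemporaneous entries inside the block: theta position -> (row, col)
  # of the block matrix B, where B[t, s] = coefficient of s -> t
  nb <- length(members)
  bt <- integer(0)
  bs <- integer(0)
  bpos <- integer(0)
  for (k in seq_along(members)) {
    j <- members[k]
    for (m in seq_along(preds[[k]])) {
      col <- preds[[k]][m]
      if (col > p && (col - p) %in% members) { # contemporaneous, source in block
        bt <- c(bt, k)
        bs <- c(bs, match(col - p, members))
        bpos <- c(bpos, pos[[k]][m])
      }
    }
  }

  resid_var <- function(theta) {
    vapply(seq_along(members), function(k) {
      d <- eq_data[[k]]
      th <- theta[pos[[k]]]
      if (!length(th)) return(d$cyy)
      d$cyy - 2 * sum(th * d$cpy) + as.numeric(th %*% d$Cpp %*% th)
    }, 0)
  }
  bmat_full <- function(theta) {
    B <- matrix(0, nb, nb)
    if (length(bpos)) B[cbind(bt, bs)] <- theta[bpos]
    B
  }
  fobj <- function(theta) {
    g <- resid_var(theta)
    if (any(!is.finite(g)) || any(g <= 1e-12)) return(1e10)
    d <- det(diag(nb) - bmat_full(theta))
    if (!is.finite(d) || abs(d) < 1e-10) return(1e10)
    sum(log(g)) - 2 * log(abs(d))
  }
  grad <- function(theta) {
    g <- resid_var(theta)
    gr <- numeric(n_par)
    for (k in seq_along(members)) {
      d <- eq_data[[k]]
      if (!length(pos[[k]])) next
      th <- theta[pos[[k]]]
      gr[pos[[k]]] <- 2 * (as.numeric(d$Cpp %*% th) - d$cpy) / g[k]
    }
    if (length(bpos)) {
      Minv <- solve(diag(nb) - bmat_full(theta))
      gr[bpos] <- gr[bpos] + 2 * Minv[cbind(bs, bt)]
    }
    gr
  }

  # --- reduced problem: only the in-block contemporaneous coefficients
  # `a` are coupled through the determinant; every other parameter is
  # profiled out analytically via a Schur complement, so the numeric
  # search runs in length(a) dimensions and the rest is one linear solve
  red <- vector("list", length(members))
  a_len <- integer(length(members))
  for (k in seq_along(members)) {
    P <- preds[[k]]
    y <- p + members[k]
    inb <- which(P > p & (P - p) %in% members)
    oth <- setdiff(seq_along(P), inb)
    d <- list(which_inb = inb, which_o = oth)
    O <- P[oth]
    D <- P[inb]
    if (length(O)) {
      SO <- C[O, O, drop = FALSE]
      sol_cOy <- solve(SO, C[O, y])
      d$gam0 <- C[y, y] - sum(C[O, y] * sol_cOy)
      d$sol_cOy <- sol_cOy
      if (length(D)) {
        COD <- C[O, D, drop = FALSE]
        d$sol_COD <- solve(SO, COD)
        d$gam1 <- C[D, y] - as.numeric(crossprod(COD, sol_cOy))
        d$Gam2 <- C[D, D, drop = FALSE] - crossprod(COD, d$sol_COD)
      }
    } else {
      d$gam0 <- C[y, y]
      if (length(D)) {
        d$gam1 <- C[D, y]
        d$Gam2 <- C[D, D, drop = FALSE]
      }
    }
    a_len[k] <- length(D)
    red[[k]] <- d
  }
  a_pos <- vector("list", length(members))
  aoff <- 0L
  for (k in seq_along(members)) {
    a_pos[[k]] <- if (a_len[k]) aoff + seq_len(a_len[k]) else integer(0)
    aoff <- aoff + a_len[k]
  }
  n_a <- aoff
  abt <- integer(0)
  abs_ <- integer(0)
  for (k in seq_along(members)) {
    inb <- red[[k]]$which_inb
    if (length(inb)) {
      abt <- c(abt, rep(k, length(inb)))
      abs_ <- c(abs_, match(preds[[k]][inb] - p, members))
    }
  }
  gvec_a <- function(a) {
    vapply(seq_along(members), function(k) {
      d <- red[[k]]
      if (!a_len[k]) return(d$gam0)
      ak <- a[a_pos[[k]]]
      d$gam0 - 2 * sum(ak * d$gam1) + as.numeric(ak %*% d$Gam2 %*% ak)
    }, 0)
  }
  bmat_a <- function(a) {
    B <- matrix(0, nb, nb)
    if (n_a) B[cbind(abt, abs_)] <- a
    B
  }
  fobj_a <- function(a) {
    g <- gvec_a(a)
    if (any(!is.finite(g)) || any(g <= 1e-12)) return(1e10)
    d <- det(diag(nb) - bmat_a(a))
    if (!is.finite(d) || abs(d) < 1e-10) return(1e10)
    sum(log(g)) - 2 * log(abs(d))
  }
  grad_a <- function(a) {
    g <- gvec_a(a)
    gr <- numeric(n_a)
    for (k in seq_along(members)) {
      if (!a_len[k]) next
      d <- red[[k]]
      ak <- a[a_pos[[k]]]
      gr[a_pos[[k]]] <- 2 * (as.numeric(d$Gam2 %*% ak) - d$gam1) / g[k]
    }
    if (n_a) {
      Minv <- solve(diag(nb) - bmat_a(a))
      gr <- gr + 2 * Minv[cbind(abs_, abt)]
    }
    gr
  }

  hess_a <- function(a) {
    g <- gvec_a(a)
    H <- matrix(0, n_a, n_a)
    for (k in seq_along(members)) {
      if (!a_len[k]) next
      d <- red[[k]]
      ak <- a[a_pos[[k]]]
      gp <- 2 * (as.numeric(d$Gam2 %*% ak) - d$gam1)
      H[a_pos[[k]], a_pos[[k]]] <- 2 * d$Gam2 / g[k] - tcrossprod(gp) / g[k]^2
    }
    if (n_a) {
      Minv <- solve(diag(nb) - bmat_a(a))
      # d2(-2 log|det(I-B)|) / dB[t_i,s_i] dB[t_j,s_j] = 2 M[s_i,t_j] M[s_j,t_i]
      H <- H + 2 * Minv[abs_, abt, drop = FALSE] * t(Minv[abs_, abt, drop = FALSE])
    }
    H
  }
  # damped Newton with analytic Hessian; returns NULL when it cannot make
  # progress (indefinite curvature, likelihood ridge), in which case the
  # quasi-Newton fallback below takes over
  newton_a <- function(a) {
    f <- fobj_a(a)
    if (f >= 1e9) return(NULL)
    n_tiny <- 0L
    for (it in seq_len(40)) {
      gr <- grad_a(a)
      if (max(abs(gr)) < 1e-9) {
        return(list(par = a, objective = f, convergence = 0L, message = "newton"))
      }
      H <- hess_a(a)
      lambda <- 0
      repeat {
        step <- tryCatch(solve(H + lambda * diag(n_a), gr), error = function(e) NULL)
        if (!is.null(step) && all(is.finite(step))) break
        lambda <- if (lambda == 0) 1e-6 else lambda * 10
        if (lambda > 1e6) return(NULL)
      }
      ok_step <- FALSE
      for (h in 0:12) {
        a2 <- a - step / 2^h
        if (any(abs(a2) > 10)) next
        f2 <- fobj_a(a2)
        if (is.finite(f2) && f2 < f) {
          gain <- f - f2
          a <- a2
          f <- f2
          ok_step <- TRUE
          # a flat ridge (weak identification) improves the objective
          # only in the last digits while the gradient stays finite;
          # the minimized value is already attained there
          n_tiny <- if (gain < 1e-11 * (1 + abs(f))) n_tiny + 1L else 0L
          break
        }
      }
      if (!ok_step || n_tiny >= 2L) {
        if (max(abs(grad_a(a))) < 1e-4 || n_tiny >= 2L) {
          return(list(par = a, objective = f, convergence = 0L, message = "newton ridge"))
        }
        return(NULL)
      }
    }
    if (max(abs(grad_a(a))) < 1e-6) {
      list(par = a, objective = f, convergence = 0L, message = "newton")
    } else {
      NULL
    }
  }

  start_full <- c(start_beta[rows], if (n_extra) 0)
  if (n_a == 0L) {
    best <- list(par = numeric(0), objective = sum(log(gvec_a(numeric(0)))), ok = TRUE)
  } else {
    start <- numeric(n_a)
    for (k in seq_along(members)) {
      if (a_len[k]) start[a_pos[[k]]] <- start_full[pos[[k]]][red[[k]]$which_inb]
    }
    start <- pmin(pmax(start, -9.9), 9.9)
    best <- newton_a(start)
    if (!is.null(best)) best$ok <- TRUE
    for (try in 0:3) {
      if (!is.null(best) && best$ok && best$convergence == 0) break
      a0 <- if (try == 0) start else {
        with_seed(90000L + try, start + stats::rnorm(n_a, sd = 0.05))
      }
      res <- tryCatch(
        stats::nlminb(a0, fobj_a, gradient = grad_a,
          lower = -10, upper = 10,
          control = list(iter.max = 500, eval.max = 1000)),
        error = function(e) NULL
      )
      if (is.null(res)) next
      # code 0 is clean convergence; a small gradient or a likelihood
      # ridge ("singular"/"false convergence", typical of weakly
      # identified reciprocal paths) still yields a valid minimized value
      ok <- res$convergence == 0 ||
        max(abs(grad_a(res$par))) < 1e-4 ||
        grepl("singular convergence|false convergence", res$message %||% "")
      if (is.null(best) || res$objective < best$objective) {
        best <- res
        best$ok <- ok
      }
      if (ok && res$convergence == 0) break
    }
  }
  if (is.null(best) || !best$ok || best$objective >= 1e9) {
    estimation_error(
      sprintf("cycle-block estimation over equations {%s} did not converge",
        paste(members, collapse = ",")),
      diagnostics = best
    )
  }
  a_hat <- best$par
  # reconstruct profiled coefficients: o_j = SO^-1 (cOy - C[O, D] a_j)
  theta <- numeric(n_par)
  for (k in seq_along(members)) {
    d <- red[[k]]
    full <- numeric(length(pos[[k]]))
    if (a_len[k]) full[d$which_inb] <- a_hat[a_pos[[k]]]
    if (length(d$which_o)) {
      full[d$which_o] <- if (a_len[k]) {
        d$sol_cOy - as.numeric(d$sol_COD %*% a_hat[a_pos[[k]]])
      } else {
        d$sol_cOy
      }
    }
    theta[pos[[k]]] <- full
  }
  g <- resid_var(theta)
  dblock <- det(diag(nb) - bmat_full(theta))
  out <- list(
    value = best$objective,
    rows = rows,
    beta = theta[seq_along(rows)],
    theta = theta,
    extra_beta = if (n_extra) theta[extra_pos] else NULL,
    psi = g,
    members = members,
    logdet = log(abs(dblock))
  )
  if (compute_se) {
    H <- tryCatch(stats::optimHess(theta, fobj, grad), error = function(e) NULL)
    if (is.null(H) || any(!is.finite(H))) {
      usem_abort(
        c("usemnet_rank_error", "usemnet_estimation_error"),
        "observed information matrix could not be computed"
      )
    }
    # eigen pseudo-inverse: directions of (near-)zero information get
    # infinite variance, so weakly identified paths carry huge SEs and
    # z near 0 instead of aborting the search
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
    tol <- max(abs(ev$values)) * 1e-10
    usable <- ev$values > tol
    if (!any(usable)) {
      usem_abort(
        c("usemnet_rank_error", "usemnet_estimation_error"),
        "observed information matrix is singular; model is rank-deficient"
      )
    }
    var_diag <- (ev$vectors[, usable, drop = FALSE]^2) %*%
      (2 / ((n_eff - 1) * ev$values[usable]))
    flat <- rowSums(abs(ev$vectors[, !usable, drop = FALSE])) > 1e-8
    se_all <- sqrt(pmax(as.numeric(var_diag), 0))
    se_all[flat] <- Inf
    out$se <- se_all[seq_along(rows)]
    out$extra_se <- if (n_extra) se_all[extra_pos] else NULL
  }
  out
}

#' Fit a unified SEM to one participant's lagged sample
#'
#' Maximum-likelihood estimation of the structural model
#' `eta_t = A eta_t + Phi eta_{t-1} + zeta_t` with free parameters only at
#' the paths in `structure`, a free diagonal innovation covariance, and
#' the covariance of the lagged (predictor) block saturated. The ML
#' discrepancy of the implied versus sample 2p covariance is minimized;
#' `chi2 = (N - 1) * F_ML` with `N` the effective number of lagged pairs.
#' Standard errors come from the inverse observed information of the
#' profiled likelihood.
#'
#' @param sample A [build_lagged_sample()] result.
#' @param structure A [network_structure()] on the same ROI labels.
#' @param compute_se Compute standard errors and z statistics (default
#'   `TRUE`; skipping them speeds up search-internal refits).
#'
#' @return An object of class `person_network`: the structure, one
#'   estimate row per path (`beta`, `se`, `z`), residual variances `psi`,
#'   and [fit_indices()] including SRMR.
#' @export
fit_usem <- function(sample, structure, compute_se = TRUE) {
  if (!inherits(sample, "lagged_sample")) input_error("sample must be a lagged_sample")
  if (!inherits(structure, "network_structure")) input_error("structure must be a network_structure")
  if (!identical(structure$labels, sample$labels)) {
    input_error("structure and sample ROI labels differ")
  }
  p <- sample$p
  C <- sample$C
  n_eff <- sample$n_eff
  n_free <- nrow(structure$paths) + p
  df <- usem_df(p, n_free)
  if (df < 0) {
    estimation_error(sprintf(
      "structure is over-parameterized: %d free parameters exceed the %d modeled moments",
      n_free, p * (2L * p + 1L) - p * (p + 1L) / 2L
    ))
  }
  if (n_eff - 1 <= n_free) {
    estimation_error("effective N must exceed the number of free parameters")
  }
  eqinfo <- build_equations(structure)
  comps <- structure_components(structure)

  est <- fit_equations_ols(C, eqinfo, p, n_eff, compute_se = compute_se)
  beta <- est$beta
  se <- est$se
  psi <- est$psi
  comp_fits <- list()
  logdet_total <- 0
  for (nodes in comps$nontrivial) {
    cf <- fit_component(C, eqinfo, p, n_eff, nodes, beta, compute_se = compute_se)
    beta[cf$rows] <- cf$beta
    psi[nodes] <- cf$psi
    if (compute_se) se[cf$rows] <- cf$se
    logdet_total <- logdet_total + cf$logdet
    comp_fits[[length(comp_fits) + 1L]] <- cf
  }
  Fval <- sum(log(psi)) - 2 * logdet_total - sample$logdet_s221

  cm <- coef_matrices(structure, beta)
  dA <- det(diag(p) - cm$A)
  if (!is.finite(dA) || abs(dA) < 1e-10) {
    estimation_error("(I - A) is singular at the solution")
  }

  chi2 <- max((n_eff - 1) * Fval, 0)
  chi2_b <- max((n_eff - 1) * sample$baseline_F, 0)
  df_b <- usem_df(p, p)
  srmr <- compute_srmr(sample, cm$A, cm$Phi, psi)
  fit <- fit_indices(chi2, df, chi2_b, df_b, n_eff, srmr = srmr)

  estimates <- structure$paths
  estimates$beta <- beta
  estimates$se <- se
  estimates$z <- ifelse(is.finite(se) & se > 0, beta / se, NA_real_)
  rownames(estimates) <- NULL

  structure(
    list(
      participant_id = sample$participant_id,
      structure = structure,
      estimates = estimates,
      fit = fit,
      psi = stats::setNames(psi, sample$labels),
      A = cm$A, Phi = cm$Phi,
      Fml = Fval,
      n_eff = n_eff,
      converged = TRUE,
      internal = list(eqinfo = eqinfo, comps = comps, comp_fits = comp_fits, beta = beta)
    ),
    class = "person_network"
  )
}

# Implied 2p covariance under (A, Phi, Psi) with the predictor block
# saturated at S11; used for SRMR and for checking F_ML directly.
implied_sigma <- function(sample, A, Phi, psi) {
  p <- sample$p
  i1 <- seq_len(p)
  S11 <- sample$C[i1, i1, drop = FALSE]
  M <- solve(diag(p) - A)
  Pi <- M %*% Phi
  Sig21 <- Pi %*% S11
  Sig22 <- Pi %*% S11 %*% t(Pi) + M %*% (psi * t(M))
  Sig <- rbind(cbind(S11, t(Sig21)), cbind(Sig21, Sig22))
  dimnames(Sig) <- dimnames(sample$C)
  (Sig + t(Sig)) / 2
}

# Root mean square of standardized residuals over the unique moments of
# the full 2p block (the saturated predictor block contributes exact
# zeros).
compute_srmr <- function(sample, A, Phi, psi) {
  S <- sample$C
  Sig <- implied_sigma(sample, A, Phi, psi)
  d <- sqrt(diag(S))
  std_resid <- (S - Sig) / tcrossprod(d)
  sqrt(mean(std_resid[lower.tri(std_resid, diag = TRUE)]^2))
}

#' SEM fit indices from model and baseline chi-square statistics
#'
#' Computes RMSEA, CFI, and NNFI (TLI) from the model and baseline
#' (independence) chi-square statistics, and carries the supplied SRMR.
#' The baseline model has no structural paths (`A = 0`, `Phi = 0`), free
#' diagonal innovation variances, and the saturated predictor block.
#'
#' Formulas: `RMSEA = sqrt(max(chi2 - df, 0) / (df * (N - 1)))` (0 when
#' `df = 0`); `CFI = 1 - max(chi2_m - df_m, 0) / max(chi2_b - df_b,
#' chi2_m - df_m, 0)` clamped to `[0, 1]`;
#' `NNFI = ((chi2_b/df_b) - (chi2_m/df_m)) / ((chi2_b/df_b) - 1)`,
#' unclamped. With `df = 0` (saturated model) NNFI is undefined and
#' reported as 1 with `nnfi_undefined = TRUE`.
#'
#' @param chi2,df Model chi-square and degrees of freedom.
#' @param chi2_baseline,df_baseline Baseline chi-square and df.
#' @param n Effective sample size.
#' @param srmr Standardized root mean square residual (optional).
#'
#' @return An object of class `usem_fit_indices`.
#' @export
fit_indices <- function(chi2, df, chi2_baseline, df_baseline, n, srmr = NA_real_) {
  if (n <= 1) input_error("n must exceed 1")
  if (df_baseline < df) input_error("baseline df must be at least the model df")
  if (chi2 < 0 || df < 0) input_error("chi2 and df must be nonnegative")

  rmsea <- if (df == 0) 0 else sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  denom <- max(chi2_baseline - df_baseline, chi2 - df, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chi2 - df, 0) / denom
  cfi <- min(max(cfi, 0), 1)

  nnfi_undefined <- FALSE
  if (df == 0 || df_baseline == 0) {
    nnfi <- 1
    nnfi_undefined <- TRUE
  } else {
    rb <- chi2_baseline / df_baseline
    if (abs(rb - 1) < .Machine$double.eps^0.5) {
      nnfi <- 1
      nnfi_undefined <- TRUE
    } else {
      nnfi <- (rb - chi2 / df) / (rb - 1)
    }
  }
  pvalue <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_

  structure(
    list(
      chi2 = chi2, df = df, pvalue = pvalue,
      rmsea = rmsea, srmr = srmr, cfi = cfi, nnfi = nnfi,
      nnfi_undefined = nnfi_undefined,
      chi2_baseline = chi2_baseline, df_baseline = df_baseline, n = n
    ),
    class = "usem_fit_indices"
  )
}

#' @export
print.usem_fit_indices <- function(x, ...) {
  cat(sprintf(
    "chi2(%s) = %.2f%s, RMSEA = %.3f, SRMR = %.3f, CFI = %.3f, NNFI = %.3f\n",
    format(x$df), x$chi2,
    if (is.na(x$pvalue)) "" else sprintf(", p = %.3g", x$pvalue),
    x$rmsea, x$srmr, x$cfi, x$nnfi
  ))
  invisible(x)
}

#' @export
print.person_network <- function(x, ...) {
  tab <- table(factor(x$estimates$level, levels = c("ar", "group", "individual")))
  cat(sprintf(
    "Person-specific uSEM network for %s: %d paths (%d AR, %d group, %d individual)\n",
    x$participant_id, nrow(x$estimates), tab[["ar"]], tab[["group"]], tab[["individual"]]
  ))
  cat("Fit: ")
  print(x$fit)
  invisible(x)
}
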