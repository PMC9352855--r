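test_that("lagged-only ML estimates equal per-equation least squares", {
  # oracle: lm() on the raw pooled lagged pairs, a different route than
  # the covariance-based fit
  A <- matrix(0, 3, 3)
  Phi <- matrix(c(0.5, 0.2, 0, 0, 0.4, 0, 0.1, 0, 0.3), 3, 3, byrow = TRUE)
  X <- sim_usem(A, Phi, c(1, 1.5, 0.8), 600, seed = 11)
  ts <- participant_ts("P01", list(X[1:300, ], X[301:600, ]))
  s <- build_lagged_sample(ts)
  st <- network_structure(
    data.frame(
      source = c("a", "b", "c", "a"), target = c("b", "a", "a", "c"),
      lag = 1L
    ),
    rois3()
  )
  fit <- fit_usem(s, st)

  x0 <- rbind(X[1:299, ], X[301:599, ])
  x1 <- rbind(X[2:300, ], X[302:600, ])
  x0 <- scale(x0, scale = FALSE)
  x1 <- scale(x1, scale = FALSE)
  for (j in 1:3) {
    rows <- fit$estimates[fit$estimates$target == letters[j], ]
    preds <- match(rows$source, letters[1:3])
    ols <- coef(lm(x1[, j] ~ x0[, preds, drop = FALSE] - 1))
    expect_equal(unname(rows$beta), unname(ols), tolerance = 1e-4)
  }
})

test_that("AR weights of 0.5 are recovered on long series", {
  Phi <- diag(0.5, 2)
  X <- sim_usem(matrix(0, 2, 2), Phi, c(1, 1), 10000, seed = 12)
  s <- build_lagged_sample(participant_ts("P01", list(X)))
  fit <- fit_usem(s, null_structure(rois2()))
  expect_true(all(abs(fit$estimates$beta - 0.5) < 0.03))
  # matching lag-1 autocorrelation of the raw series
  for (j in 1:2) {
    ac <- acf(X[, j], lag.max = 1, plot = FALSE)$acf[2]
    expect_lt(abs(ac - 0.5), 0.03)
  }
})

test_that("a just-identified structure gives df 0, chi2 0, perfect indices", {
  A <- matrix(0, 3, 3)
  A[2, 1] <- 0.4
  Phi <- diag(0.4, 3)
  X <- sim_usem(A, Phi, rep(1, 3), 400, seed = 13)
  s <- build_lagged_sample(participant_ts("P01", list(X)))
  fit <- fit_usem(s, saturated_structure(rois3()))
  expect_equal(fit$fit$df, 0)
  expect_lt(fit$fit$chi2, 1e-6)
  expect_equal(fit$fit$cfi, 1)
  expect_equal(fit$fit$rmsea, 0)
  expect_lt(fit$fit$srmr, 1e-8)
})

test_that("omitting a strong planted contemporaneous path is detected", {
  A <- matrix(0, 3, 3)
  A[2, 1] <- 0.6 # a -> b, planted but omitted from the model
  Phi <- diag(0.4, 3)
  X <- sim_usem(A, Phi, rep(1, 3), 1000, seed = 14)
  s <- build_lagged_sample(participant_ts("P01", list(X)))
  fit <- fit_usem(s, null_structure(rois3()))
  expect_lt(fit$fit$pvalue, 0.001)
  expect_gt(fit$fit$rmsea, 0.10)
})

test_that("degrees of freedom match the hand count at p = 2", {
  # 2p block has p(2p+1) = 10 unique moments; the saturated predictor
  # block fixes p(p+1)/2 = 3 of them; AR-only model frees 2 AR + 2 psi
  X <- sim_usem(matrix(0, 2, 2), diag(0.4, 2), c(1, 1), 300, seed = 15)
  s <- build_lagged_sample(participant_ts("P01", list(X)))
  fit <- fit_usem(s, null_structure(rois2()))
  expect_equal(fit$fit$df, 10 - 3 - 4)
  # baseline frees only the 2 psi
  expect_equal(fit$fit$df_baseline, 10 - 3 - 2)
})

test_that("profiled discrepancy equals the direct F_ML formula", {
  A <- matrix(0, 2, 2)
  A[2, 1] <- 0.5
  X <- sim_usem(A, diag(0.4, 2), c(1, 1), 500, seed = 16)
  s <- build_lagged_sample(participant_ts("P01", list(X)))
  st <- network_structure(data.frame(source = "a", target = "b", lag = 0L), rois2())
  fit <- fit_usem(s, st)
  Sig <- usemnet:::implied_sigma(s, fit$A, fit$Phi, fit$psi)
  direct <- as.numeric(
    determinant(Sig)$modulus - determinant(s$C)$modulus +
      sum(diag(s$C %*% solve(Sig))) - 2 * s$p
  )
  expect_equal(fit$Fml, direct, tolerance = 1e-9)
})

test_that("adding a path never increases chi-square", {
  A <- matrix(0, 3, 3)
  A[2, 1] <- 0.4
  Phi <- diag(0.4, 3)
  Phi[3, 1] <- 0.3
  X <- sim_usem(A, Phi, rep(1, 3), 500, seed = 17)
  s <- build_lagged_sample(participant_ts("P01", list(X)))
  st <- null_structure(rois3())
  fit <- fit_usem(s, st, compute_se = FALSE)
  cands <- usemnet:::candidate_paths(st)
  for (i in seq_len(nrow(cands))) {
    st2 <- usemnet:::st_add_path(st, cands$source[i], cands$target[i],
      cands$lag[i], "individual")
    f2 <- fit_usem(s, st2, compute_se = FALSE)
    expect_lte(f2$fit$chi2, fit$fit$chi2 + 1e-6)
  }
})

test_that("cyclic (reciprocal) structures are estimated consistently", {
  # reciprocal pair: check the coupled fit against brute-force grid
  # refinement of the profiled objective
  A <- matrix(0, 2, 2)
  A[2, 1] <- 0.5
  Phi <- diag(0.5, 2)
  X <- sim_usem(A, Phi, c(1, 1), 2000, seed = 18)
  s <- build_lagged_sample(participant_ts("P01", list(X)))
  st <- network_structure(
    data.frame(source = c("a", "b"), target = c("b", "a"), lag = 0L), rois2()
  )
  fit <- fit_usem(s, st, compute_se = FALSE)
  # optimality: no small perturbation of the two coupled coefficients
  # improves the fit
  eqinfo <- usemnet:::build_equations(st)
  base <- fit$Fml
  for (d in c(-0.02, 0.02)) {
    for (target in c("a", "b")) {
      est <- fit$estimates
      i <- which(est$lag == 0L & est$target == target)
      st_beta <- fit$internal$beta
      st_beta[i] <- st_beta[i] + d
      cm <- usemnet:::coef_matrices(st, st_beta)
      # profile psi at the perturbed coefficients
      M <- diag(2) - cm$A
      G <- M %*% s$C[3:4, 3:4] %*% t(M) - M %*% s$C[3:4, 1:2] %*% t(cm$Phi) -
        cm$Phi %*% s$C[1:2, 3:4] %*% t(M) + cm$Phi %*% s$C[1:2, 1:2] %*% t(cm$Phi)
      Fpert <- sum(log(diag(G))) - 2 * log(abs(det(M))) - s$logdet_s221
      expect_gte(Fpert, base - 1e-8)
    }
  }
})

test_that("overparameterized and undersized problems raise estimation errors", {
  X <- sim_usem(matrix(0, 2, 2), diag(0.4, 2), c(1, 1), 30, seed = 19)
  s <- build_lagged_sample(participant_ts("P01", list(X)))
  # both contemporaneous directions + all lagged paths: df would be -1
  allp <- expand.grid(source = c("a", "b"), target = c("a", "b"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  allp$lag <- 1L
  both <- rbind(allp, data.frame(source = c("a", "b"), target = c("b", "a"), lag = 0L))
  st <- network_structure(both, rois2())
  expect_error(fit_usem(s, st), class = "usemnet_estimation_error")
})
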