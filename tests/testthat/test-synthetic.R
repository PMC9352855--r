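test_that("identical config and seed give identical truths and data", {
  cfg <- truth_config(n_participants = 3, individual_range = c(2, 4),
    run_lengths = c(40L, 40L))
  t1 <- generate_truth(cfg, seed = 7)
  t2 <- generate_truth(cfg, seed = 7)
  expect_identical(t1, t2)
  d1 <- simulate_timeseries(t1)
  d2 <- simulate_timeseries(t2)
  expect_identical(d1, d2)
  c1 <- generate_covariates(t1)
  c2 <- generate_covariates(t2)
  expect_identical(c1, c2)
})

test_that("a null config plants only the 10 AR paths", {
  cfg <- truth_config(group_counts = c(mrn = 0, dmn = 0, between = 0),
    individual_range = c(0, 0))
  tr <- generate_truth(cfg, seed = 5)
  expect_equal(nrow(tr$group_paths), 0)
  expect_true(all(vapply(tr$individual_paths, nrow, 0L) == 0))
  st <- truth_structure(tr, "P01")
  expect_equal(nrow(st$paths), 10)
  expect_true(all(st$paths$level == "ar"))
})

test_that("planted block counts reproduce the expected metric profile", {
  cfg <- truth_config(group_counts = c(mrn = 12, dmn = 6, between = 7),
    individual_range = c(0, 0), n_participants = 1)
  tr <- generate_truth(cfg, seed = 9)
  met <- compute_metrics(truth_structure(tr, "P01"), tr$rois)
  expect_equal(met$complexity, 35L)
  expect_equal(met$density_mrn, 12 / 35)
  expect_equal(met$density_dmn, 6 / 35)
  expect_equal(met$density_between, 7 / 35)
})

test_that("every participant system satisfies the truth invariants", {
  tr <- generate_truth(truth_config(), seed = 31)
  gkey <- sprintf("%d:%s>%s", tr$group_paths$lag, tr$group_paths$source,
    tr$group_paths$target)
  for (id in tr$participants) {
    st <- truth_structure(tr, id)
    keys <- sprintf("%d:%s>%s", st$paths$lag, st$paths$source, st$paths$target)
    expect_true(all(gkey %in% keys)) # superset of the group structure
    expect_false(any(st$paths$source == st$paths$target & st$paths$lag == 0L))
    ar <- st$paths$source == st$paths$target & st$paths$lag == 1L
    expect_equal(sum(ar), 10) # all AR self-paths present
    M <- solve(diag(10) - tr$A[[id]])
    rho <- max(Mod(eigen(M %*% tr$Phi[[id]], only.values = TRUE)$values))
    expect_lt(rho, 1) # stationary
  }
})

test_that("the default configuration emits the study-scale dataset", {
  tr <- generate_truth(truth_config(), seed = 32)
  sim <- simulate_timeseries(tr)
  expect_length(sim, 11)
  for (ts in sim) {
    expect_length(ts$runs, 2)
    expect_true(all(vapply(ts$runs, nrow, 0L) == 134))
    expect_true(all(vapply(ts$runs, ncol, 0L) == 10))
    expect_equal(colnames(ts$runs[[1]]), default_roi_set()$labels)
  }
})

test_that("a zero-weight system produces white noise", {
  cfg <- truth_config(n_participants = 1, rois = rois2(),
    run_lengths = 10000L, group_counts = c(mrn = 0, dmn = 0, between = 0),
    individual_range = c(0, 0))
  tr <- generate_truth(cfg, seed = 33)
  tr$A[[1]][] <- 0
  tr$Phi[[1]][] <- 0
  X <- simulate_timeseries(tr)[[1]]$runs[[1]]
  S <- cov(cbind(X[-nrow(X), ], X[-1, ]))
  expect_true(all(abs(diag(S)[] - 1) < 0.05))
  expect_true(all(abs(S[upper.tri(S)]) < 0.05))
})

test_that("empirical moments match the analytic stationary covariance", {
  # moderately dependent system: with spectral radius well below 1 the
  # sampling noise of a T = 10000 covariance sits comfortably inside the
  # 5% band, so a simulator bias would be visible
  cfg <- truth_config(n_participants = 1, rois = rois4(),
    run_lengths = 10000L, group_counts = c(mrn = 1, dmn = 1, between = 1),
    individual_range = c(0, 0), prop_lagged = 0.3,
    weight_range = c(0.3, 0.45), ar_range = c(0.45, 0.55))
  tr <- generate_truth(cfg, seed = 34)
  # five independent runs of T = 10000 average away the sampling noise of
  # any single realization; a simulator bias would not average away
  runs <- simulate_timeseries(tr, run_lengths = rep(10000L, 5))[[1]]$runs
  an <- stationary_covariance(tr$A[[1]], tr$Phi[[1]], tr$noise_variances)
  emp0 <- Reduce(`+`, lapply(runs, cov)) / length(runs)
  emp1 <- Reduce(`+`, lapply(runs, function(X) {
    cov(X[-1, ], X[-nrow(X), ]) # Cov(eta_t, eta_{t-1})
  })) / length(runs)
  rel <- function(a, b) norm(a - b, "F") / norm(b, "F")
  expect_lt(rel(emp0, an$gamma0), 0.05)
  expect_lt(rel(emp1, an$gamma1), 0.05)
})

test_that("covariate targets are met by the truncated draws", {
  cfg <- truth_config(n_participants = 10000, rois = rois2(),
    run_lengths = c(20L, 20L), group_counts = c(mrn = 0, dmn = 0, between = 0),
    individual_range = c(0, 0))
  tr <- generate_truth(cfg, seed = 35)
  cov <- generate_covariates(tr, hormone_behavior_params(), seed = 36)
  expect_true(all(cov$estradiol >= 0))
  expect_true(all(cov$progesterone >= 0))
  expect_true(all(cov$pct_correct >= 0 & cov$pct_correct <= 100))
  expect_lt(abs(mean(cov$progesterone) - 239.01) / 239.01, 0.02)
  expect_lt(abs(mean(cov$estradiol) - 1.33) / 1.33, 0.02)
  expect_lt(abs(mean(cov$pct_correct) - 75) / 75, 0.02)
})

test_that("zero SDs give every participant the exact mean", {
  cfg <- truth_config(n_participants = 5, rois = rois2(), run_lengths = c(20L, 20L),
    group_counts = c(mrn = 0, dmn = 0, between = 0), individual_range = c(0, 0))
  tr <- generate_truth(cfg, seed = 37)
  pars <- hormone_behavior_params(
    sds = c(estradiol = 0, progesterone = 0, testosterone = 0, pct_correct = 0)
  )
  cov <- generate_covariates(tr, pars, seed = 38)
  expect_true(all(cov$progesterone == 239.01))
  expect_true(all(cov$pct_correct == 75))
})

test_that("zero coupling leaves behavior independent of network size", {
  cfg <- truth_config(n_participants = 1000, rois = rois4(),
    run_lengths = c(20L, 20L), group_counts = c(mrn = 1, dmn = 1, between = 1),
    individual_range = c(1, 6))
  tr <- generate_truth(cfg, seed = 39)
  pars <- hormone_behavior_params(
    coupling = c(estradiol = 0, progesterone = 0, testosterone = 0, pct_correct = 0)
  )
  cov <- generate_covariates(tr, pars, seed = 40)
  ic <- vapply(tr$individual_paths, nrow, 0L)
  expect_lt(abs(cor(cov$pct_correct, ic)), 0.1)
})

test_that("infeasible path requests raise configuration errors", {
  expect_error(
    generate_truth(truth_config(group_counts = c(mrn = 100, dmn = 0, between = 0)),
      seed = 1),
    class = "usemnet_config_error"
  )
  expect_error(truth_config(weight_range = c(0, 1.2)) |> generate_truth(seed = 1),
    class = "usemnet_config_error")
})
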