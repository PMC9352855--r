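# Small-scale search behavior; the paper-scale specificity and recovery
# benchmarks live in test-acceptance.R.

make_sample_set <- function(n, A, Phi, psi, Tn, seed0, labels) {
  lapply(seq_len(n), function(i) {
    X <- sim_usem(A, Phi, psi, Tn, seed = seed0 + i, labels = labels)
    build_lagged_sample(participant_ts(sprintf("P%02d", i), list(X)))
  })
}

test_that("the 75% criterion requires 9 of 11 participants", {
  cfg <- search_config()
  expect_equal(ceiling(cfg$group_threshold * 11), 9)
  A <- matrix(0, 2, 2)
  samples <- make_sample_set(11, A, diag(0.4, 2), c(1, 1), 60, 100, c("a", "b"))
  gs <- group_search(samples, cfg, rois = rois2())
  expect_equal(gs$n_required, 9)
})

test_that("a shared planted path is found at group level and weights differ", {
  A <- matrix(0, 3, 3)
  A[2, 1] <- 0.5 # a -> b in every participant
  Phi <- diag(0.4, 3)
  samples <- make_sample_set(6, A, Phi, rep(1, 3), 300, 200, c("a", "b", "c"))
  res <- run_sample_search(
    lapply(seq_along(samples), function(i) {
      X <- sim_usem(A, Phi, rep(1, 3), 300, seed = 200 + i, labels = c("a", "b", "c"))
      participant_ts(sprintf("P%02d", i), list(X))
    }),
    search_config()
  )
  grp <- res$group_structure$paths
  expect_true(any(grp$source == "a" & grp$target == "b" & grp$lag == 0L &
    grp$level == "group"))
  betas <- vapply(res$networks, function(nw) {
    nw$estimates$beta[nw$estimates$source == "a" & nw$estimates$target == "b" &
      nw$estimates$lag == 0L]
  }, 0)
  expect_gt(length(unique(round(betas, 8))), 1) # individualized weights
  expect_true(all(abs(betas - 0.5) < 0.15))
})

test_that("every final structure contains every group path", {
  A <- matrix(0, 3, 3)
  A[2, 1] <- 0.5
  Phi <- diag(0.4, 3)
  ts_list <- lapply(1:5, function(i) {
    X <- sim_usem(A, Phi, rep(1, 3), 250, seed = 300 + i, labels = c("a", "b", "c"))
    participant_ts(sprintf("P%02d", i), list(X))
  })
  res <- run_sample_search(ts_list, search_config())
  gkey <- usemnet:::path_key(res$group_structure$paths)
  for (nw in res$networks) {
    expect_true(all(gkey %in% usemnet:::path_key(nw$structure$paths)))
  }
})

test_that("the search is deterministic for a fixed dataset and config", {
  A <- matrix(0, 3, 3)
  A[2, 1] <- 0.5
  Phi <- diag(0.4, 3)
  Phi[3, 1] <- 0.3
  ts_list <- lapply(1:4, function(i) {
    X <- sim_usem(A, Phi, rep(1, 3), 200, seed = 400 + i, labels = c("a", "b", "c"))
    participant_ts(sprintf("P%02d", i), list(X))
  })
  r1 <- run_sample_search(ts_list, search_config())
  r2 <- run_sample_search(ts_list, search_config())
  expect_identical(r1$group_structure$paths, r2$group_structure$paths)
  expect_identical(r1$group_trace, r2$group_trace)
  expect_identical(
    lapply(r1$networks, function(nw) nw$estimates),
    lapply(r2$networks, function(nw) nw$estimates)
  )
})

test_that("a person-unique planted path appears at the individual level", {
  A <- matrix(0, 3, 3)
  A[2, 1] <- 0.5 # group path for everyone
  Phi <- diag(0.4, 3)
  ts_list <- lapply(1:5, function(i) {
    Ai <- A
    if (i == 3) Ai[3, 2] <- 0.6 # unique to participant 3: b -> c
    X <- sim_usem(Ai, Phi, rep(1, 3), 400, seed = 500 + i, labels = c("a", "b", "c"))
    participant_ts(sprintf("P%02d", i), list(X))
  })
  res <- run_sample_search(ts_list, search_config())
  est3 <- res$networks[["P03"]]$estimates
  expect_true(any(est3$source == "b" & est3$target == "c" & est3$lag == 0L &
    est3$level == "individual"))
})

test_that("a well-fitting group model gains no individual paths", {
  A <- matrix(0, 3, 3)
  A[2, 1] <- 0.6
  Phi <- diag(0.5, 3)
  X <- sim_usem(A, Phi, rep(1, 3), 5000, seed = 600, labels = c("a", "b", "c"))
  s <- build_lagged_sample(participant_ts("P01", list(X)))
  truth_st <- network_structure(
    data.frame(source = "a", target = "b", lag = 0L, level = "group"), rois3()
  )
  res <- individual_search(s, truth_st, search_config())
  expect_equal(sum(res$network$estimates$level == "individual"), 0)
  expect_true(usemnet:::fit_rule_met(res$network$fit, search_config()))
})

test_that("logged additions strictly decrease the participant chi-square", {
  A <- matrix(0, 3, 3)
  A[2, 1] <- 0.5
  A[3, 1] <- 0.4
  Phi <- diag(0.4, 3)
  X <- sim_usem(A, Phi, rep(1, 3), 400, seed = 700, labels = c("a", "b", "c"))
  s <- build_lagged_sample(participant_ts("P01", list(X)))
  res <- individual_search(s, null_structure(rois3()), search_config())
  adds <- res$trace[res$trace$action == "add", ]
  if (nrow(adds)) {
    expect_true(all(adds$chi2_after < adds$chi2_before))
  }
  expect_gt(nrow(adds), 0)
})

test_that("search configuration is validated", {
  expect_error(search_config(group_threshold = 0.4), class = "usemnet_config_error")
  expect_error(search_config(alpha_mi = 0), class = "usemnet_config_error")
  expect_error(search_config(fit_rule = 5), class = "usemnet_config_error")
})

test_that("group search needs at least two participants", {
  X <- sim_usem(matrix(0, 2, 2), diag(0.4, 2), c(1, 1), 100, seed = 800)
  s <- build_lagged_sample(participant_ts("P01", list(X)))
  expect_error(group_search(list(s)), class = "usemnet_input_error")
})
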